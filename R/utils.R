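# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
#' Cross-distance matrix between two point sets (rows are points).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# user's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

stop_gd <- function(...) stop(..., call. = FALSE)
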