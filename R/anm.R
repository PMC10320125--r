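#' Anisotropic network model (ANM) mode basis for backbone flexibility
#'
#' Builds an elastic network over CA atoms (uniform force constant, spring
#' cutoff `cutoff` angstrom), diagonalizes the `3n x 3n` Hessian and
#' returns the `n_modes` lowest-frequency internal modes, skipping the six
#' zero-frequency rigid-body modes. Modes are orthonormal displacement
#' fields over the CA atoms; during [apply_pose()] each residue moves
#' rigidly with its CA. Flexibility is disabled for membrane-associated
#' receptors, which must stay fixed relative to the membrane slab.
#'
#' @param mol a [Molecule] with at least 3 CA atoms; kind must not be
#'   `membrane_protein`.
#' @param n_modes number of internal modes to return (default 10).
#' @param cutoff spring cutoff in angstrom (default 15).
#' @param scale angstrom of displacement per unit mode amplitude
#'   (default 3).
#' @return a `ModeBasis`: list with `modes` (list of `n_ca x 3` matrices),
#'   `eigenvalues` (internal-mode eigenvalues, ascending), `scale`, and
#'   `ca_keys` (residue keys in CA order).
#' @export
compute_anm_basis <- function(mol, n_modes = 10, cutoff = 15, scale = 3) {
  if (identical(mol$kind, "membrane_protein"))
    stop_gd("flexibility disabled for membrane receptors")
  if (n_modes < 0) stop_gd("invalid mode count")
  ca <- mol$atoms[mol$atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) < 3) stop_gd("need at least 3 CA atoms for an elastic network")
  xyz <- as.matrix(ca[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- cross_dist(xyz, xyz)
  adj <- d <= cutoff & d > 1e-9
  if (!network_connected(adj)) stop_gd("disconnected elastic network")
  H <- anm_hessian(xyz, adj, d)
  eig <- eigen(H, symmetric = TRUE)
  vals <- rev(eig$values)              # ascending
  vecs <- eig$vectors[, rev(seq_len(3 * n)), drop = FALSE]
  n_zero <- sum(abs(vals) < 1e-8)
  avail <- 3 * n - n_zero
  if (n_modes > avail)
    stop_gd("requested ", n_modes, " modes but only ", avail, " internal modes exist")
  sel <- seq.int(n_zero + 1, n_zero + n_modes)
  modes <- lapply(sel, function(j) matrix(vecs[, j], ncol = 3, byrow = TRUE))
  structure(list(modes = modes,
                 eigenvalues = vals[sel],
                 all_eigenvalues = vals,
                 scale = scale,
                 ca_keys = residue_keys(ca)),
            class = "ModeBasis")
}

# Dense ANM Hessian: off-diagonal 3x3 block for a contact pair (i, j) is
# -(d d^T)/|d|^2 with d = x_j - x_i; diagonal blocks are minus the row sums.
anm_hessian <- function(xyz, adj, d) {
  n <- nrow(xyz)
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (!adj[i, j]) next
      dv <- xyz[j, ] - xyz[i, ]
      blk <- -tcrossprod(dv) / sum(dv * dv)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk
      H[rj, ri] <- blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
    }
  }
  H
}

network_connected <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(adj[i, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}
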