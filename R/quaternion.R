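#' Quaternion algebra for rigid-body rotations
#'
#' Rotations of ligand poses are encoded as unit quaternions `(w, x, y, z)`.
#' Quaternions are kept in canonical sign (`w >= 0`; if `w == 0`, the first
#' nonzero component is positive) so that the antipodal pair `q` and `-q`,
#' which encode the same rotation, are identified everywhere, in particular
#' in the pose-space metric.
#'
#' @param q,a,b numeric length-4 quaternions `(w, x, y, z)`.
#' @name quaternion
NULL

#' @rdname quaternion
#' @return `quat_normalize()`: a unit quaternion in canonical sign.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-12) stop_gd("cannot normalize a zero quaternion")
  quat_canonical(q / n)
}

#' @rdname quaternion
#' @export
quat_canonical <- function(q) {
  for (k in 1:4) {
    if (q[k] > 0) return(q)
    if (q[k] < 0) return(-q)
  }
  q
}

#' @rdname quaternion
#' @return `quat_multiply()`: the Hamilton product `a * b`.
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' @rdname quaternion
#' @export
quat_conjugate <- function(q) c(q[1], -q[2:4])

#' Build a quaternion from an axis and an angle
#'
#' @param axis 3-vector (need not be unit length).
#' @param angle rotation angle in radians.
#' @return unit quaternion in canonical sign.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- unit(axis)
  quat_canonical(c(cos(angle / 2), sin(angle / 2) * axis))
}

#' Minimal rotation aligning one direction onto another
#'
#' Returns the smallest-angle rotation mapping unit direction `from` onto
#' unit direction `to`. Antiparallel inputs rotate by pi about an arbitrary
#' perpendicular axis.
#'
#' @param from,to 3-vectors (normalized internally).
#' @return unit quaternion.
#' @export
quat_align_vectors <- function(from, to) {
  f <- unit(from); t <- unit(to)
  d <- sum(f * t)
  if (d > 1 - 1e-12) return(c(1, 0, 0, 0))
  if (d < -1 + 1e-12) {
    # any axis perpendicular to f
    ax <- cross3(f, c(1, 0, 0))
    if (vec_norm(ax) < 1e-6) ax <- cross3(f, c(0, 1, 0))
    return(quat_from_axis_angle(ax, pi))
  }
  ax <- cross3(f, t)
  quat_normalize(c(1 + d, ax))
}

#' Rotate points by a unit quaternion
#'
#' Standard conjugation `q p q*`; an isometry of 3-space fixing the origin.
#'
#' @param q unit quaternion (`||q| - 1| <= 1e-6` enforced).
#' @param p a 3-vector or an `n x 3` matrix of points.
#' @return rotated points, same shape as `p`.
#' @export
rotate_point <- function(q, p) {
  if (abs(sqrt(sum(q * q)) - 1) > 1e-6) stop_gd("non-unit quaternion")
  w <- q[1]; v <- q[2:4]
  # R = (w^2 - v.v) I + 2 v v^T + 2 w [v]_x
  vv <- sum(v * v)
  R <- diag(3) * (w * w - vv) + 2 * tcrossprod(v) +
    2 * w * matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  if (is.matrix(p)) p %*% t(R) else as.numeric(R %*% p)
}

#' Uniform random rotation (Shoemake's method)
#'
#' Draws a quaternion uniformly on SO(3) from three uniform variates. Uses
#' the current RNG stream.
#'
#' @return unit quaternion in canonical sign.
#' @export
random_quaternion <- function() {
  u <- runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  quat_canonical(q)
}
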