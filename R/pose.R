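#' Ligand poses
#'
#' A `Pose` places the ligand in the receptor frame: a translation (the
#' target position of the ligand heavy-atom centroid, in angstrom), a unit
#' quaternion rotation about that centroid (canonical sign, see
#' [quat_canonical()]), and an optional vector of normal-mode amplitudes
#' (dimensionless) driving backbone flexibility through a [compute_anm_basis()]
#' mode basis.
#'
#' @param translation 3-vector, angstrom.
#' @param rotation unit quaternion `(w, x, y, z)`; normalized and
#'   sign-canonicalized on construction.
#' @param mode_amplitudes numeric vector (may be length 0).
#' @return an object of class `"Pose"`.
#' @export
Pose <- function(translation = c(0, 0, 0), rotation = c(1, 0, 0, 0),
                 mode_amplitudes = numeric(0)) {
  stopifnot(length(translation) == 3, length(rotation) == 4)
  structure(list(translation = as.numeric(translation),
                 rotation = quat_normalize(as.numeric(rotation)),
                 mode_amplitudes = as.numeric(mode_amplitudes)),
            class = "Pose")
}

#' @export
print.Pose <- function(x, ...) {
  cat(sprintf("Pose: t = (%.2f, %.2f, %.2f), q = (%.3f, %.3f, %.3f, %.3f), %d modes\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation[1], x$rotation[2], x$rotation[3], x$rotation[4],
              length(x$mode_amplitudes)))
  invisible(x)
}

#' Draw a random pose inside a swarm
#'
#' The translation is uniform in the ball of radius `swarm_radius` around
#' `swarm_center`, the rotation uniform on SO(3) ([random_quaternion()]),
#' and amplitudes i.i.d. standard normal. Uses the current RNG stream, so
#' results are reproducible under a fixed seed.
#'
#' @param swarm_center 3-vector.
#' @param swarm_radius positive radius, angstrom.
#' @param n_modes number of mode amplitudes (`>= 0`).
#' @return a [Pose].
#' @export
random_pose <- function(swarm_center, swarm_radius, n_modes = 0) {
  if (swarm_radius <= 0) stop_gd("swarm_radius must be positive")
  if (n_modes < 0) stop_gd("invalid mode count")
  # uniform in ball: direction on sphere, radius ~ U^(1/3)
  d <- stats::rnorm(3)
  while (vec_norm(d) < 1e-12) d <- stats::rnorm(3)
  r <- swarm_radius * stats::runif(1)^(1 / 3)
  Pose(translation = swarm_center + r * unit(d),
       rotation = random_quaternion(),
       mode_amplitudes = if (n_modes > 0) stats::rnorm(n_modes) else numeric(0))
}

#' Apply a pose to ligand coordinates
#'
#' Rotates the ligand about its heavy-atom centroid by the pose rotation,
#' translates the centroid to the pose translation, then (when a mode
#' basis is given) displaces each residue rigidly by its CA atom's
#' normal-mode displacement `sum_k amplitude_k * scale * mode_k`.
#' Amplitudes without a basis are inert (rigid docking).
#'
#' @param ligand a [Molecule].
#' @param pose a [Pose].
#' @param basis a `ModeBasis` from [compute_anm_basis()], or `NULL`.
#' @return `n x 3` matrix of posed coordinates for all ligand atoms.
#' @export
apply_pose <- function(ligand, pose, basis = NULL) {
  xyz <- coords(ligand)
  cen <- centroid(ligand)
  rotated <- rotate_point(pose$rotation, sweep(xyz, 2, cen))
  out <- sweep(rotated, 2, pose$translation, "+")
  if (!is.null(basis) && length(pose$mode_amplitudes) > 0) {
    if (length(pose$mode_amplitudes) != length(basis$modes))
      stop_gd("mode basis incompatible")
    if (any(pose$mode_amplitudes != 0)) {
      n_ca <- nrow(basis$modes[[1]])
      disp <- matrix(0, n_ca, 3)
      for (k in seq_along(basis$modes))
        disp <- disp + pose$mode_amplitudes[k] * basis$scale * basis$modes[[k]]
      ridx <- residue_index_of_atoms(ligand, basis$ca_keys)
      out <- out + disp[ridx, , drop = FALSE]
    }
  }
  out
}

# Map every atom to the row of its residue in the CA ordering `ca_keys`.
residue_index_of_atoms <- function(mol, ca_keys) {
  keys <- residue_keys(mol$atoms)
  idx <- match(keys, ca_keys)
  if (anyNA(idx)) stop_gd("mode basis incompatible")
  idx
}

#' Distance between two poses
#'
#' Euclidean norm of the concatenated difference vector
#' `[t_a - t_b, w_q (q_a - q_b), nu_a - nu_b]`, where translations are in
#' angstrom, quaternions carry weight `w_q` (angstrom per quaternion unit)
#' and amplitudes are dimensionless. With canonical-sign quaternions this
#' is a metric identifying `q` and `-q`.
#'
#' @param a,b [Pose] objects with equal amplitude lengths.
#' @param w_q quaternion weight, default 10.
#' @return nonnegative scalar.
#' @export
pose_distance <- function(a, b, w_q = 10) {
  if (length(a$mode_amplitudes) != length(b$mode_amplitudes))
    stop_gd("amplitude-length mismatch")
  sqrt(sum((a$translation - b$translation)^2) +
         w_q^2 * sum((a$rotation - b$rotation)^2) +
         sum((a$mode_amplitudes - b$mode_amplitudes)^2))
}

# Flatten poses to rows of [t, w_q * q, nu] so per-step neighbor searches
# can use one vectorized distance computation; row distances equal
# pose_distance exactly.
pose_matrix <- function(poses, w_q = 10) {
  t(vapply(poses, function(p)
    c(p$translation, w_q * p$rotation, p$mode_amplitudes),
    numeric(7 + length(poses[[1]]$mode_amplitudes))))
}
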