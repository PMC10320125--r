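# Solvent accessibility by the rolling-probe (Shrake-Rupley) point-sampling
# approximation: an atom is surface-exposed when any test point on its
# probe-expanded sphere is outside every neighbor's probe-expanded sphere.

sphere_points <- function(n = 92) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Surface heavy atoms of a molecule
#'
#' Marks heavy atoms with nonzero solvent accessibility under a rolling
#' probe of radius `probe` (Shrake-Rupley point sampling, 92 points per
#' atom). The cheaper `"radial"` method instead takes atoms in the outer
#' half of the radial-distance distribution about the centroid.
#'
#' @param mol a [Molecule].
#' @param probe probe radius, angstrom (default 1.4).
#' @param method `"sasa"` (default) or `"radial"`.
#' @return logical vector over heavy atoms (in heavy-atom order).
#' @export
surface_atoms <- function(mol, probe = 1.4, method = c("sasa", "radial")) {
  method <- match.arg(method)
  xyz <- coords(mol, heavy_only = TRUE)
  if (method == "radial") {
    r <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
    return(r >= stats::median(r))
  }
  rad <- mol$atoms$radius[heavy_mask(mol)] + probe
  n <- nrow(xyz)
  pts <- sphere_points()
  d <- cross_dist(xyz, xyz)
  out <- logical(n)
  for (i in seq_len(n)) {
    nb <- which(d[, i] < rad[i] + rad & seq_len(n) != i)
    if (!length(nb)) { out[i] <- TRUE; next }
    test <- sweep(pts * rad[i], 2, xyz[i, ], "+")
    buried_all <- rep(FALSE, nrow(test))
    for (j in nb) {
      buried_all <- buried_all |
        rowSums(sweep(test, 2, xyz[j, ])^2) < rad[j]^2
      if (all(buried_all)) break
    }
    out[i] <- !all(buried_all)
  }
  out
}
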