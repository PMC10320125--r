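#' Swarm generation over the receptor surface
#'
#' Sampling is organized in swarms: independent loci anchored just off the
#' receptor surface, each holding its own glowworm population. Candidate
#' centers are built by displacing every surface heavy atom outward
#' (along the atom-minus-centroid direction) by `placement_distance`, then
#' greedily thinned so that no two centers lie closer than
#' `density_spacing` (visiting candidates by descending distance from the
#' centroid, ties by atom serial). The number of swarms is therefore a
#' function of receptor size and shape rather than a constant.
#'
#' @param receptor a [Molecule] (at least 4 heavy atoms).
#' @param placement_distance outward displacement of centers, angstrom.
#' @param swarm_radius sampling radius of each swarm, angstrom.
#' @param density_spacing minimum center-to-center distance, angstrom.
#' @param n_swarms optional override of the dynamic count: survivors are
#'   subsampled evenly, or the spacing is tightened for a denser sampling.
#' @param surface_method passed to [surface_atoms()].
#' @return list of `Swarm` objects (`id`, `center`, `radius`, `glowworms`).
#' @export
generate_swarms <- function(receptor, placement_distance = 10,
                            swarm_radius = 10, density_spacing = 10,
                            n_swarms = NULL,
                            surface_method = c("sasa", "radial")) {
  hm <- heavy_mask(receptor)
  if (sum(hm) < 4) stop_gd("receptor too small")
  surface_method <- match.arg(surface_method)
  xyz <- coords(receptor, heavy_only = TRUE)
  serial <- receptor$atoms$serial[hm]
  cen <- colMeans(xyz)
  surf <- surface_atoms(receptor, method = surface_method)
  xyz <- xyz[surf, , drop = FALSE]; serial <- serial[surf]
  dr <- sweep(xyz, 2, cen)
  nr <- sqrt(rowSums(dr^2))
  ok <- nr > 1e-9
  xyz <- xyz[ok, , drop = FALSE]; dr <- dr[ok, , drop = FALSE]
  nr <- nr[ok]; serial <- serial[ok]
  cand <- xyz + placement_distance * dr / nr
  ord <- order(-nr, serial)
  cand <- cand[ord, , drop = FALSE]
  centers <- thin_candidates(cand, density_spacing)
  if (!is.null(n_swarms)) {
    spacing <- density_spacing
    while (nrow(centers) < n_swarms && spacing > 0.5) {
      spacing <- spacing * 0.8
      centers <- thin_candidates(cand, spacing)
    }
    if (nrow(centers) > n_swarms) {
      pick <- unique(round(seq(1, nrow(centers), length.out = n_swarms)))
      centers <- centers[pick, , drop = FALSE]
    }
  }
  lapply(seq_len(nrow(centers)), function(i)
    structure(list(id = i, center = centers[i, ], radius = swarm_radius,
                   glowworms = NULL), class = "Swarm"))
}

thin_candidates <- function(cand, spacing) {
  kept <- matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(kept) == 0 ||
        min(sqrt(rowSums(sweep(kept, 2, p)^2))) >= spacing)
      kept <- rbind(kept, p)
  }
  rownames(kept) <- NULL
  kept
}

#' Filter swarms by receptor restraints
#'
#' Keeps a swarm when its center lies within `keep_cutoff` of any heavy
#' atom of any receptor-restraint residue, excluding irrelevant sampling
#' regions before the simulation. With no receptor restraints this is the
#' identity.
#'
#' @param swarms list of swarms from [generate_swarms()].
#' @param receptor a [Molecule].
#' @param restraints a `RestraintSet`.
#' @param keep_cutoff angstrom (default 20).
#' @return the surviving swarms, ids and poses untouched.
#' @export
filter_swarms_by_restraints <- function(swarms, receptor, restraints,
                                        keep_cutoff = 20) {
  if (!has_receptor_restraints(restraints)) return(swarms)
  sets <- restraint_atom_sets(receptor, restraints$receptor)
  axyz <- as.matrix(receptor$atoms[unlist(sets), c("x", "y", "z")])
  keep <- vapply(swarms, function(s)
    min(cross_dist(matrix(s$center, 1), axyz)) <= keep_cutoff, logical(1))
  if (!any(keep)) stop_gd("restraints eliminate all swarms")
  swarms[keep]
}

#' Filter swarms by an explicit membrane
#'
#' Keeps a swarm only when its center lies outside the slab spanned by the
#' membrane bead z-extrema, widened by `cushion` on both sides, so that
#' sampling is restricted to the extramembranous space.
#'
#' @param swarms list of swarms.
#' @param membrane a `MembraneModel` from [parse_membrane_beads()] or
#'   [build_membrane()].
#' @param cushion slab widening, angstrom (default 5).
#' @return surviving swarms.
#' @export
filter_swarms_by_membrane <- function(swarms, membrane, cushion = 5) {
  keep <- vapply(swarms, function(s) {
    z <- s$center[3]
    z > membrane$z_max + cushion || z < membrane$z_min - cushion
  }, logical(1))
  if (!any(keep)) stop_gd("membrane eliminates all swarms")
  swarms[keep]
}

#' Initialize the glowworm population of a swarm
#'
#' Draws `n_glowworms` random poses inside the swarm
#' ([random_pose()]). When ligand restraints are present, each agent
#' instead orients the ligand so that a randomly drawn ligand-restraint
#' residue faces a randomly drawn receptor-restraint residue: the minimal
#' rotation aligning the ligand-centroid-to-residue direction onto the
#' direction toward the receptor patch, perturbed by a random rotation of
#' at most `jitter_deg` degrees. All agents start with luciferin `ell0`
#' and vision range `2 * swarm radius`.
#'
#' @param swarm a `Swarm`.
#' @param ligand a [Molecule].
#' @param n_glowworms population size (default 200, minimum 2).
#' @param restraints a `RestraintSet` or `NULL`.
#' @param receptor receptor [Molecule] (required when ligand restraints
#'   are present).
#' @param n_modes number of flexibility mode amplitudes per pose.
#' @param seed integer seed; the population is reproducible given it.
#' @param ell0 initial luciferin (default 5).
#' @param jitter_deg orientation perturbation bound, degrees (default 15).
#' @return the swarm with its `glowworms` list populated.
#' @export
init_glowworms <- function(swarm, ligand, n_glowworms = 200,
                           restraints = NULL, receptor = NULL, n_modes = 0,
                           seed = 1, ell0 = 5, jitter_deg = 15) {
  if (n_glowworms < 2) stop_gd("need at least 2 glowworms")
  oriented <- has_ligand_restraints(restraints)
  if (oriented) {
    if (is.null(receptor)) stop_gd("receptor needed for restraint orientation")
    rec_cen <- lapply(restraint_atom_sets(receptor, restraints$receptor),
                      function(i) colMeans(as.matrix(
                        receptor$atoms[i, c("x", "y", "z")])))
    lig_cen <- lapply(restraint_atom_sets(ligand, restraints$ligand),
                      function(i) colMeans(as.matrix(
                        ligand$atoms[i, c("x", "y", "z")])))
    body_cen <- centroid(ligand)
  }
  swarm$glowworms <- with_seed(seed, lapply(seq_len(n_glowworms), function(i) {
    pose <- random_pose(swarm$center, swarm$radius, n_modes)
    if (oriented) {
      r <- rec_cen[[sample.int(length(rec_cen), 1)]]
      l <- lig_cen[[sample.int(length(lig_cen), 1)]]
      v_l <- unit(l - body_cen)
      u <- unit(r - pose$translation)
      q0 <- quat_align_vectors(v_l, u)
      if (jitter_deg > 0) {
        ax <- stats::rnorm(3)
        ang <- stats::runif(1, 0, jitter_deg * pi / 180)
        q0 <- quat_multiply(quat_from_axis_angle(ax, ang), q0)
      }
      pose$rotation <- quat_normalize(q0)
    }
    list(id = i, pose = pose, luciferin = ell0,
         vision_range = 2 * swarm$radius, score = NA_real_,
         f_sat = NA_real_, J = NA_real_)
  }))
  swarm
}

#' Write and read swarm population files
#'
#' `write_swarm_state()` writes one line per glowworm: translation (3),
#' quaternion (4) and amplitudes (M) tab-separated; with
#' `include_scores = TRUE` the luciferin and raw score columns are
#' appended (the `gso_<step>.out` snapshot format).
#'
#' @param swarm a populated `Swarm`.
#' @param file output path.
#' @param include_scores append luciferin and score columns.
#' @return `file`, invisibly.
#' @export
write_swarm_state <- function(swarm, file, include_scores = FALSE) {
  rows <- vapply(swarm$glowworms, function(g) {
    v <- c(g$pose$translation, g$pose$rotation, g$pose$mode_amplitudes)
    if (include_scores) v <- c(v, g$luciferin, g$score)
    paste(sprintf("%.9g", v), collapse = "\t")
  }, character(1))
  writeLines(rows, file)
  invisible(file)
}

#' @rdname write_swarm_state
#' @param n_modes number of amplitude columns expected in `file`.
#' @export
read_swarm_state <- function(file, n_modes = 0) {
  rows <- strsplit(readLines(file), "\t", fixed = TRUE)
  lapply(seq_along(rows), function(i) {
    v <- as.numeric(rows[[i]])
    pose <- Pose(v[1:3], v[4:7],
                 if (n_modes > 0) v[7 + seq_len(n_modes)] else numeric(0))
    extra <- v[-seq_len(7 + n_modes)]
    list(id = i, pose = pose,
         luciferin = if (length(extra) >= 1) extra[1] else NA_real_,
         vision_range = NA_real_,
         score = if (length(extra) >= 2) extra[2] else NA_real_,
         f_sat = NA_real_, J = NA_real_)
  })
}
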