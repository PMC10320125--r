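#' Ligand RMSD between two posed coordinate sets
#'
#' Root-mean-square deviation over matched anchor atoms (CA for amino
#' acids, C1' for nucleotides) without superposition: all poses share the
#' receptor frame, so no fitting is wanted.
#'
#' @param coords_a,coords_b `n x 3` matrices with matched rows.
#' @return RMSD in angstrom.
#' @export
ligand_rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b))) stop_gd("coordinate count mismatch")
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Cluster the final glowworms of a swarm
#'
#' One-pass BSAS threshold clustering over anchor-atom (CA / C1') RMSD:
#' glowworms are visited by descending luciferin (ties by id ascending);
#' a glowworm founds a new cluster when its RMSD to every existing
#' cluster representative exceeds `rmsd_cutoff`, otherwise it joins the
#' nearest representative's cluster. Representatives are the founders, so
#' each cluster is represented by its brightest member.
#'
#' @param swarm a `Swarm` after [run_swarm()].
#' @param ligand the ligand [Molecule].
#' @param rmsd_cutoff angstrom (default 4).
#' @param basis optional `ModeBasis` used during the run.
#' @return integer cluster id per glowworm (in glowworm order), with the
#'   representative glowworm ids as attribute `representatives`.
#' @export
cluster_swarm <- function(swarm, ligand, rmsd_cutoff = 4, basis = NULL) {
  pop <- swarm$glowworms
  if (!length(pop)) stop_gd("swarm has no glowworms")
  anchors <- anchor_atom_indices(ligand)
  acoords <- lapply(pop, function(g)
    apply_pose(ligand, g$pose, basis)[anchors, , drop = FALSE])
  ell <- vapply(pop, `[[`, numeric(1), "luciferin")
  ids <- vapply(pop, `[[`, numeric(1), "id")
  visit <- order(-ell, ids)
  assign <- integer(length(pop))
  reps <- integer(0)
  for (k in visit) {
    if (!length(reps)) {
      reps <- k; assign[k] <- 1L; next
    }
    d <- vapply(reps, function(r) ligand_rmsd(acoords[[k]], acoords[[r]]),
                numeric(1))
    if (all(d > rmsd_cutoff)) {
      reps <- c(reps, k)
      assign[k] <- length(reps)
    } else {
      assign[k] <- which.min(d)
    }
  }
  attr(assign, "representatives") <- ids[reps]
  assign
}

#' Rank cluster representatives across swarms
#'
#' Sorts models by raw score descending (the physical score, not the
#' restraint-biased objective), breaking ties by `(swarm_id,
#' glowworm_id)` ascending, and assigns ranks `1..N`.
#'
#' @param models data frame with columns `swarm_id`, `glowworm_id`,
#'   `score`, `f_sat`, `cluster_id` and a `pose` list-column.
#' @return the same data frame ordered with a `rank` column prepended.
#' @export
rank_models <- function(models) {
  if (!nrow(models)) stop_gd("no models to rank")
  o <- order(-models$score, models$swarm_id, models$glowworm_id)
  models <- models[o, , drop = FALSE]
  models <- cbind(rank = seq_len(nrow(models)), models)
  rownames(models) <- NULL
  models
}

#' Filter ranked models by restraint satisfaction
#'
#' Keeps models whose satisfaction fraction is at least `min_fsat` and
#' re-ranks the survivors `1..K`; this guarantees the delivered models
#' agree with the declared interface data. Without restraints it is the
#' identity. Zero survivors produce a warning and an empty model table,
#' not an error.
#'
#' @param models ranked model data frame (see [rank_models()]).
#' @param restraints a `RestraintSet` or `NULL`.
#' @param min_fsat minimum satisfaction fraction (default 0.5).
#' @return filtered, re-ranked model data frame.
#' @export
filter_models_by_restraints <- function(models, restraints, min_fsat = 0.5) {
  if (!has_receptor_restraints(restraints)) return(models)
  keep <- !is.na(models$f_sat) & models$f_sat >= min_fsat
  if (!any(keep)) {
    warning("all models violate the restraints; empty report", call. = FALSE)
    out <- models[0, , drop = FALSE]
    return(out)
  }
  out <- models[keep, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write the ranking report and top models
#'
#' Writes `rank.tsv` (rank, swarm, glowworm, score, f_sat, cluster) for
#' every model and `model_<rank>.pdb` for the top `top_n` (default 5,
#' option 10), each containing the receptor and the posed ligand under
#' distinct chain ids.
#'
#' @param models ranked model data frame.
#' @param receptor,ligand [Molecule] objects.
#' @param out_dir output directory (created if needed).
#' @param top_n how many PDB models to write (default 5).
#' @param basis optional `ModeBasis`.
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(models, receptor, ligand, out_dir, top_n = 5,
                         basis = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(out_dir, "rank.tsv")
  utils::write.table(
    data.frame(rank = models$rank, swarm = models$swarm_id,
               glowworm = models$glowworm_id,
               score = round(models$score, 4),
               f_sat = round(models$f_sat, 4),
               cluster = models$cluster_id),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- tsv
  n_out <- min(top_n, nrow(models))
  if (n_out > 0) {
    lig_chains <- unique(ligand$atoms$chain)
    free <- setdiff(c(LETTERS, letters, 0:9), unique(receptor$atoms$chain))
    remap <- stats::setNames(free[seq_along(lig_chains)], lig_chains)
    for (i in seq_len(n_out)) {
      posed <- apply_pose(ligand, models$pose[[i]], basis)
      lig_out <- ligand
      lig_out$atoms$chain <- unname(remap[lig_out$atoms$chain])
      lig_out$atoms[, c("x", "y", "z")] <- posed
      combo <- lig_out
      combo$atoms <- rbind(receptor$atoms, lig_out$atoms)
      combo$atoms$serial <- seq_len(nrow(combo$atoms))
      f <- file.path(out_dir, sprintf("model_%d.pdb", models$rank[i]))
      write_pdb(combo, f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Final-relaxation hook
#'
#' Placeholder for a short energy-minimization pass on the top models to
#' clean local geometry. The plug-in contract: a function taking
#' `(models, receptor, ligand)` and returning the models (possibly with
#' updated poses and scores). The built-in default performs no relaxation
#' and returns its input unchanged.
#'
#' @param models ranked model data frame.
#' @param receptor,ligand [Molecule] objects.
#' @param relaxer plug-in function, or `NULL` for the identity.
#' @return the (possibly relaxed) models.
#' @export
relax_models <- function(models, receptor, ligand, relaxer = NULL) {
  if (is.null(relaxer)) return(models)
  relaxer(models, receptor, ligand)
}
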