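#' Scoring parameters for the default pose objective
#'
#' The default scoring function is a softcore Lennard-Jones potential plus
#' a distance-screened Coulomb term over receptor-ligand heavy-atom pairs:
#' for each pair within `cutoff`, with `r' = max(r, clash_floor)`,
#' `E = sum eps_ij ((sigma_ij / r')^12 - 2 (sigma_ij / r')^6)
#'   + k_c q_i q_j / (eps_r r')`,
#' where `sigma_ij = r_i + r_j` is the sum of element radii. The score is
#' `S = -E`, so higher is better. The clamp at `clash_floor` keeps early
#' random poses finite.
#'
#' @param vdw_epsilon LJ well depth, kcal/mol (default 0.1).
#' @param element_radii named vector of element radii, angstrom.
#' @param default_radius radius for unlisted elements, angstrom.
#' @param dielectric relative dielectric (default 15).
#' @param coulomb_constant 332.0 kcal A / (mol e^2).
#' @param cutoff pair cutoff, angstrom (default 10).
#' @param clash_floor minimum effective pair distance, angstrom (default 1).
#' @param contact_cutoff heavy-atom contact distance for restraint
#'   satisfaction, angstrom (default 5).
#' @param bias_floor floor on the satisfaction fraction used in the biased
#'   objective (default 0.01).
#' @return list of class `"ScoringParameters"`.
#' @export
scoring_parameters <- function(vdw_epsilon = 0.1,
                               element_radii = c(C = 1.9, N = 1.7, O = 1.6,
                                                 S = 2.0, P = 2.1),
                               default_radius = 1.8,
                               dielectric = 15,
                               coulomb_constant = 332.0,
                               cutoff = 10,
                               clash_floor = 1.0,
                               contact_cutoff = 5.0,
                               bias_floor = 0.01) {
  stopifnot(cutoff > clash_floor, clash_floor > 0,
            bias_floor > 0, bias_floor <= 1)
  structure(list(vdw_epsilon = vdw_epsilon, element_radii = element_radii,
                 default_radius = default_radius, dielectric = dielectric,
                 coulomb_constant = coulomb_constant, cutoff = cutoff,
                 clash_floor = clash_floor, contact_cutoff = contact_cutoff,
                 bias_floor = bias_floor),
            class = "ScoringParameters")
}

#' Assign per-atom radii and formal charges
#'
#' Radii come from the element map in the parameters. Formal charges use a
#' coarse united-charge table: Asp `OD1`/`OD2` and Glu `OE1`/`OE2` carry
#' -0.5 each, Lys `NZ` +1, Arg `NH1`/`NH2` +0.5 each, and DNA phosphate
#' `OP1`/`OP2` -0.5 each; everything else is neutral. Unknown elements get
#' the default radius and zero charge.
#'
#' @param mol a [Molecule].
#' @param params a [scoring_parameters()] list.
#' @return the molecule with `radius` and `charge` columns filled.
#' @export
assign_parameters <- function(mol, params = scoring_parameters()) {
  a <- mol$atoms
  r <- unname(params$element_radii[a$element])
  r[is.na(r)] <- params$default_radius
  a$radius <- r
  q <- numeric(nrow(a))
  q[a$resname == "ASP" & a$name %in% c("OD1", "OD2")] <- -0.5
  q[a$resname == "GLU" & a$name %in% c("OE1", "OE2")] <- -0.5
  q[a$resname == "LYS" & a$name == "NZ"] <- 1
  q[a$resname == "ARG" & a$name %in% c("NH1", "NH2")] <- 0.5
  q[a$resname %in% dna_residues() & a$name %in% c("OP1", "OP2")] <- -0.5
  a$charge <- q
  mol$atoms <- a
  mol
}

#' Score a posed ligand against the receptor
#'
#' Evaluates the default pairwise potential (see [scoring_parameters()])
#' over receptor-ligand heavy-atom pairs. Returns 0 when no pair falls
#' within the cutoff.
#'
#' @param receptor a [Molecule] with parameters assigned
#'   ([assign_parameters()]).
#' @param ligand a [Molecule] with parameters assigned.
#' @param ligand_coords optional `n x 3` posed coordinates for all ligand
#'   atoms (defaults to the ligand's stored coordinates).
#' @param params a [scoring_parameters()] list.
#' @return raw score `S` (kcal/mol, higher is better).
#' @export
score_pose <- function(receptor, ligand, ligand_coords = NULL,
                       params = scoring_parameters()) {
  lm <- heavy_mask(ligand)
  lxyz <- if (is.null(ligand_coords)) coords(ligand, heavy_only = TRUE) else
    ligand_coords[lm, , drop = FALSE]
  rm_ <- heavy_mask(receptor)
  score_core(coords(receptor, heavy_only = TRUE),
             receptor$atoms$radius[rm_], receptor$atoms$charge[rm_],
             lxyz, ligand$atoms$radius[lm], ligand$atoms$charge[lm], params)
}

score_core <- function(rxyz, rrad, rq, lxyz, lrad, lq, p) {
  d <- cross_dist(rxyz, lxyz)
  idx <- which(d <= p$cutoff)
  if (!length(idx)) return(0)
  rp <- pmax(d[idx], p$clash_floor)
  sig <- outer(rrad, lrad, "+")[idx]
  sr6 <- (sig / rp)^6
  e_lj <- p$vdw_epsilon * (sr6 * sr6 - 2 * sr6)
  e_c <- p$coulomb_constant * outer(rq, lq)[idx] / (p$dielectric * rp)
  -(sum(e_lj) + sum(e_c))
}

#' Fraction of satisfied residue restraints
#'
#' A restraint residue is satisfied when any of its heavy atoms lies
#' within `contact_cutoff` of any heavy atom of the partner molecule.
#' Receptor and ligand restraints are pooled into a single fraction.
#'
#' @inheritParams score_pose
#' @param restraints a `RestraintSet` from [parse_restraints()].
#' @return fraction in `[0, 1]`.
#' @export
satisfied_fraction <- function(receptor, ligand, restraints,
                               ligand_coords = NULL,
                               params = scoring_parameters()) {
  if (!has_receptor_restraints(restraints)) stop_gd("no restraints given")
  lm <- heavy_mask(ligand)
  lxyz_all <- if (is.null(ligand_coords)) coords(ligand) else ligand_coords
  lxyz <- lxyz_all[lm, , drop = FALSE]
  rxyz <- coords(receptor, heavy_only = TRUE)
  d_c <- params$contact_cutoff
  rec_sets <- restraint_atom_sets(receptor, restraints$receptor)
  sat <- vapply(rec_sets, function(idx) {
    min(cross_dist(as.matrix(receptor$atoms[idx, c("x", "y", "z")]), lxyz)) <= d_c
  }, logical(1))
  if (has_ligand_restraints(restraints)) {
    lig_sets <- restraint_atom_sets(ligand, restraints$ligand)
    sat <- c(sat, vapply(lig_sets, function(idx) {
      min(cross_dist(lxyz_all[idx, , drop = FALSE], rxyz)) <= d_c
    }, logical(1)))
  }
  mean(sat)
}

#' Restraint-biased objective
#'
#' When restraints are present the raw score is modulated by the
#' satisfaction fraction: `J = S * max(f_sat, bias_floor)` for positive
#' scores and `J = S / max(f_sat, bias_floor)` for non-positive ones, so
#' violating restraints always worsens the objective regardless of sign.
#' Without restraints `J = S`.
#'
#' @param S raw score.
#' @param f_sat satisfaction fraction in `[0, 1]`.
#' @param restraints_present logical.
#' @param params a [scoring_parameters()] list (supplies `bias_floor`).
#' @return objective value `J`.
#' @export
biased_objective <- function(S, f_sat, restraints_present = TRUE,
                             params = scoring_parameters()) {
  if (!restraints_present) return(S)
  f <- max(f_sat, params$bias_floor)
  if (S > 0) S * f else S / f
}

#' Build the pose objective used by the GSO engine
#'
#' Precomputes heavy-atom coordinates, radii, charges and restraint atom
#' sets, and returns a closure mapping a [Pose] to
#' `list(S, f_sat, J)`. The closure is the pluggable scoring contract:
#' any function with this signature can drive [run_swarm()].
#'
#' @inheritParams score_pose
#' @param restraints a `RestraintSet` or `NULL`.
#' @param basis optional `ModeBasis` for ligand flexibility.
#' @return function of one [Pose].
#' @export
make_objective <- function(receptor, ligand, restraints = NULL,
                           params = scoring_parameters(), basis = NULL) {
  receptor <- assign_parameters(receptor, params)
  ligand <- assign_parameters(ligand, params)
  rm_ <- heavy_mask(receptor); lm <- heavy_mask(ligand)
  rxyz <- coords(receptor, heavy_only = TRUE)
  rrad <- receptor$atoms$radius[rm_]; rq <- receptor$atoms$charge[rm_]
  lrad <- ligand$atoms$radius[lm]; lq <- ligand$atoms$charge[lm]
  restr <- has_receptor_restraints(restraints)
  rec_sets <- if (restr) restraint_atom_sets(receptor, restraints$receptor)
  rec_xyz <- if (restr) lapply(rec_sets, function(i)
    as.matrix(receptor$atoms[i, c("x", "y", "z")]))
  lig_sets <- if (restr && has_ligand_restraints(restraints))
    restraint_atom_sets(ligand, restraints$ligand)
  d_c <- params$contact_cutoff
  function(pose) {
    posed <- apply_pose(ligand, pose, basis)
    lh <- posed[lm, , drop = FALSE]
    S <- score_core(rxyz, rrad, rq, lh, lrad, lq, params)
    if (!restr) return(list(S = S, f_sat = NA_real_, J = S))
    sat <- vapply(rec_xyz, function(m) min(cross_dist(m, lh)) <= d_c, logical(1))
    if (!is.null(lig_sets))
      sat <- c(sat, vapply(lig_sets, function(i)
        min(cross_dist(posed[i, , drop = FALSE], rxyz)) <= d_c, logical(1)))
    f_sat <- mean(sat)
    list(S = S, f_sat = f_sat,
         J = biased_objective(S, f_sat, TRUE, params))
  }
}
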