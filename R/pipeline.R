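#' Supported receptor-ligand scenarios
#'
#' The nine docking scenarios, as receptor and ligand molecule kinds.
#' The membrane scenario carries the flag that disables receptor
#' flexibility, since the receptor must stay fixed relative to the
#' membrane slab.
#'
#' @return data frame with columns `mode`, `receptor_kind`,
#'   `ligand_kind`, `receptor_flexibility`.
#' @export
enumerate_modes <- function() {
  data.frame(
    mode = c("protein-protein", "protein-protein+dna", "protein-dna",
             "protein+dna-protein", "dna-protein",
             "membrane_protein-protein", "antibody-protein",
             "antibody-protein+dna", "antibody-dna"),
    receptor_kind = c("protein", "protein", "protein", "protein_dna", "dna",
                      "membrane_protein", "antibody", "antibody", "antibody"),
    ligand_kind = c("protein", "protein_dna", "dna", "protein", "protein",
                    "protein", "protein", "protein_dna", "dna"),
    receptor_flexibility = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE,
                             TRUE, TRUE),
    stringsAsFactors = FALSE)
}

#' Docking run configuration
#'
#' Collects and validates every knob of a run. A membrane-protein
#' receptor forces receptor flexibility off. The seed is mandatory:
#' there is no silent nondeterminism.
#'
#' @param mode one of `enumerate_modes()$mode`.
#' @param seed integer seed (required).
#' @param steps GSO steps (default 100).
#' @param n_swarms optional override of the dynamic swarm count.
#' @param n_glowworms population per swarm (default 200).
#' @param flex_receptor,flex_ligand enable ANM backbone flexibility.
#' @param n_modes ANM modes per flexible partner (default 10).
#' @param scoring name of the registered scoring function (default
#'   `"default"`).
#' @param top_n models written as PDB, 5 or 10.
#' @param min_fsat restraint-satisfaction threshold for final filtering.
#' @param scheme antibody numbering scheme.
#' @param keep_cutoff swarm-restraint filter cutoff, angstrom.
#' @param membrane_cushion slab cushion, angstrom.
#' @param gso a [gso_parameters()] list; its `steps` is set from `steps`.
#' @param scoring_params a [scoring_parameters()] list.
#' @return validated list of class `"RunConfig"`.
#' @export
run_config <- function(mode = "protein-protein", seed, steps = 100,
                       n_swarms = NULL, n_glowworms = 200,
                       flex_receptor = FALSE, flex_ligand = FALSE,
                       n_modes = 10, scoring = "default", top_n = 5,
                       min_fsat = 0.5, scheme = "chothia", keep_cutoff = 20,
                       membrane_cushion = 5, gso = gso_parameters(),
                       scoring_params = scoring_parameters()) {
  if (missing(seed) || is.null(seed)) stop_gd("a seed is required")
  modes <- enumerate_modes()
  if (!mode %in% modes$mode)
    stop_gd("unknown mode: ", mode, " (see enumerate_modes())")
  if (!top_n %in% c(5, 10)) stop_gd("top_n must be 5 or 10")
  if (modes$receptor_kind[modes$mode == mode] == "membrane_protein")
    flex_receptor <- FALSE
  gso$steps <- as.integer(steps)
  structure(list(mode = mode, seed = as.integer(seed), steps = as.integer(steps),
                 n_swarms = n_swarms, n_glowworms = n_glowworms,
                 flex_receptor = flex_receptor, flex_ligand = flex_ligand,
                 n_modes = n_modes, scoring = scoring, top_n = top_n,
                 min_fsat = min_fsat, scheme = scheme,
                 keep_cutoff = keep_cutoff,
                 membrane_cushion = membrane_cushion, gso = gso,
                 scoring_params = scoring_params),
            class = "RunConfig")
}

#' Set up a docking simulation
#'
#' Resolves restraints (auto-deriving CDR restraints for an antibody
#' receptor and merging them with any user restraints), generates swarms
#' over the receptor surface, applies the restraint and membrane swarm
#' filters, computes the ligand mode basis when flexibility is on, and
#' initializes every swarm's glowworm population. With `out_dir` set,
#' writes `init/swarm_<i>.txt` population files and a `run_config.json`
#' echo.
#'
#' @param receptor,ligand [Molecule] objects.
#' @param config a [run_config()].
#' @param restraints a `RestraintSet` or `NULL`.
#' @param membrane a `MembraneModel` or `NULL` (required for the
#'   membrane mode).
#' @param out_dir optional run directory.
#' @return list of class `"DockingSetup"`: `receptor`, `ligand`,
#'   `swarms`, `restraints`, `membrane`, `basis`, `config`.
#' @export
setup_docking <- function(receptor, ligand, config, restraints = NULL,
                          membrane = NULL, out_dir = NULL) {
  if (receptor$kind == "antibody") {
    cdr <- detect_cdr_restraints(receptor, config$scheme)
    if (has_receptor_restraints(restraints)) {
      merged <- rbind(cdr$receptor, restraints$receptor)
      cdr$receptor <- merged[!duplicated(merged), , drop = FALSE]
      cdr$ligand <- restraints$ligand
    }
    restraints <- cdr
  }
  if (receptor$kind == "membrane_protein" && is.null(membrane))
    membrane <- parse_membrane_beads(receptor)
  # the n_swarms override counts swarms that actually run, so the
  # restraint/membrane filters apply before any subsampling
  swarms <- generate_swarms(receptor,
                            n_swarms = if (!has_receptor_restraints(restraints) &&
                                           is.null(membrane)) config$n_swarms)
  if (has_receptor_restraints(restraints))
    swarms <- filter_swarms_by_restraints(swarms, receptor, restraints,
                                          config$keep_cutoff)
  if (!is.null(membrane))
    swarms <- filter_swarms_by_membrane(swarms, membrane,
                                        config$membrane_cushion)
  if (!is.null(config$n_swarms) &&
      (has_receptor_restraints(restraints) || !is.null(membrane)) &&
      length(swarms) > config$n_swarms) {
    pick <- unique(round(seq(1, length(swarms), length.out = config$n_swarms)))
    swarms <- swarms[pick]
  }
  basis <- NULL
  if (config$flex_ligand)
    basis <- compute_anm_basis(ligand, n_modes = config$n_modes)
  n_modes <- if (is.null(basis)) 0 else length(basis$modes)
  swarms <- lapply(swarms, function(s)
    init_glowworms(s, ligand, n_glowworms = config$n_glowworms,
                   restraints = restraints, receptor = receptor,
                   n_modes = n_modes, seed = config$seed + s$id,
                   ell0 = config$gso$ell0))
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "init"), showWarnings = FALSE,
               recursive = TRUE)
    for (s in swarms)
      write_swarm_state(s, file.path(out_dir, "init",
                                     sprintf("swarm_%d.txt", s$id)))
    jsonlite::write_json(config_json(config),
                         file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(receptor = receptor, ligand = ligand, swarms = swarms,
                 restraints = restraints, membrane = membrane,
                 basis = basis, config = config),
            class = "DockingSetup")
}

config_json <- function(config) {
  out <- unclass(config)
  out$gso <- unclass(out$gso)
  out$scoring_params <- as.list(unclass(out$scoring_params))
  out
}

#' Run the GSO simulation of a docking setup
#'
#' Optimizes every swarm independently with [run_swarm()] under the
#' configured objective (restraint-biased whenever restraints exist).
#'
#' @param setup a `DockingSetup` from [setup_docking()].
#' @param out_dir optional run directory for `gso_<step>.out` snapshots.
#' @param save_every snapshot interval (`NULL`: final state only).
#' @param verbose log one line per swarm.
#' @return the setup with optimized swarms and a `traces` element
#'   (per-swarm best-score traces).
#' @export
run_docking <- function(setup, out_dir = NULL, save_every = NULL,
                        verbose = FALSE) {
  objective <- make_objective(setup$receptor, setup$ligand, setup$restraints,
                              setup$config$scoring_params, setup$basis)
  swarms <- vector("list", length(setup$swarms))
  traces <- vector("list", length(setup$swarms))
  for (k in seq_along(setup$swarms)) {
    s <- setup$swarms[[k]]
    sdir <- if (!is.null(out_dir)) {
      d <- file.path(out_dir, sprintf("swarm_%d", s$id))
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      d
    }
    s <- run_swarm(s, objective, setup$config$gso, seed = setup$config$seed,
                   save_every = save_every %||%
                     (if (!is.null(out_dir)) setup$config$gso$steps),
                   out_dir = sdir)
    if (verbose)
      message(sprintf("swarm %d: best score %.3f", s$id,
                      max(attr(s, "trace"))))
    traces[[k]] <- attr(s, "trace")
    swarms[[k]] <- s
  }
  setup$swarms <- swarms
  setup$traces <- traces
  setup
}

#' Cluster, rank, filter and report the final models
#'
#' Clusters each swarm's final population ([cluster_swarm()]), takes the
#' cluster representatives, ranks them globally by raw score
#' ([rank_models()]), filters by restraint satisfaction
#' ([filter_models_by_restraints()]), and optionally writes the report
#' and top-model PDBs ([write_report()]).
#'
#' @param setup an optimized `DockingSetup` from [run_docking()].
#' @param out_dir optional run directory.
#' @param rmsd_cutoff clustering cutoff, angstrom (default 4).
#' @return ranked (filtered) model data frame.
#' @export
rank_docking <- function(setup, out_dir = NULL, rmsd_cutoff = 4) {
  rows <- list()
  for (s in setup$swarms) {
    cl <- cluster_swarm(s, setup$ligand, rmsd_cutoff, setup$basis)
    reps <- attr(cl, "representatives")
    ids <- vapply(s$glowworms, `[[`, numeric(1), "id")
    for (j in seq_along(reps)) {
      g <- s$glowworms[[which(ids == reps[j])]]
      rows[[length(rows) + 1]] <- data.frame(
        swarm_id = s$id, glowworm_id = g$id, score = g$score,
        f_sat = g$f_sat, cluster_id = j, stringsAsFactors = FALSE)
      rows[[length(rows)]]$pose <- I(list(g$pose))
    }
  }
  models <- do.call(rbind, rows)
  models <- rank_models(models)
  models <- filter_models_by_restraints(models, setup$restraints,
                                        setup$config$min_fsat)
  if (!is.null(out_dir) && nrow(models))
    write_report(models, setup$receptor, setup$ligand, out_dir,
                 top_n = setup$config$top_n, basis = setup$basis)
  models
}

#' One-call docking pipeline
#'
#' `setup_docking()` + `run_docking()` + `rank_docking()`.
#'
#' @inheritParams setup_docking
#' @param out_dir optional run directory for all outputs.
#' @param verbose log progress.
#' @return list with `models` (ranked data frame) and `setup` (the
#'   optimized `DockingSetup`).
#' @export
dock <- function(receptor, ligand, config, restraints = NULL,
                 membrane = NULL, out_dir = NULL, verbose = FALSE) {
  setup <- setup_docking(receptor, ligand, config, restraints, membrane,
                         out_dir)
  setup <- run_docking(setup, out_dir = out_dir, verbose = verbose)
  models <- rank_docking(setup, out_dir = out_dir)
  list(models = models, setup = setup)
}
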