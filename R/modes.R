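#' CDR loop windows for a numbering scheme
#'
#' Residue-number windows of the six hypervariable loops (H1-H3, L1-L3)
#' under the Chothia, Kabat or IMGT numbering scheme. The tables ship as
#' a data file (`extdata/cdr_windows.csv`) so corrections do not require
#' code changes. Insertion-coded residues whose number falls inside a
#' window are part of the loop.
#'
#' @param scheme `"chothia"`, `"kabat"` or `"imgt"`.
#' @return data frame with columns `scheme`, `chain`, `loop`, `start`,
#'   `end`.
#' @export
cdr_windows <- function(scheme = c("chothia", "kabat", "imgt")) {
  scheme <- match.arg(scheme)
  tab <- utils::read.csv(system.file("extdata", "cdr_windows.csv",
                                     package = "glowdock"),
                         stringsAsFactors = FALSE)
  tab[tab$scheme == scheme, , drop = FALSE]
}

#' Derive residue restraints from antibody CDR loops
#'
#' For an antibody already numbered under a recognized scheme (chain ids
#' must be `H` and `L` for the heavy and light chains), returns every
#' residue present in the structure whose (chain, number) falls inside
#' one of the six CDR windows, as receptor-side restraints. These drive
#' the standard restraint machinery: swarm filtering around the paratope
#' when the antibody is the receptor, and pose orientation when it is the
#' ligand.
#'
#' @param antibody a [Molecule] with chains `H` and `L`.
#' @param scheme numbering scheme, see [cdr_windows()].
#' @return a `RestraintSet` with receptor restraints only.
#' @export
detect_cdr_restraints <- function(antibody, scheme = c("chothia", "kabat", "imgt")) {
  scheme <- match.arg(scheme)
  chains <- unique(antibody$atoms$chain)
  if (!all(c("H", "L") %in% chains))
    stop_gd("antibody must have chains H and L")
  win <- cdr_windows(scheme)
  a <- antibody$atoms
  res <- unique(a[, c("chain", "resno", "icode")])
  keep <- vapply(seq_len(nrow(res)), function(i) {
    w <- win[win$chain == res$chain[i], , drop = FALSE]
    any(res$resno[i] >= w$start & res$resno[i] <= w$end)
  }, logical(1))
  res <- res[keep, , drop = FALSE]
  if (!nrow(res)) stop_gd("numbering scheme mismatch: no CDR residues found")
  res <- res[order(match(res$chain, c("H", "L")), res$resno, res$icode), ]
  structure(list(receptor = residue_ref_df(res$chain, res$resno, res$icode),
                 ligand = residue_ref_df()),
            class = "RestraintSet")
}

#' Parse coarse-grained membrane beads from a structure
#'
#' Collects atoms with residue name `MMB` and atom name `BJ` (renamed
#' MARTINI PO4 phosphate beads marking the lipid headgroup planes) and
#' derives the membrane slab from their z extrema. Non-bead atoms are
#' ignored, so the receptor PDB with beads appended parses directly.
#'
#' @param mol a [Molecule].
#' @return a `MembraneModel`: list with `beads` (`n x 3` matrix), `z_min`
#'   and `z_max`.
#' @export
parse_membrane_beads <- function(mol) {
  sel <- mol$atoms$resname == "MMB" & mol$atoms$name == "BJ"
  if (!any(sel)) stop_gd("no membrane beads found")
  beads <- as.matrix(mol$atoms[sel, c("x", "y", "z")])
  rownames(beads) <- NULL
  structure(list(beads = beads, z_min = min(beads[, 3]),
                 z_max = max(beads[, 3])),
            class = "MembraneModel")
}

#' Build an approximate explicit membrane around a receptor
#'
#' Given an anchor residue on a receptor already oriented with the
#' membrane normal along z, lays a single planar square grid of beads at
#' the anchor CA's z coordinate, spanning the receptor's xy bounding box
#' expanded by `margin`, and removes beads within `clash_distance` of any
#' receptor heavy atom. Beads are emitted as `MMB`/`BJ` `HETATM` records
#' in a dedicated chain, appendable to the receptor file.
#'
#' @param receptor a [Molecule].
#' @param anchor a residue reference: either a `"<chain>.<number>"` string
#'   or a one-row data frame (`chain`, `resno`, `icode`).
#' @param spacing grid spacing, angstrom (default 5).
#' @param margin bounding-box expansion, angstrom (default 20).
#' @param clash_distance bead-receptor exclusion distance, angstrom
#'   (default 3).
#' @param chain chain id for the emitted beads (default `"M"`).
#' @return list with `membrane` (a `MembraneModel`) and `beads` (a
#'   [Molecule] of the bead layer).
#' @export
build_membrane <- function(receptor, anchor, spacing = 5, margin = 20,
                           clash_distance = 3, chain = "M") {
  if (is.character(anchor)) anchor <- parse_residue_refs(anchor)
  if (!nrow(anchor)) stop_gd("unknown anchor residue")
  a <- receptor$atoms
  sel <- a$chain == anchor$chain[1] & a$resno == anchor$resno[1] &
    a$icode == anchor$icode[1]
  ca <- which(sel & a$name == "CA")
  if (!length(ca)) {
    if (!any(sel)) stop_gd("unknown anchor residue ",
                           format_residue_ref(anchor[1, ]))
    ca <- which(sel)[1]
  }
  z0 <- a$z[ca[1]]
  xyz <- coords(receptor, heavy_only = TRUE)
  xs <- seq(min(xyz[, 1]) - margin, max(xyz[, 1]) + margin, by = spacing)
  ys <- seq(min(xyz[, 2]) - margin, max(xyz[, 2]) + margin, by = spacing)
  grid <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)), z0)
  keep <- apply(cross_dist(grid, xyz), 1, min) >= clash_distance
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) stop_gd("membrane eliminates all beads")
  beads <- Molecule(data.frame(
    serial = seq_len(nrow(grid)), name = "BJ", element = "C",
    resname = "MMB", resno = seq_len(nrow(grid)), icode = "",
    chain = chain, x = grid[, 1], y = grid[, 2], z = grid[, 3],
    hetatm = TRUE, stringsAsFactors = FALSE),
    kind = "membrane_beads", label = "membrane")
  list(membrane = structure(list(beads = grid, z_min = z0, z_max = z0),
                            class = "MembraneModel"),
       beads = beads)
}
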