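#' Molecule objects
#'
#' A `Molecule` is an ordered atomic structure: a data frame of atoms
#' (one row per atom, order preserved from input) plus a detected or
#' user-assigned molecule kind and a free-text label. Atom columns:
#' `serial`, `name`, `element`, `resname`, `resno`, `icode`, `chain`,
#' `x`, `y`, `z` (angstrom), `charge` (elementary charges), `radius`
#' (angstrom), `mass` (Da), `hetatm` (logical).
#'
#' @param atoms data frame with at least `serial`, `name`, `resname`,
#'   `resno`, `chain`, `x`, `y`, `z`; `element`, `icode`, `hetatm` are
#'   filled in when missing.
#' @param kind molecule kind, one of [molecule_kinds()], or `NA` to
#'   auto-detect with [detect_molecule_kind()].
#' @param label free-text label for reports.
#' @return an object of class `"Molecule"`.
#' @export
Molecule <- function(atoms, kind = NA_character_, label = "molecule") {
  if (!is.data.frame(atoms) || nrow(atoms) == 0) stop_gd("no atoms")
  atoms$name <- trimws(as.character(atoms$name))
  atoms$resname <- trimws(as.character(atoms$resname))
  atoms$chain <- as.character(atoms$chain)
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  if (is.null(atoms$hetatm)) atoms$hetatm <- FALSE
  if (is.null(atoms$element) || anyNA(atoms$element) || any(!nzchar(atoms$element))) {
    miss <- if (is.null(atoms$element)) rep(TRUE, nrow(atoms)) else
      (is.na(atoms$element) | !nzchar(atoms$element))
    if (is.null(atoms$element)) atoms$element <- NA_character_
    atoms$element[miss] <- infer_element(atoms$name[miss])
  }
  atoms$element <- toupper(trimws(atoms$element))
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms$charge[is.na(atoms$charge)] <- 0
  atoms$mass <- element_property(atoms$element, "mass")
  atoms$radius <- element_property(atoms$element, "radius")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop_gd("malformed record: non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$name, sep = "|")
  if (anyDuplicated(key)) stop_gd("duplicate atom identity (chain, residue, name)")
  mol <- structure(list(atoms = atoms, kind = kind, label = label),
                   class = "Molecule")
  if (is.na(kind)) mol$kind <- detect_molecule_kind(mol)
  else if (!kind %in% molecule_kinds()) stop_gd("unknown molecule type: ", kind)
  mol
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("Molecule '%s' (%s): %d atoms, %d residues, chains %s\n",
              x$label, x$kind, nrow(x$atoms), n_residues(x),
              paste(unique(x$atoms$chain), collapse = "")))
  invisible(x)
}

#' @rdname Molecule
#' @export
molecule_kinds <- function() {
  c("protein", "dna", "protein_dna", "peptide", "antibody",
    "membrane_protein", "membrane_beads")
}

standard_aa <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

dna_residues <- function() c("DA", "DC", "DG", "DT")

# Element inference from the atom name when the PDB element column is blank:
# strip leading digits/primes, take the leading letter; two-letter metals are
# not expected in these inputs so a one-letter read is sufficient.
infer_element <- function(name) {
  vapply(name, function(nm) {
    nm <- gsub("^[0-9']+", "", trimws(nm))
    if (!nzchar(nm)) return("C")
    toupper(substr(nm, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

element_property <- function(element, what = c("mass", "radius")) {
  what <- match.arg(what)
  tab <- list(
    mass = c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
             P = 30.974),
    radius = c(H = 1.1, C = 1.9, N = 1.7, O = 1.6, S = 2.0, P = 2.1))[[what]]
  default <- if (what == "mass") 12.011 else 1.8
  out <- unname(tab[element])
  out[is.na(out)] <- default
  out
}

#' Atom coordinates as a matrix
#' @param mol a [Molecule].
#' @param heavy_only drop hydrogens/deuteriums.
#' @return `n x 3` numeric matrix.
#' @export
coords <- function(mol, heavy_only = FALSE) {
  a <- mol$atoms
  if (heavy_only) a <- a[heavy_mask(mol), , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

heavy_mask <- function(mol) !(mol$atoms$element %in% c("H", "D"))

#' @rdname coords
#' @export
centroid <- function(mol, heavy_only = TRUE) colMeans(coords(mol, heavy_only))

residue_keys <- function(atoms) paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")

n_residues <- function(mol) length(unique(residue_keys(mol$atoms)))

# Indices of anchor atoms, one per residue in order of first appearance:
# CA for amino acids, C1' for nucleotides, first atom otherwise.
anchor_atom_indices <- function(mol) {
  a <- mol$atoms
  keys <- residue_keys(a)
  ures <- unique(keys)
  vapply(ures, function(k) {
    idx <- which(keys == k)
    hit <- idx[a$name[idx] == "CA"]
    if (!length(hit)) hit <- idx[a$name[idx] %in% c("C1'", "C1*")]
    if (!length(hit)) hit <- idx[1]
    hit[1]
  }, integer(1), USE.NAMES = FALSE)
}

#' Detect the kind of a molecule from its residue content
#'
#' Pure nucleotide content (PDB v3 names `DA`/`DC`/`DG`/`DT`) is `dna`;
#' pure standard amino-acid content is `protein`, downgraded to `peptide`
#' for a single chain of at most 30 residues; a mixture of both is
#' `protein_dna`; pure `MMB` bead content is `membrane_beads`; amino acids
#' accompanied by `MMB` beads are a `membrane_protein`. A user-supplied
#' kind (the `kind` argument of [Molecule()] or [read_pdb()]) always
#' overrides this detection. Single-letter legacy nucleotide names
#' (`A`/`C`/`G`/`T`) are not recognized.
#'
#' @param mol a [Molecule].
#' @return one of [molecule_kinds()].
#' @export
detect_molecule_kind <- function(mol) {
  res <- unique(mol$atoms$resname)
  is_aa <- res %in% standard_aa()
  is_dna <- res %in% dna_residues()
  is_bead <- res == "MMB"
  if (any(!(is_aa | is_dna | is_bead)) || length(res) == 0)
    stop_gd("unknown molecule type: unrecognized residue name(s) ",
            paste(utils::head(res[!(is_aa | is_dna | is_bead)], 5), collapse = ", "))
  has_aa <- any(is_aa); has_dna <- any(is_dna); has_bead <- any(is_bead)
  if (has_bead && !has_aa && !has_dna) return("membrane_beads")
  if (has_aa && has_bead && !has_dna) return("membrane_protein")
  if (has_aa && has_dna) return("protein_dna")
  if (has_dna) return("dna")
  # pure amino acid
  prot <- mol$atoms[mol$atoms$resname %in% standard_aa(), , drop = FALSE]
  nres <- length(unique(residue_keys(prot)))
  if (nres <= 30 && length(unique(prot$chain)) == 1) "peptide" else "protein"
}
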