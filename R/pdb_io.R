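#' Read a structure from a PDB file
#'
#' Parses fixed-column `ATOM`/`HETATM` records (via bio3d) with the
#' conventions used throughout the docking protocol:
#' * only the first `MODEL` of a multi-model file is read;
#' * alternate locations: only blank or `A` altloc records are kept;
#' * `HETATM` records are dropped unless the residue name is `MMB`
#'   (coarse-grained membrane beads, atom name `BJ`);
#' * the element is taken from columns 77-78 when present, otherwise
#'   inferred from the atom name;
#' * hydrogens are parsed and kept, but excluded from scoring and
#'   contact checks downstream.
#'
#' @param source path to a PDB file, or a character vector of PDB lines.
#' @param kind optional molecule kind overriding auto-detection
#'   (see [detect_molecule_kind()]).
#' @param label label stored on the returned molecule; defaults to the
#'   file name.
#' @return a [Molecule].
#' @export
read_pdb <- function(source, kind = NA_character_, label = NULL) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    label <- label %||% basename(source)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
    label <- label %||% "molecule"
  }
  # first-model rule
  mstart <- grep("^MODEL", lines)
  if (length(mstart)) {
    mend <- grep("^ENDMDL", lines)
    mend <- if (length(mend)) mend[1] else length(lines) + 1L
    inside <- seq_along(lines) > mstart[1] & seq_along(lines) < mend
    is_rec <- grepl("^(ATOM  |HETATM)", lines)
    keep <- !is_rec | inside
    lines_idx <- which(keep)
    lines <- lines[keep]
  } else {
    lines_idx <- seq_along(lines)
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop_gd("no atoms")
  # validate coordinate fields up front so errors carry a line number
  for (i in which(rec)) {
    fields <- c(substr(lines[i], 31, 38), substr(lines[i], 39, 46),
                substr(lines[i], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(fields))))
      stop_gd("malformed record at line ", lines_idx[i])
  }
  # altloc rule (column 17) and HETATM rule
  alt <- substr(lines, 17, 17)
  resname <- trimws(substr(lines, 18, 20))
  drop <- rec & !(alt %in% c(" ", "A", "")) |
    (grepl("^HETATM", lines) & resname != "MMB")
  lines <- lines[!drop]
  if (!any(grepl("^(ATOM  |HETATM)", lines))) stop_gd("no atoms")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  invisible(utils::capture.output(
    p <- suppressWarnings(bio3d::read.pdb(tf, multi = FALSE,
                                          verbose = FALSE))))
  a <- p$atom
  atoms <- data.frame(
    serial = a$eleno,
    name = a$elety,
    element = ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)), NA_character_,
                     toupper(trimws(a$elesy))),
    resname = a$resid,
    resno = a$resno,
    icode = ifelse(is.na(a$insert), "", a$insert),
    chain = ifelse(is.na(a$chain), " ", a$chain),
    x = a$x, y = a$y, z = a$z,
    hetatm = a$type == "HETATM",
    stringsAsFactors = FALSE)
  Molecule(atoms, kind = kind, label = label)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column `ATOM`/`HETATM` records; [read_pdb()] on the output
#' recovers chain, residue number, insertion code, atom name and
#' coordinates rounded to 3 decimals. Membrane beads round-trip as
#' `HETATM` records with residue `MMB` and atom name `BJ`.
#'
#' @param mol a [Molecule].
#' @param file output path.
#' @param coordinates optional `n x 3` matrix replacing the stored
#'   coordinates (used to write posed ligands).
#' @return `file`, invisibly.
#' @export
write_pdb <- function(mol, file, coordinates = NULL) {
  if (!inherits(mol, "Molecule") || nrow(mol$atoms) == 0) stop_gd("no atoms")
  a <- mol$atoms
  xyz <- if (is.null(coordinates)) as.matrix(a[, c("x", "y", "z")]) else {
    stopifnot(nrow(coordinates) == nrow(a))
    coordinates
  }
  if (any(abs(xyz) >= 10000)) stop_gd("unrepresentable coordinate (|v| >= 10000 A)")
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(xyz)),
                   type = ifelse(a$hetatm, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name,
                   resid = a$resname, chain = ifelse(a$chain == " ", "", a$chain),
                   resno = a$resno, insert = a$icode,
                   elesy = a$element)
  invisible(file)
}
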