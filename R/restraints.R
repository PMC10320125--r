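#' Residue restraints and membrane topology annotations
#'
#' Interface information enters the protocol as residue restraints written
#' `<chain>.<residue number>`, e.g. `A.411`, with an optional insertion-code
#' suffix (`A.52A`). Restraints may be given for the receptor only, or for
#' both partners; ligand-only restraints are rejected because they cannot
#' focus the sampling (swap the molecules instead).
#'
#' @name restraints
NULL

residue_ref_df <- function(chain = character(), resno = integer(),
                           icode = character()) {
  data.frame(chain = as.character(chain), resno = as.integer(resno),
             icode = as.character(icode), stringsAsFactors = FALSE)
}

format_residue_ref <- function(ref) {
  paste0(ref$chain, ".", ref$resno, ref$icode)
}

parse_residue_refs <- function(text) {
  tokens <- unlist(strsplit(text, "[,[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return(residue_ref_df())
  m <- regmatches(tokens, regexec("^([A-Za-z0-9])\\.([0-9]+)([A-Za-z]?)$", tokens))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop_gd("malformed restraint: ", tokens[bad][1])
  out <- residue_ref_df(
    chain = vapply(m, `[`, character(1), 2),
    resno = as.integer(vapply(m, `[`, character(1), 3)),
    icode = vapply(m, `[`, character(1), 4))
  out[!duplicated(out), , drop = FALSE]
}

#' Parse receptor and ligand restraint lists
#'
#' @param receptor_text,ligand_text whitespace- or comma-separated
#'   `<chain>.<number>` tokens (may be empty strings).
#' @return a `RestraintSet`: list with data frames `receptor` and `ligand`
#'   (columns `chain`, `resno`, `icode`), duplicates removed preserving
#'   order.
#' @examples
#' parse_restraints("A.411 A.466", "")
#' @export
parse_restraints <- function(receptor_text = "", ligand_text = "") {
  rec <- parse_residue_refs(receptor_text)
  lig <- parse_residue_refs(ligand_text)
  if (nrow(lig) > 0 && nrow(rec) == 0)
    stop_gd("ligand-only restraints not allowed")
  structure(list(receptor = rec, ligand = lig), class = "RestraintSet")
}

has_receptor_restraints <- function(r) {
  !is.null(r) && nrow(r$receptor) > 0
}

has_ligand_restraints <- function(r) {
  !is.null(r) && nrow(r$ligand) > 0
}

# Heavy-atom row indices in mol$atoms for one residue reference; errors if
# the residue is absent.
restraint_atom_indices <- function(mol, ref) {
  a <- mol$atoms
  idx <- which(a$chain == ref$chain & a$resno == ref$resno &
                 a$icode == ref$icode & heavy_mask(mol))
  if (!length(idx))
    stop_gd("unknown restraint residue ", format_residue_ref(ref))
  idx
}

# List of heavy-atom index vectors, one per restraint residue.
restraint_atom_sets <- function(mol, refs) {
  lapply(seq_len(nrow(refs)), function(i)
    restraint_atom_indices(mol, refs[i, , drop = FALSE]))
}

#' Parse a membrane topology annotation
#'
#' One segment per line, `<kind> <start>-<end>`, where kind is
#' `transmembrane`, `cytoplasmic` or `extracellular` and the range is in
#' residue numbers (hyphen or en-dash accepted). Segments must be
#' internally ordered (`start <= end`) and pairwise non-overlapping.
#'
#' @param text annotation text (lines separated by newlines) or a
#'   character vector of lines.
#' @return a data frame with columns `kind`, `start`, `end`, class
#'   `"TopologyAnnotation"`.
#' @export
parse_topology <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kinds <- c("transmembrane", "cytoplasmic", "extracellular")
  segs <- lapply(lines, function(ln) {
    m <- regexec("^([A-Za-z]+)[[:space:]]+([0-9]+)[-–]([0-9]+)$", ln)
    g <- regmatches(ln, m)[[1]]
    if (!length(g)) stop_gd("malformed topology line: ", ln)
    kind <- tolower(g[2])
    if (!kind %in% kinds) stop_gd("unknown segment kind: ", g[2])
    start <- as.integer(g[3]); end <- as.integer(g[4])
    if (start > end) stop_gd("inconsistent topology: start > end in ", ln)
    data.frame(kind = kind, start = start, end = end, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- data.frame(kind = character(), start = integer(),
                                      end = integer())
  if (nrow(out) > 1) {
    o <- order(out$start)
    s <- out[o, ]
    if (any(s$start[-1] <= s$end[-nrow(s)]))
      stop_gd("inconsistent topology: overlapping segments")
  }
  class(out) <- c("TopologyAnnotation", "data.frame")
  out
}
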