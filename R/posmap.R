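#' Bundled bovine rhodopsin reference
#'
#' Returns the bovine rhodopsin protein sequence bundled with the package
#' (UniProt P02699, 348 residues), the community standard anchor for opsin
#' residue numbering ("bovine rhodopsin numbering"). The reference is
#' deliberately swappable: any single protein sequence can be passed to
#' [map_to_reference()] in its place.
#'
#' @return A single named character string (the protein sequence).
#' @export
bovine_rhodopsin <- function() {
  path <- system.file("extdata", "bovine_rhodopsin.fasta", package = "opsinevol")
  read_fasta(path)[1]
}

#' Map query residues to reference numbering
#'
#' Globally aligns an amino-acid query to a reference protein (by default the
#' bundled bovine rhodopsin) with a BLOSUM62 scoring scheme and affine gap
#' penalties, and returns the partial monotone map between query residue
#' positions and reference residue numbers (1-based). Columns opposite a gap
#' in either sequence are unmapped.
#'
#' @param aa_seq Query amino-acid string. `*` and `?` are treated as `X`
#'   for alignment purposes; a trailing stop is dropped.
#' @param reference Reference amino-acid string (default [bovine_rhodopsin()]).
#' @param min_identity Identity floor (identical aligned pairs as a fraction
#'   of the shorter sequence's length, default 0.15). Below the floor a
#'   warning is issued and an empty map returned, because numbering
#'   transferred through a non-homologous alignment would be meaningless.
#' @param gap_opening,gap_extension Affine gap penalties passed to
#'   [Biostrings::pairwiseAlignment()].
#' @return An object of class `"position_map"`: a data.frame with columns
#'   `query_pos` and `ref_pos`, both strictly increasing.
#' @export
map_to_reference <- function(aa_seq, reference = bovine_rhodopsin(),
                             min_identity = 0.15,
                             gap_opening = 10, gap_extension = 0.5) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1L, nzchar(aa_seq),
            is.character(reference), length(reference) == 1L, nzchar(reference))
  q <- toupper(aa_seq)
  q <- sub("\\*$", "", q)                  # trailing stop is not a residue
  q_aln <- chartr("*?", "XX", q)
  q_aln <- gsub("[^A-Z]", "X", q_aln)
  r <- toupper(reference)
  if (!nzchar(q_aln)) stop("query is empty after removing the terminal stop")

  mat <- blosum62_x()
  pa <- Biostrings::pairwiseAlignment(
    pattern = q_aln, subject = r, type = "global",
    substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ap != "-" & as != "-"
  if (!any(both)) {
    warning("alignment to reference has no aligned columns; empty position map")
    return(empty_position_map())
  }
  # identity relative to the shorter sequence, so sparse gappy alignments of
  # non-homologous queries cannot masquerade as high-identity matches
  ident <- sum(ap[both] == as[both]) / min(nchar(q_aln), nchar(r))
  if (ident < min_identity) {
    warning(sprintf(
      "alignment identity %.1f%% below floor %.1f%%; empty position map",
      100 * ident, 100 * min_identity))
    return(empty_position_map())
  }
  qpos <- cumsum(ap != "-")
  rpos <- cumsum(as != "-")
  out <- data.frame(query_pos = qpos[both], ref_pos = rpos[both])
  structure(out, class = c("position_map", "data.frame"),
            identity = ident)
}

empty_position_map <- function() {
  structure(data.frame(query_pos = integer(), ref_pos = integer()),
            class = c("position_map", "data.frame"), identity = NA_real_)
}

# BLOSUM62 extended so X/* rows exist for any residue letter we may emit.
blosum62_x <- function() {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  data_env$BLOSUM62
}

#' @export
print.position_map <- function(x, ...) {
  cat("Position map:", nrow(x), "aligned residues")
  if (!is.na(attr(x, "identity")))
    cat(sprintf(" (identity %.1f%%)", 100 * attr(x, "identity")))
  cat("\n")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Look up query positions for reference residue numbers
#'
#' @param posmap A [map_to_reference()] result.
#' @param ref_positions Integer vector of reference residue numbers.
#' @return Integer vector of query positions (`NA` where unmapped).
#' @export
ref_to_query <- function(posmap, ref_positions) {
  idx <- match(ref_positions, posmap$ref_pos)
  posmap$query_pos[idx]
}
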