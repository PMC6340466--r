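#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' collection invariants used throughout the package: unique identifiers and
#' non-empty sequences. Sequences are returned in file order as a named
#' character vector; case is preserved unless `to_upper = TRUE`.
#'
#' @param path Path to a FASTA file.
#' @param to_upper Convert sequences to upper case (default `FALSE`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, to_upper = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(set))  # id = first whitespace-delimited token
  seqs <- as.character(set)
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop("duplicated sequence id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence(s) in '", path, "': ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  if (to_upper) seqs[] <- toupper(seqs)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Guess whether a sequence is nucleotide or amino acid
#'
#' @param seq A sequence string.
#' @return `"nt"` or `"aa"`.
#' @export
guess_moltype <- function(seq) {
  chars <- setdiff(unique(strsplit(toupper(seq), "")[[1]]), c("-", ".", "?", "*"))
  nt_alpha <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
  if (length(chars) && all(chars %in% nt_alpha)) "nt" else "aa"
}

#' Codon alignment container
#'
#' Bundles an aligned set of coding nucleotide sequences with its codon-column
#' structure and genetic code. All rows must have equal length; by default the
#' length must be divisible by 3 (codon column `c` spans nucleotide columns
#' `3c-2 .. 3c`, 1-based). Frame-shifting insertions produced by
#' [inject_lesions()] can break the divisibility; such alignments are accepted
#' with `frame_strict = FALSE` and codon columns are then interpreted relative
#' to the reference reading frame.
#'
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @param code A [genetic_code()].
#' @param gap_char Gap character (default `"-"`).
#' @param frame_strict Require total length divisible by 3 (default `TRUE`).
#' @return An object of class `"codon_alignment"`.
#' @export
codon_alignment <- function(seqs, code = genetic_code(), gap_char = "-",
                            frame_strict = TRUE) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs)))
    stop("duplicated taxon id(s): ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  len <- unique(nchar(seqs))
  if (length(len) != 1L)
    stop("alignment rows differ in length (", paste(len, collapse = ", "), ")")
  if (frame_strict && len %% 3L != 0L)
    stop("alignment length ", len, " is not divisible by 3")
  structure(list(
    seqs = seqs,
    n_codon = len %/% 3L,
    length = len,
    code = code,
    gap_char = gap_char
  ), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment:", length(x$seqs), "sequences x", x$n_codon,
      "codon columns (", x$length, "nt )\n")
  invisible(x)
}

#' @export
as.matrix.codon_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(toupper(x$seqs), ""))
  rownames(m) <- names(x$seqs)
  m
}

#' Extract codon strings from a codon alignment
#'
#' @param aln A [codon_alignment()].
#' @return Character matrix, taxa in rows, codon columns in columns.
#' @export
codon_matrix <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$length %% 3L != 0L)
    stop("alignment length not divisible by 3; cannot form codon columns")
  starts <- seq.int(1L, aln$length, by = 3L)
  rows <- lapply(toupper(aln$seqs), function(s)
    substring(s, starts, starts + 2L))
  m <- matrix(unlist(rows, use.names = FALSE), nrow = length(rows),
              ncol = aln$n_codon, byrow = TRUE)
  rownames(m) <- names(aln$seqs)
  m
}

#' Read a phylogenetic tree from a newick file
#'
#' Wrapper around [ape::read.tree()] that validates the invariants required
#' downstream: unique tip labels, non-negative branch lengths, a single root.
#'
#' @param path Path to a newick file (or a newick string via `text`).
#' @param text Optional newick string, used instead of `path`.
#' @param require_lengths Require branch lengths to be present (default `TRUE`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL, require_lengths = TRUE) {
  tree <- if (is.null(text)) {
    if (!file.exists(path)) stop("newick file not found: ", path)
    ape::read.tree(path)
  } else ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse error (unbalanced parentheses?)")
  validate_tree(tree, require_lengths = require_lengths)
  tree
}

validate_tree <- function(tree, require_lengths = TRUE) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  if (require_lengths && is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch length(s) in tree")
  invisible(tree)
}

#' Write a tree to newick
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path; if `NULL` the newick string is returned.
#' @return The newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Deterministic TSV writer used by all pipeline outputs, so that identical
# inputs + seed give byte-identical files.
write_tsv_det <- function(df, path, header_lines = character()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con, sep = "\n")
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

#' Read a tab-separated annotation table
#'
#' Annotation tables map taxa to traits (functionality, echolocation type,
#' roosting habit, diet) and are used for branch labelling.
#'
#' @param path TSV file with a header row; first column must be the taxon id.
#' @return A data.frame.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 2L) stop("annotation table needs a taxon column plus traits")
  names(df)[1] <- "taxon"
  if (anyDuplicated(df$taxon))
    stop("duplicated taxa in annotation table")
  df
}
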