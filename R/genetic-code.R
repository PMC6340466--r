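#' Genetic code tables
#'
#' Returns a genetic code as a codon-to-amino-acid lookup plus the set of stop
#' codons. Codes are taken from the NCBI translation tables shipped with
#' Biostrings; the default is the standard nuclear code (id `"1"`), which is
#' the appropriate code for mammalian nuclear opsin genes.
#'
#' @param id NCBI genetic code identifier as a string (default `"1"`,
#'   the standard code).
#' @return An object of class `"genetic_code"`: a list with elements
#'   `table` (named character vector of length 64 mapping codons, written in
#'   DNA alphabet, to one-letter amino acids with `"*"` for stops),
#'   `stop_codons`, `sense_codons` and `id`.
#' @examples
#' gc <- genetic_code()
#' gc$table[["ATG"]]
#' gc$stop_codons
#' @export
genetic_code <- function(id = "1") {
  tab <- Biostrings::getGeneticCode(id_or_name2 = id, as.data.frame = FALSE)
  # Biostrings uses RNA-free DNA codons ("TTT", ...) already
  stopifnot(length(tab) == 64L)
  structure(list(
    table = tab,
    stop_codons = names(tab)[tab == "*"],
    sense_codons = names(tab)[tab != "*"],
    id = id
  ), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code", x$id, "-", length(x$sense_codons), "sense codons, stops:",
      paste(x$stop_codons, collapse = " "), "\n")
  invisible(x)
}

is_genetic_code <- function(x) inherits(x, "genetic_code")

#' Translate a coding nucleotide sequence
#'
#' Translates codon by codon in the requested frame. Any codon containing a
#' gap (`-`) or a base outside `A/C/G/T` is rendered `"X"`; stop codons are
#' rendered `"*"`; a trailing partial codon is dropped. This is a total
#' function on the IUPAC alphabet: ambiguity is propagated, never guessed,
#' so that downstream key-site calls can treat `"X"` as unresolved.
#'
#' @param seq A single nucleotide string (may contain gaps and IUPAC
#'   ambiguity codes).
#' @param code A [genetic_code()].
#' @param frame Reading frame, 1, 2 or 3.
#' @return A single amino-acid string.
#' @examples
#' translate_cds("ATGTAA")      # "M*"
#' translate_cds("ATG---AAA")   # "MXK"
#' @export
translate_cds <- function(seq, code = genetic_code(), frame = 1L) {
  stopifnot(is.character(seq), length(seq) == 1L, frame %in% 1:3)
  s <- toupper(gsub("U", "T", seq, fixed = TRUE))
  s <- substr(s, frame, nchar(s))
  n_cod <- nchar(s) %/% 3L
  if (n_cod == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n_cod)
  codons <- substring(s, starts, starts + 2L)
  aa <- code$table[codons]
  aa[is.na(aa)] <- "X"  # gap- or ambiguity-containing codons
  paste(aa, collapse = "")
}
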