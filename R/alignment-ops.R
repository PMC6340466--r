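#' Remove codon columns containing indels (and, optionally, stops)
#'
#' Codon-model likelihoods are defined on gap-free, stop-free codon columns,
#' so every codon column containing a gap in any retained sequence is removed
#' before fitting; by default columns containing a stop codon or an ambiguous
#' base in any sequence are removed as well (disrupted codons of pseudogene
#' sequences are treated like indel columns). A removal log is attached.
#'
#' @param aln A [codon_alignment()].
#' @param drop_disrupted Also remove columns containing a stop codon or an
#'   ambiguous/non-ACGT codon in any sequence (default `TRUE`).
#' @return The stripped [codon_alignment()], with attribute `"removed"`:
#'   a data.frame of (codon_column, reason).
#' @export
strip_indel_codons <- function(aln, drop_disrupted = TRUE) {
  stopifnot(inherits(aln, "codon_alignment"))
  cm <- codon_matrix(aln)
  has_gap <- apply(cm, 2, function(x) any(grepl("-", x, fixed = TRUE)))
  reason <- ifelse(has_gap, "indel", NA_character_)
  if (drop_disrupted) {
    is_acgt <- apply(cm, 2, function(x) all(grepl("^[ACGT]{3}$", x)))
    has_stop <- logical(ncol(cm))
    ok_cols <- which(is_acgt)
    for (j in ok_cols)
      has_stop[j] <- any(aln$code$table[cm[, j]] == "*")
    reason[is.na(reason) & !is_acgt] <- "ambiguous"
    reason[is.na(reason) & has_stop] <- "stop"
  }
  drop <- !is.na(reason)
  if (all(drop)) stop("all codon columns removed; nothing left to analyse")
  keep <- which(!drop)
  seqs <- vapply(seq_len(nrow(cm)), function(i)
    paste(cm[i, keep], collapse = ""), character(1))
  names(seqs) <- rownames(cm)
  out <- codon_alignment(seqs, code = aln$code, gap_char = aln$gap_char)
  attr(out, "removed") <- data.frame(codon_column = which(drop),
                                     reason = reason[drop])
  out
}

#' Subset an alignment and tree to a clade and re-strip indel codons
#'
#' Column-wise indel stripping discards a codon column if any retained
#' sequence has a gap there, so analysing a clade on the full alignment can
#' throw away columns that are clean within the clade. Subsetting first and
#' re-stripping keeps those columns - useful when dating losses clade by
#' clade.
#'
#' @param aln A [codon_alignment()].
#' @param tree An [ape::phylo] tree.
#' @param tips Tip labels (or a node id whose clade is taken).
#' @param strip Re-run [strip_indel_codons()] on the subset (default `TRUE`).
#' @return List with `alignment` and `tree` restricted to the clade.
#' @export
clade_subset <- function(aln, tree, tips, strip = TRUE) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.numeric(tips)) {
    desc <- node_descendant_tips(tree)
    tips <- tree$tip.label[desc[[as.integer(tips)]]]
  }
  missing_tips <- setdiff(tips, names(aln$seqs))
  if (length(missing_tips))
    stop("taxa not in alignment: ", paste(missing_tips, collapse = ", "))
  if (length(tips) < 2L) stop("a clade subset needs at least 2 tips")
  sub <- codon_alignment(aln$seqs[tips], code = aln$code,
                         gap_char = aln$gap_char,
                         frame_strict = aln$length %% 3L == 0L)
  if (strip) sub <- strip_indel_codons(sub)
  list(alignment = sub,
       tree = ape::keep.tip(tree, tips))
}
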