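# ORF integrity: detection of loss-of-function lesions (frameshift indels,
# premature stop codons, splice-boundary violations), functional/pseudogene
# classification, and parsimony placement of shared lesions on the tree.

gap_runs <- function(mask) {
  # maximal TRUE runs -> data.frame(start, length); adjacent runs are never
  # merged across non-gap columns, each run is one lesion
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], length = r$lengths[r$values])
}

exon_of <- function(nt_col, exons) {
  if (is.null(exons)) return(NA_integer_)
  hit <- which(exons$start_nt <= nt_col & nt_col <= exons$end_nt)
  if (length(hit)) exons$exon[hit[1]] else NA_integer_
}

#' Scan an alignment for ORF-disrupting lesions
#'
#' Compares every sequence against a gap-free, internally stop-free reference
#' row. Gaps relative to the reference are aggregated into maximal indel runs
#' (insertion/deletion polarity is defined relative to the reference); each
#' sequence's own reading frame - which shifts downstream of frameshifting
#' indels simply because the degapped sequence is read from its start - is
#' then scanned for premature stop codons. A sequence is classified
#' `pseudogene` when it carries at least one frameshifting indel or a
#' premature stop codon; in-frame indels are tolerated.
#'
#' The terminal stop codon is never a lesion. A stop inside the final
#' `leniency` fraction of the alignment is reported with
#' `in_leniency = TRUE` and by default does not flip the status to
#' pseudogene, because C-terminal truncations may retain function; set
#' `leniency_flips_status = TRUE` (or `leniency = 0`) for the strict rule.
#'
#' @param aln A [codon_alignment()] (gaps allowed).
#' @param reference_taxon Reference row; default: the first taxon whose row
#'   is gap-free and internally stop-free. An explicitly named disrupted
#'   reference is an error.
#' @param exons Optional exon annotation: data.frame(exon, start_nt, end_nt)
#'   in alignment coordinates (1-based closed); gives lesions an exon index.
#' @param leniency Fraction of the 3' end of the ORF in which stops are
#'   reported but tolerated (default 0.1).
#' @param leniency_flips_status Treat leniency-window stops as
#'   pseudogenising (default `FALSE`).
#' @return Object of class `"orf_scan"`: list with `calls` (taxon, status,
#'   n_lesions), `lesions` (taxon, kind, exon_index, codon_column, length_nt,
#'   causes_frameshift, in_leniency) and `reference`.
#' @export
scan_orf <- function(aln, reference_taxon = NULL, exons = NULL,
                     leniency = 0.1, leniency_flips_status = FALSE) {
  stopifnot(inherits(aln, "codon_alignment"))
  code <- aln$code
  seqs <- toupper(aln$seqs)
  # A valid reference may carry gap columns opposite other taxa's insertions;
  # it is judged on its own degapped reading frame: no internal stops.
  is_clean <- function(s) {
    degap <- gsub("-", "", s, fixed = TRUE)
    if (!nzchar(degap) || nchar(degap) %% 3L != 0L) return(FALSE)
    aa <- translate_cds(degap, code)
    !grepl("\\*", substr(aa, 1, nchar(aa) - 1L))
  }
  if (is.null(reference_taxon)) {
    ok <- vapply(seqs, is_clean, logical(1))
    if (!any(ok)) stop("no gap-free, stop-free sequence available as reference")
    reference_taxon <- names(seqs)[which(ok)[1]]
  } else {
    if (!reference_taxon %in% names(seqs))
      stop("reference taxon not in alignment: ", reference_taxon)
    if (!is_clean(seqs[[reference_taxon]]))
      stop("reference row '", reference_taxon,
           "' is itself disrupted; pick another reference")
  }
  ref <- strsplit(seqs[[reference_taxon]], "")[[1]]
  L <- length(ref)
  n_codon_cols <- ceiling(L / 3)
  lesion_rows <- list()
  status <- character(0)

  for (tx in names(seqs)) {
    chars <- strsplit(seqs[[tx]], "")[[1]]
    les <- list()
    if (tx != reference_taxon) {
      del <- gap_runs(chars == "-" & ref != "-")
      ins <- gap_runs(chars != "-" & ref == "-")
      if (nrow(del)) for (i in seq_len(nrow(del)))
        les[[length(les) + 1L]] <- data.frame(
          taxon = tx, kind = "deletion",
          exon_index = exon_of(del$start[i], exons),
          codon_column = (del$start[i] - 1L) %/% 3L + 1L,
          length_nt = del$length[i],
          causes_frameshift = del$length[i] %% 3L != 0L,
          in_leniency = FALSE)
      if (nrow(ins)) for (i in seq_len(nrow(ins)))
        les[[length(les) + 1L]] <- data.frame(
          taxon = tx, kind = "insertion",
          exon_index = exon_of(ins$start[i], exons),
          codon_column = (ins$start[i] - 1L) %/% 3L + 1L,
          length_nt = ins$length[i],
          causes_frameshift = ins$length[i] %% 3L != 0L,
          in_leniency = FALSE)
    }
    # premature stops in the taxon's own reading frame
    keep <- which(chars != "-")
    degap <- paste(chars[keep], collapse = "")
    aa <- strsplit(translate_cds(degap, code), "")[[1]]
    stops <- which(aa == "*")
    stops <- stops[stops < length(aa)]   # terminal stop is not a lesion
    for (k in stops) {
      col <- keep[3L * (k - 1L) + 1L]
      cc <- (col - 1L) %/% 3L + 1L
      les[[length(les) + 1L]] <- data.frame(
        taxon = tx, kind = "premature_stop",
        exon_index = exon_of(col, exons),
        codon_column = cc, length_nt = 3L,
        causes_frameshift = FALSE,
        in_leniency = cc > (1 - leniency) * n_codon_cols)
    }
    ldf <- if (length(les)) do.call(rbind, les) else NULL
    disrupting <- !is.null(ldf) && any(
      (ldf$kind %in% c("deletion", "insertion") & ldf$causes_frameshift) |
      (ldf$kind == "premature_stop" &
         (!ldf$in_leniency | leniency_flips_status)))
    status[tx] <- if (disrupting) "pseudogene" else "functional"
    if (!is.null(ldf)) lesion_rows[[tx]] <- ldf
  }
  lesions <- if (length(lesion_rows)) do.call(rbind, lesion_rows) else
    data.frame(taxon = character(), kind = character(),
               exon_index = integer(), codon_column = integer(),
               length_nt = integer(), causes_frameshift = logical(),
               in_leniency = logical())
  lesions <- lesions[order(match(lesions$taxon, names(seqs)),
                           lesions$codon_column), ]
  rownames(lesions) <- NULL
  calls <- data.frame(
    taxon = names(seqs), status = unname(status[names(seqs)]),
    n_lesions = vapply(names(seqs), function(tx)
      sum(lesions$taxon == tx), integer(1)),
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  structure(list(calls = calls, lesions = lesions,
                 reference = reference_taxon),
            class = "orf_scan")
}

#' @export
print.orf_scan <- function(x, ...) {
  np <- sum(x$calls$status == "pseudogene")
  cat("ORF scan vs reference '", x$reference, "': ",
      nrow(x$calls), " taxa, ", np, " pseudogene(s), ",
      nrow(x$lesions), " lesion(s)\n", sep = "")
  invisible(x)
}

#' Check intron splice boundaries (GT/AG rule)
#'
#' For each intron implied by consecutive exon intervals on a genomic
#' sequence, the donor dinucleotide must be `GT` and the acceptor `AG`;
#' violations are returned with the observed dinucleotides.
#'
#' @param genomic_seq Genomic nucleotide string.
#' @param exon_intervals Data.frame with columns `start`, `end` (1-based
#'   closed), sorted and non-overlapping.
#' @return Data.frame of violations: intron_index, kind
#'   (`"splice_violation"`), donor, acceptor. Zero rows when all boundaries
#'   conform (or with a single exon).
#' @export
check_splice_sites <- function(genomic_seq, exon_intervals) {
  stopifnot(is.character(genomic_seq), length(genomic_seq) == 1L)
  ex <- exon_intervals
  stopifnot(all(c("start", "end") %in% names(ex)))
  if (is.unsorted(ex$start) || any(ex$end < ex$start) ||
      (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])))
    stop("exon intervals must be sorted and non-overlapping")
  s <- toupper(genomic_seq)
  if (any(ex$end > nchar(s)) || any(ex$start < 1L))
    stop("exon interval outside sequence")
  out <- list()
  if (nrow(ex) > 1L) {
    for (i in seq_len(nrow(ex) - 1L)) {
      don <- substr(s, ex$end[i] + 1L, ex$end[i] + 2L)
      acc <- substr(s, ex$start[i + 1L] - 2L, ex$start[i + 1L] - 1L)
      if (don != "GT" || acc != "AG")
        out[[length(out) + 1L]] <- data.frame(
          intron_index = i, kind = "splice_violation",
          donor = don, acceptor = acc)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(intron_index = integer(), kind = character(),
               donor = character(), acceptor = character())
}

#' Place shared lesions on the tree by Dollo parsimony
#'
#' Each distinct lesion signature (kind + codon column + length) is placed on
#' the branch above the most recent common ancestor of its carrier taxa
#' (single gain, no loss). When non-carrier tips also descend from that
#' branch the single-origin placement is inconsistent; the lesion is flagged
#' homoplastic and left tip-assigned (no origin branch).
#'
#' @param scan An [scan_orf()] result (or a lesion data.frame with columns
#'   taxon, kind, codon_column, length_nt).
#' @param tree An [ape::phylo] tree containing all carrier taxa.
#' @return Data.frame: kind, codon_column, length_nt, n_carriers, carriers
#'   (comma-separated), origin_child (child node id of the origin branch;
#'   `NA` when homoplastic), homoplastic.
#' @export
place_lesions <- function(scan, tree) {
  lesions <- if (inherits(scan, "orf_scan")) scan$lesions else scan
  validate_tree(tree, require_lengths = FALSE)
  if (!nrow(lesions))
    return(data.frame(kind = character(), codon_column = integer(),
                      length_nt = integer(), n_carriers = integer(),
                      carriers = character(), origin_child = integer(),
                      homoplastic = logical()))
  missing_tips <- setdiff(lesions$taxon, tree$tip.label)
  if (length(missing_tips))
    stop("carrier taxa not on tree: ", paste(missing_tips, collapse = ", "))
  sig <- paste(lesions$kind, lesions$codon_column, lesions$length_nt)
  desc <- node_descendant_tips(tree)
  out <- lapply(split(seq_len(nrow(lesions)), sig), function(ii) {
    carriers <- unique(lesions$taxon[ii])
    tip_ids <- match(carriers, tree$tip.label)
    node <- if (length(tip_ids) == 1L) tip_ids else
      ape::getMRCA(tree, tip_ids)
    clade <- desc[[node]]
    homo <- !setequal(clade, tip_ids)
    data.frame(kind = lesions$kind[ii[1]],
               codon_column = lesions$codon_column[ii[1]],
               length_nt = lesions$length_nt[ii[1]],
               n_carriers = length(carriers),
               carriers = paste(sort(carriers), collapse = ","),
               origin_child = if (homo) NA_integer_ else node,
               homoplastic = homo)
  })
  res <- do.call(rbind, out)
  res <- res[order(res$codon_column, res$kind), ]
  rownames(res) <- NULL
  res
}
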