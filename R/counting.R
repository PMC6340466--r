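# Nei-Gojobori (1986) counting estimator of dN/dS, the maximum-likelihood-free
# cross-check on the codon-model fits.

ng86_site_fractions <- function(codon, code) {
  # fraction of single-nt changes at each position that are synonymous,
  # mutations to stop codons excluded from the denominator
  nts <- c("A", "C", "G", "T")
  aa0 <- code$table[[codon]]
  s <- 0
  for (p in 1:3) {
    from <- substr(codon, p, p)
    syn <- 0L; tot <- 0L
    for (nt in setdiff(nts, from)) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (code$table[[alt]] == "*") next
      tot <- tot + 1L
      if (code$table[[alt]] == aa0) syn <- syn + 1L
    }
    if (tot > 0L) s <- s + syn / tot
  }
  c(S = s, N = 3 - s)
}

ng86_path_counts <- function(c1, c2, code) {
  # average synonymous/nonsynonymous difference counts over all minimal
  # mutational pathways between two codons, skipping pathways through stops
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(Sd = 0, Nd = 0))
  step <- function(a, p) { b <- a; substr(b, p, p) <- substr(c2, p, p); b }
  paths <- if (k == 1L) list(pos) else {
    perms <- if (k == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(i) pos[i])
    }
    perms
  }
  count_one <- function(order) {
    cur <- c1; sd <- 0L; nd <- 0L
    for (p in order) {
      nxt <- step(cur, p)
      if (code$table[[nxt]] == "*") return(NULL)
      if (code$table[[nxt]] == code$table[[cur]]) sd <- sd + 1L else nd <- nd + 1L
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, count_one))
  if (!length(res)) {
    # every pathway passes through a stop; fall back to counting over all
    # pathways with stop intermediates treated as a distinct residue
    count_any <- function(order) {
      cur <- c1; sd <- 0L; nd <- 0L
      for (p in order) {
        nxt <- step(cur, p)
        if (code$table[[nxt]] == code$table[[cur]]) sd <- sd + 1L else nd <- nd + 1L
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(paths, count_any)
  }
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

#' Pairwise dN/dS by Nei-Gojobori (1986) counting
#'
#' Counts synonymous and nonsynonymous sites (each codon position weighted by
#' the fraction of its single-nucleotide changes that are synonymous, with
#' changes to stop codons excluded) and synonymous/nonsynonymous differences
#' (multi-nucleotide codon differences averaged over all minimal mutational
#' pathways that avoid stop codons), then applies the Jukes-Cantor correction
#' to the proportions to obtain per-site distances dN and dS.
#'
#' @param seq_a,seq_b Equal-length, indel-stripped, in-frame coding sequences.
#' @param code A [genetic_code()].
#' @return Object of class `"dnds_count"`: list with `N`, `S` (site counts,
#'   `N + S` = 3 x compared codons), `Nd`, `Sd` (difference counts), `pN`,
#'   `pS`, `dN`, `dS` and `omega` (`NA` with a `reason` attribute when
#'   `dS == 0`).
#' @export
count_dnds <- function(seq_a, seq_b, code = genetic_code()) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  a <- toupper(seq_a); b <- toupper(seq_b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("sequence length not divisible by 3")
  n_cod <- nchar(a) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_cod)
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  ok <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  if (any(code$table[ca[ok]] == "*") || any(code$table[cb[ok]] == "*"))
    stop("internal stop codon in input; strip disrupted codons first")
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")

  fa <- vapply(ca, ng86_site_fractions, numeric(2), code = code)
  fb <- vapply(cb, ng86_site_fractions, numeric(2), code = code)
  S <- (sum(fa["S", ]) + sum(fb["S", ])) / 2
  N <- (sum(fa["N", ]) + sum(fb["N", ])) / 2
  d <- mapply(function(x, y) ng86_path_counts(x, y, code), ca, cb)
  Sd <- sum(d["Sd", ]); Nd <- sum(d["Nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS); dN <- jc(pN)
  omega <- NA_real_
  reason <- NULL
  if (is.na(dS) || is.na(dN)) {
    reason <- "proportion of differences too large for Jukes-Cantor correction"
  } else if (dS == 0) {
    reason <- "dS = 0: omega undefined"
  } else omega <- dN / dS
  structure(list(n_codons = length(ca), N = N, S = S, Nd = Nd, Sd = Sd,
                 pN = pN, pS = pS, dN = dN, dS = dS, omega = omega,
                 reason = reason),
            class = "dnds_count")
}

#' @export
print.dnds_count <- function(x, ...) {
  cat(sprintf("NG86 counting over %d codons: N=%.2f S=%.2f Nd=%.2f Sd=%.2f\n",
              x$n_codons, x$N, x$S, x$Nd, x$Sd))
  cat(sprintf("  dN=%.4f dS=%.4f omega=%s\n", x$dN, x$dS,
              ifelse(is.na(x$omega), paste0("NA (", x$reason, ")"),
                     sprintf("%.4f", x$omega))))
  invisible(x)
}
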