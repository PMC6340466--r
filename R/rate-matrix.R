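# Goldman-Yang codon substitution model: rate matrix construction.
#
# q_ij = 0                       if codons i,j differ at >1 position
#      = pi_j                    synonymous transversion
#      = kappa * pi_j            synonymous transition
#      = omega * pi_j            nonsynonymous transversion
#      = omega * kappa * pi_j    nonsynonymous transition
# with the diagonal set to minus the row sum.

.opsinevol_cache <- new.env(parent = emptyenv())

# Structural tables for a codon state set: single-nt-difference mask,
# transition mask, nonsynonymous mask. Cached per (code id, state set).
codon_structure <- function(states, code) {
  key <- paste0(code$id, ":", length(states))
  hit <- .opsinevol_cache[[key]]
  if (!is.null(hit) && identical(hit$states, states)) return(hit)
  n <- length(states)
  m <- do.call(rbind, strsplit(states, ""))
  ndiff <- matrix(0L, n, n)
  pos_diff <- matrix(0L, n, n)
  for (p in 1:3) {
    d <- outer(m[, p], m[, p], "!=")
    ndiff <- ndiff + d
    pos_diff[d & pos_diff == 0L] <- p
  }
  single <- ndiff == 1L
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  is_ts <- matrix(FALSE, n, n)
  for (p in 1:3) {
    sel <- single & pos_diff == p
    ts <- outer(purine[m[, p]], purine[m[, p]], "==")
    is_ts[sel] <- ts[sel]
  }
  aa <- unname(code$table[states])
  nonsyn <- outer(aa, aa, "!=")
  out <- list(states = states, single = single, is_ts = is_ts,
              nonsyn = nonsyn, aa = aa)
  .opsinevol_cache[[key]] <- out
  out
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the instantaneous rate matrix (generator) of a codon substitution
#' model over the sense codons, parameterised by the transition/transversion
#' rate ratio `kappa`, the nonsynonymous/synonymous rate ratio `omega`, and
#' codon equilibrium frequencies.
#'
#' Scaling conventions: `"expected"` (default) rescales the generator so that
#' one unit of branch length is one expected substitution per codon site under
#' this matrix; `"neutral"` rescales by the rate of the corresponding neutral
#' (`omega = 1`) matrix, so that the synonymous clock is comparable across
#' matrices that differ only in `omega` (used by the pseudogenisation
#' simulator, where dN/dS algebra requires an era-independent synonymous
#' rate); `"none"` leaves the generator unscaled.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio, >= 0.
#' @param freqs Codon equilibrium frequencies over the sense codons (named or
#'   in state order), or `NULL` for uniform.
#' @param code A [genetic_code()].
#' @param scale `"expected"`, `"neutral"`, or `"none"`.
#' @param states `"sense"` (default, 61 codons under the standard code) or
#'   `"all64"`. With `"all64"` every single-nucleotide change is permitted and
#'   changes into or out of stop codons are treated as neutral (rate
#'   `pi_j * kappa^ts`), the regime of a dead pseudogene.
#' @return Square generator matrix with row/column names the codon states and
#'   attributes `pi`, `kappa`, `omega`, `rate` (pre-scaling expected rate).
#' @export
codon_rate_matrix <- function(kappa, omega, freqs = NULL,
                              code = genetic_code(),
                              scale = c("expected", "neutral", "none"),
                              states = c("sense", "all64")) {
  scale <- match.arg(scale)
  states <- match.arg(states)
  stopifnot(kappa > 0, omega >= 0)
  st <- if (states == "sense") code$sense_codons else names(code$table)
  n <- length(st)
  if (is.null(freqs)) freqs <- rep(1 / n, n)
  if (!is.null(names(freqs))) freqs <- freqs[st]
  if (length(freqs) != n || anyNA(freqs) || any(freqs < 0))
    stop("invalid codon frequencies")
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("codon frequencies must sum to 1 over the ", n, " states")
  names(freqs) <- st
  cs <- codon_structure(st, code)

  Q <- matrix(0, n, n, dimnames = list(st, st))
  Q[cs$single] <- rep(freqs, each = n)[cs$single]
  Q[cs$single & cs$is_ts] <- Q[cs$single & cs$is_ts] * kappa
  if (states == "sense") {
    ns <- cs$single & cs$nonsyn
    Q[ns] <- Q[ns] * omega
  } else {
    # sense<->sense nonsynonymous changes scale with omega; any change
    # touching a stop codon is neutral (pseudogene regime)
    is_stop <- cs$aa == "*"
    stop_touch <- outer(is_stop, is_stop, "|")
    ns <- cs$single & cs$nonsyn & !stop_touch
    Q[ns] <- Q[ns] * omega
  }
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  if (scale == "expected") {
    if (rate <= 0) stop("degenerate rate matrix (expected rate is 0)")
    Q <- Q / rate
  } else if (scale == "neutral") {
    Qn <- codon_rate_matrix(kappa, 1, freqs = if (states == "sense") freqs else NULL,
                            code = code, scale = "none", states = "sense")
    nr <- attr(Qn, "rate")
    if (states == "all64") {
      # use the sense-state neutral rate computed on the sense marginals of freqs
      fs <- freqs[code$sense_codons] / sum(freqs[code$sense_codons])
      Qn <- codon_rate_matrix(kappa, 1, freqs = fs, code = code,
                              scale = "none", states = "sense")
      nr <- attr(Qn, "rate")
    }
    Q <- Q / nr
  }
  structure(Q, pi = freqs, kappa = kappa, omega = omega, rate = rate,
            states = states)
}

#' Empirical codon frequencies from an alignment
#'
#' @param aln A [codon_alignment()] (or character vector of sequences).
#' @param method `"F1x4"` (products of overall nucleotide frequencies,
#'   default), `"F3x4"` (position-specific nucleotide frequencies) or
#'   `"uniform"`. Stop codons are excluded and the result renormalised over
#'   the sense codons.
#' @param code A [genetic_code()].
#' @return Named numeric vector over the sense codons, summing to 1.
#' @export
codon_freqs <- function(aln, method = c("F1x4", "F3x4", "uniform"),
                        code = genetic_code()) {
  method <- match.arg(method)
  st <- code$sense_codons
  if (method == "uniform")
    return(stats::setNames(rep(1 / length(st), length(st)), st))
  seqs <- if (inherits(aln, "codon_alignment")) aln$seqs else aln
  chars <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  keep <- chars %in% c("A", "C", "G", "T")
  nts <- c("A", "C", "G", "T")
  cm <- do.call(rbind, strsplit(st, ""))
  if (method == "F1x4") {
    f <- table(factor(chars[keep], levels = nts))
    f <- as.numeric(f) / sum(f)
    names(f) <- nts
    p <- f[cm[, 1]] * f[cm[, 2]] * f[cm[, 3]]
  } else {
    pos <- ((seq_along(chars) - 1L) %% 3L) + 1L  # frame of the alignment
    p_by <- sapply(1:3, function(k) {
      x <- chars[keep & pos == k]
      f <- table(factor(x, levels = nts))
      as.numeric(f) / sum(f)
    })
    rownames(p_by) <- nts
    p <- p_by[cm[, 1], 1] * p_by[cm[, 2], 2] * p_by[cm[, 3], 3]
  }
  p <- p / sum(p)
  stats::setNames(as.numeric(p), st)
}

# Symmetrising eigendecomposition of a reversible generator.
# Returns a closure environment usable to compute P(t) cheaply.
rev_eigen <- function(Q, pi = attr(Q, "pi")) {
  d <- sqrt(pi)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2          # symmetrise against round-off
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       A = e$vectors / d,       # rows scaled by 1/sqrt(pi)
       B = t(e$vectors * d))    # = t(vectors) %*% diag(sqrt(pi))
}

# Transition probability matrix P(t) = exp(Qt) from a rev_eigen decomposition.
trans_prob <- function(eig, t) {
  P <- eig$A %*% (exp(eig$values * t) * eig$B)
  P[P < 0] <- 0
  P
}
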