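# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's computational path: transition probabilities come from
# Matrix::expm, parsimony minima from exhaustive enumeration, synonymy calls
# from direct genetic-code lookups.

tree4 <- function() read_newick(text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
tree3 <- function() read_newick(text = "((A:0.2,B:0.3):0.1,C:0.4);")

balanced_tree <- function(n, bl = 0.1) {
  shape <- if (log2(n) %% 1 == 0) "balanced" else "left"
  tr <- ape::stree(n, shape)
  tr$edge.length <- rep(bl, nrow(tr$edge))
  tr
}

# Exhaustive-summation log-likelihood over all internal-node state
# assignments; tractable for <= 3 internal nodes. P matrices via Matrix::expm.
bf_loglik <- function(aln, tree, kappa, omega, freqs = NULL) {
  code <- aln$code
  if (is.null(freqs)) freqs <- codon_freqs(aln, "F1x4", code)
  Q <- codon_rate_matrix(kappa, omega, freqs = freqs, code = code)
  pi <- attr(Q, "pi")
  st <- rownames(Q)
  trp <- ape::reorder.phylo(tree, "postorder")
  P <- lapply(trp$edge.length, function(t)
    as.matrix(Matrix::expm(Q * t)))
  cm <- codon_matrix(aln)
  idx <- matrix(match(cm, st), nrow = nrow(cm), dimnames = dimnames(cm))
  idx <- idx[trp$tip.label, , drop = FALSE]
  ntip <- length(trp$tip.label)
  ints <- (ntip + 1L):(ntip + trp$Nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_along(st)), length(ints))))
  ll <- 0
  for (s in seq_len(ncol(idx))) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- function(v) {
        if (v <= ntip) idx[v, s] else grid[g, match(v, ints)]
      }
      p <- pi[assign_state(ntip + 1L)]
      for (e in seq_len(nrow(trp$edge)))
        p <- p * P[[e]][assign_state(trp$edge[e, 1]), assign_state(trp$edge[e, 2])]
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  unname(ll)
}

# Exhaustive minimum-changes parsimony score for one site: internal nodes
# enumerated over the states observed at the tips (an optimum using only
# observed states always exists under uniform costs).
bf_parsimony_site <- function(tree, tip_states) {
  trp <- ape::reorder.phylo(tree, "postorder")
  obs <- tip_states[trp$tip.label]
  keep <- !is.na(obs)
  states <- sort(unique(obs[keep]))
  if (sum(keep) < 2L) return(NA_integer_)
  ntip <- length(trp$tip.label)
  ints <- (ntip + 1L):(ntip + trp$Nnode)
  grid <- as.matrix(expand.grid(rep(list(states), length(ints))))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    lab <- function(v) if (v <= ntip) obs[v] else grid[g, match(v, ints)]
    ch <- 0L
    for (e in seq_len(nrow(trp$edge))) {
      a <- lab(trp$edge[e, 1]); b <- lab(trp$edge[e, 2])
      if (!is.na(a) && !is.na(b) && a != b) ch <- ch + 1L
    }
    best <- min(best, ch)
  }
  best
}

# Direct synonymy oracle: is the single-nucleotide change c1 -> c2 synonymous?
oracle_synonymous <- function(c1, c2) {
  gc <- genetic_code()
  unname(gc$table[c1] == gc$table[c2])
}

# Closed-form Poisson amino-acid transition probability (20 states).
poisson_P <- function(t) {
  e <- exp(-20 * t / 19)
  m <- matrix((1 - e) / 20, 20, 20)
  diag(m) <- e + (1 - e) / 20
  dimnames(m) <- list(opsinevol:::AA_ALPHABET, opsinevol:::AA_ALPHABET)
  m
}

degap <- function(s) gsub("-", "", s, fixed = TRUE)

make_position_map <- function(query_pos, ref_pos) {
  structure(data.frame(query_pos = query_pos, ref_pos = ref_pos),
            class = c("position_map", "data.frame"), identity = 1)
}
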