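# Felsenstein pruning over a phylogeny for an arbitrary finite state space.
# One engine serves both the codon-model likelihoods (61 states) and the
# marginal amino-acid reconstructions (20 states). The inside pass computes
# per-node conditional likelihoods bottom-up; the outside pass computes the
# complementary ("rest of tree") likelihoods top-down, which gives marginal
# node posteriors and cheap one-branch likelihood profiles for branch-length
# optimisation. All partials carry per-pattern log scale factors to prevent
# underflow.

compress_patterns <- function(idx) {
  # idx: ntaxa x nsites integer matrix (NA = missing)
  key <- apply(idx, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(idx = idx[, first, drop = FALSE], weights = weights,
       pattern_of_site = match(key, key[first]))
}

lik_engine <- function(tree, idx, nstate, weights = NULL) {
  # idx rows must be named by taxa present in the tree
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  if (is.null(rownames(idx))) stop("state matrix must have taxon rownames")
  miss <- setdiff(tree$tip.label, rownames(idx))
  if (length(miss)) stop("taxa missing from alignment: ", paste(miss, collapse = ", "))
  idx <- idx[tree$tip.label, , drop = FALSE]
  if (is.null(weights)) weights <- rep(1, ncol(idx))
  npat <- ncol(idx)
  tipmat <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    m <- matrix(0, nstate, npat)
    ok <- !is.na(idx[i, ])
    m[cbind(idx[i, ok], which(ok))] <- 1
    m[, !ok] <- 1   # missing data: partial likelihood 1 for every state
    tipmat[[i]] <- m
  }
  list(tree = tree, edge = tree$edge, nedge = nrow(tree$edge),
       ntip = ntip, nnode = ntip + tree$Nnode,
       root = ntip + 1L, nstate = nstate, npat = npat,
       tipmat = tipmat, weights = weights)
}

rescale_cols <- function(m) {
  s <- colSums(m)
  s[s <= 0] <- 1
  list(m = m / rep(s, each = nrow(m)), logs = log(s))
}

inside_pass <- function(eng, P) {
  part <- vector("list", eng$nnode)
  slog <- vector("list", eng$nnode)
  msg <- vector("list", eng$nedge)
  mslog <- vector("list", eng$nedge)
  zero <- numeric(eng$npat)
  for (i in seq_len(eng$ntip)) { part[[i]] <- eng$tipmat[[i]]; slog[[i]] <- zero }
  for (e in seq_len(eng$nedge)) {
    pa <- eng$edge[e, 1]; ch <- eng$edge[e, 2]
    M <- P[[e]] %*% part[[ch]]
    r <- rescale_cols(M)
    msg[[e]] <- r$m
    mslog[[e]] <- slog[[ch]] + r$logs
    if (is.null(part[[pa]])) {
      part[[pa]] <- msg[[e]]; slog[[pa]] <- mslog[[e]]
    } else {
      part[[pa]] <- part[[pa]] * msg[[e]]
      slog[[pa]] <- slog[[pa]] + mslog[[e]]
    }
  }
  list(part = part, slog = slog, msg = msg, mslog = mslog)
}

root_site_loglik <- function(eng, ins, pi) {
  v <- colSums(pi * ins$part[[eng$root]])
  log(v) + ins$slog[[eng$root]]
}

outside_pass <- function(eng, P, ins, pi) {
  out <- vector("list", eng$nnode)
  oslog <- vector("list", eng$nnode)
  above <- vector("list", eng$nedge)
  aslog <- vector("list", eng$nedge)
  out[[eng$root]] <- matrix(pi, eng$nstate, eng$npat)
  oslog[[eng$root]] <- numeric(eng$npat)
  kids <- split(seq_len(eng$nedge), eng$edge[, 1])
  for (e in rev(seq_len(eng$nedge))) {   # preorder: parents before children
    pa <- eng$edge[e, 1]; ch <- eng$edge[e, 2]
    A <- out[[pa]]; As <- oslog[[pa]]
    for (sib in kids[[as.character(pa)]]) {
      if (sib == e) next
      A <- A * ins$msg[[sib]]
      As <- As + ins$mslog[[sib]]
    }
    r <- rescale_cols(A)
    above[[e]] <- r$m
    aslog[[e]] <- As + r$logs
    Oc <- crossprod(P[[e]], above[[e]])
    r2 <- rescale_cols(Oc)
    out[[ch]] <- r2$m
    oslog[[ch]] <- aslog[[e]] + r2$logs
  }
  list(out = out, oslog = oslog, above = above, aslog = aslog)
}

# Marginal posterior state probabilities at every node (columns = patterns).
node_posteriors <- function(eng, ins, outs) {
  post <- vector("list", eng$nnode)
  for (v in seq_len(eng$nnode)) {
    m <- ins$part[[v]] * outs$out[[v]]
    s <- colSums(m)
    s[s <= 0] <- 1
    post[[v]] <- m / rep(s, each = eng$nstate)
  }
  post
}

logsumexp_rows <- function(mat) {
  # mat: k x n of log terms; returns length-n vector log(sum_k exp)
  mx <- apply(mat, 2, max)
  mx + log(colSums(exp(mat - rep(mx, each = nrow(mat)))))
}
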