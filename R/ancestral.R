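# Ancestral amino-acid state reconstruction (two-pass Fitch parsimony and
# marginal maximum likelihood via the shared pruning engine) and
# convergent/divergent substitution classification between branch pairs.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

aa_state_matrix <- function(x, code = genetic_code()) {
  # x: named character vector of protein sequences, or codon_alignment
  if (inherits(x, "codon_alignment"))
    x <- vapply(x$seqs, translate_cds, character(1), code = code)
  m <- do.call(rbind, strsplit(toupper(x), ""))
  rownames(m) <- names(x)
  m
}

node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  c(tree$tip.label, paste0("node", (ntip + 1L):(ntip + tree$Nnode)))
}

#' Fitch parsimony reconstruction of ancestral states
#'
#' Standard two-pass Fitch parsimony per site. Gaps, `X` and `?` at tips are
#' missing data and excluded from scoring; sites with fewer than two observed
#' tips are skipped with a note. Ambiguous nodes carry their full state set;
#' the reported representative state is made deterministic by preferring the
#' parent's state when available and the alphabetically first member
#' otherwise.
#'
#' @param tree An [ape::phylo] tree (branch lengths not required).
#' @param states Taxa-by-sites character matrix (rownames = taxa), a named
#'   character vector of protein sequences, or a [codon_alignment()]
#'   (translated first).
#' @return Object of class `"aa_ancestral"`, method `"parsimony"`: `states`
#'   (all-nodes-by-sites representative matrix), `sets` (per-site list of
#'   node state sets, `|`-collapsed), `score` (per-site parsimony score,
#'   `NA` for skipped sites), `total_score`, `skipped`, `tree` (postorder).
#' @export
fitch_parsimony <- function(tree, states) {
  validate_tree(tree, require_lengths = FALSE)
  m <- if (is.matrix(states)) states else aa_state_matrix(states)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, rownames(m))
  if (length(missing_tips)) stop("taxa missing: ", paste(missing_tips, collapse = ", "))
  m <- m[tree$tip.label, , drop = FALSE]
  m[m %in% c("-", "X", "?", ".", "*")] <- NA
  nn <- ntip + tree$Nnode
  nsite <- ncol(m)
  rep_states <- matrix(NA_character_, nn, nsite,
                       dimnames = list(node_labels(tree), NULL))
  rep_states[seq_len(ntip), ] <- m
  score <- rep(NA_integer_, nsite)
  sets_out <- vector("list", nsite)
  edge <- tree$edge
  root <- ntip + 1L

  for (s in seq_len(nsite)) {
    obs <- m[, s]
    if (sum(!is.na(obs)) < 2L) next   # skipped: too few observed tips
    sets <- vector("list", nn)
    for (i in seq_len(ntip)) sets[[i]] <- if (is.na(obs[i])) character() else obs[i]
    sc <- 0L
    # bottom-up in postorder edge order: children are complete before parents
    for (e in seq_len(nrow(edge))) {
      pa <- edge[e, 1]; ch <- edge[e, 2]
      child_set <- sets[[ch]]
      if (is.null(sets[[pa]])) { sets[[pa]] <- child_set; next }
      if (!length(child_set)) next          # missing child: no information
      if (!length(sets[[pa]])) { sets[[pa]] <- child_set; next }
      inter <- intersect(sets[[pa]], child_set)
      if (length(inter)) sets[[pa]] <- inter
      else { sets[[pa]] <- union(sets[[pa]], child_set); sc <- sc + 1L }
    }
    score[s] <- sc
    # top-down representative assignment
    rs <- rep(NA_character_, nn)
    root_set <- sort(sets[[root]])
    if (length(root_set)) rs[root] <- root_set[1]
    for (e in rev(seq_len(nrow(edge)))) {
      pa <- edge[e, 1]; ch <- edge[e, 2]
      if (ch <= ntip) { rs[ch] <- obs[ch]; next }
      chset <- sort(sets[[ch]])
      if (!length(chset)) { rs[ch] <- rs[pa]; next }
      rs[ch] <- if (!is.na(rs[pa]) && rs[pa] %in% chset) rs[pa] else chset[1]
    }
    rep_states[, s] <- rs
    sets_out[[s]] <- vapply(sets, function(x)
      paste(sort(x), collapse = "|"), character(1))
  }
  structure(list(method = "parsimony", states = rep_states, sets = sets_out,
                 score = score, total_score = sum(score, na.rm = TRUE),
                 skipped = which(is.na(score)), tree = tree),
            class = "aa_ancestral")
}

#' Marginal maximum-likelihood ancestral reconstruction
#'
#' Computes, for every internal node and site, the marginal posterior
#' distribution over the 20 amino acids via the inside-outside (pruning up,
#' complementary likelihood down) algorithm, under a uniform-rate Poisson
#' model by default or a user-supplied reversible generator. The reported
#' state is the posterior argmax, ties broken alphabetically. Gaps/`X` at
#' tips are missing data (partial likelihood 1 over all states).
#'
#' @param tree Tree with branch lengths in expected substitutions/site
#'   (zero lengths are floored at 1e-9 so posteriors collapse to the
#'   observed consensus rather than degenerating).
#' @param states As in [fitch_parsimony()].
#' @param Q Optional 20x20 reversible generator (rownames = amino acids) with
#'   matching `freqs`; default: Poisson (equal exchangeabilities and
#'   frequencies, expected rate 1).
#' @param freqs Equilibrium frequencies (default uniform).
#' @return Object of class `"aa_ancestral"`, method `"ml"`: `states`
#'   (representative matrix), `posterior` (sites-list of nodes x 20
#'   matrices), `loglik`, `alphabet`, `tree` (postorder).
#' @export
marginal_ml_reconstruction <- function(tree, states, Q = NULL, freqs = NULL) {
  validate_tree(tree)
  m <- if (is.matrix(states)) states else aa_state_matrix(states)
  m[m %in% c("-", "X", "?", ".", "*")] <- NA
  alphabet <- AA_ALPHABET
  if (is.null(freqs)) freqs <- rep(1 / 20, 20)
  if (is.null(Q)) {
    Q <- matrix(1 / 19, 20, 20, dimnames = list(alphabet, alphabet))
    diag(Q) <- -1
  } else {
    stopifnot(all(dim(Q) == c(20, 20)))
    alphabet <- rownames(Q)
  }
  idx <- matrix(match(m, alphabet), nrow = nrow(m), dimnames = dimnames(m))
  eng <- lik_engine(tree, idx, nstate = length(alphabet))
  tree_po <- eng$tree
  bl <- pmax(tree_po$edge.length, 1e-9)
  eig <- rev_eigen(Q, freqs)
  P <- lapply(bl, function(t) trans_prob(eig, t))
  ins <- inside_pass(eng, P)
  outs <- outside_pass(eng, P, ins, freqs)
  post <- node_posteriors(eng, ins, outs)
  ll <- sum(eng$weights * root_site_loglik(eng, ins, freqs))
  nn <- eng$nnode
  nsite <- ncol(idx)
  rep_states <- matrix(NA_character_, nn, nsite,
                       dimnames = list(node_labels(tree_po), NULL))
  posterior <- vector("list", nsite)
  for (s in seq_len(nsite)) {
    pm <- t(vapply(post, function(x) x[, s], numeric(length(alphabet))))
    colnames(pm) <- alphabet
    posterior[[s]] <- pm
    rep_states[, s] <- alphabet[max.col(pm, ties.method = "first")]
  }
  idx_po <- idx[tree_po$tip.label, , drop = FALSE]
  obs_ok <- !is.na(idx_po)
  tip_block <- rep_states[seq_len(eng$ntip), , drop = FALSE]
  tip_block[obs_ok] <- alphabet[idx_po[obs_ok]]
  rep_states[seq_len(eng$ntip), ] <- tip_block
  structure(list(method = "ml", states = rep_states, posterior = posterior,
                 loglik = ll, alphabet = alphabet, tree = tree_po),
            class = "aa_ancestral")
}

#' @export
print.aa_ancestral <- function(x, ...) {
  cat("Ancestral reconstruction (", x$method, "): ",
      nrow(x$states), " nodes x ", ncol(x$states), " sites",
      if (x$method == "parsimony") paste0("; parsimony score ", x$total_score),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate per-branch substitution events
#'
#' One event wherever the reconstructed (representative) state of a branch's
#' parent differs from that of its child, both being resolved. With
#' ties in the underlying reconstruction the deterministic representative
#' rule applies, so the event list is reproducible.
#'
#' @param anc An `"aa_ancestral"` reconstruction.
#' @return Data.frame: child (node id of the branch), parent, site,
#'   from, to.
#' @export
enumerate_substitutions <- function(anc) {
  stopifnot(inherits(anc, "aa_ancestral"))
  edge <- anc$tree$edge
  rows <- list()
  for (e in seq_len(nrow(edge))) {
    pa <- edge[e, 1]; ch <- edge[e, 2]
    f <- anc$states[pa, ]; t <- anc$states[ch, ]
    sel <- which(!is.na(f) & !is.na(t) & f != t)
    if (length(sel))
      rows[[length(rows) + 1L]] <- data.frame(
        child = ch, parent = pa, site = sel, from = f[sel], to = t[sel])
  }
  if (length(rows)) {
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  } else data.frame(child = integer(), parent = integer(), site = integer(),
                    from = character(), to = character())
}

resolve_branch <- function(tree, spec) {
  # branch spec: child node id, a tip label, or >=2 tip labels (MRCA)
  if (is.numeric(spec)) return(as.integer(spec[1]))
  stopifnot(is.character(spec))
  bad <- setdiff(spec, tree$tip.label)
  if (length(bad)) stop("unknown tip label(s): ", paste(bad, collapse = ", "))
  ids <- match(spec, tree$tip.label)
  if (length(ids) == 1L) return(ids)
  ape::getMRCA(tree, ids)
}

ancestor_path <- function(tree, node) {
  edge <- tree$edge
  path <- integer()
  cur <- node
  repeat {
    pa <- edge[match(cur, edge[, 2]), 1]
    if (is.na(pa)) break
    path <- c(path, pa)
    cur <- pa
  }
  path
}

#' Classify convergent versus divergent sites between two branches
#'
#' For amino-acid sites substituted on both compared branches, a site is
#' convergent when both branches end in the same derived state and divergent
#' when the derived states differ. The two branches must be distinct and
#' neither ancestral to the other.
#'
#' @param events Substitution events from [enumerate_substitutions()].
#' @param tree The tree the events were enumerated on (postorder,
#'   `anc$tree`).
#' @param branch_a,branch_b Branch specifications: child node id, a tip
#'   label, or a vector of tip labels naming the branch above their MRCA.
#' @return Object of class `"convergence_report"`: list with `branch_pair`,
#'   `convergent` / `divergent` (data.frames: site, state(s)),
#'   `n_convergent`, `n_divergent`, `n_shared`.
#' @export
detect_convergence <- function(events, tree, branch_a, branch_b) {
  a <- resolve_branch(tree, branch_a)
  b <- resolve_branch(tree, branch_b)
  if (a == b) stop("branches must be distinct")
  if (a %in% ancestor_path(tree, b) || b %in% ancestor_path(tree, a))
    stop("branches are nested (one ancestral to the other); ",
         "convergence between them is not defined")
  ea <- events[events$child == a, ]
  eb <- events[events$child == b, ]
  shared <- intersect(ea$site, eb$site)
  conv <- list(); divg <- list()
  for (s in shared) {
    ta <- ea$to[ea$site == s][1]
    tb <- eb$to[eb$site == s][1]
    if (ta == tb)
      conv[[length(conv) + 1L]] <- data.frame(site = s, state = ta)
    else
      divg[[length(divg) + 1L]] <- data.frame(site = s, state_a = ta,
                                              state_b = tb)
  }
  convergent <- if (length(conv)) do.call(rbind, conv) else
    data.frame(site = integer(), state = character())
  divergent <- if (length(divg)) do.call(rbind, divg) else
    data.frame(site = integer(), state_a = character(), state_b = character())
  structure(list(branch_pair = c(a, b), convergent = convergent,
                 divergent = divergent,
                 n_convergent = nrow(convergent),
                 n_divergent = nrow(divergent),
                 n_shared = length(shared)),
            class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence report for branches above nodes",
      paste(x$branch_pair, collapse = " and "), "\n")
  cat("  sites changed on both branches:", x$n_shared,
      "-", x$n_convergent, "convergent,", x$n_divergent, "divergent\n")
  if (x$n_convergent)
    cat("  convergent sites:", paste(x$convergent$site, collapse = ", "), "\n")
  invisible(x)
}
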