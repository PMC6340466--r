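# Codon-sequence simulation on a tree: exact event-by-event (Gillespie)
# sampling from the continuous-time Markov chain defined by a Goldman-Yang
# generator, with branch-specific omega, optional post-loss neutral evolution
# on the full 64-codon space, and injected loss-of-function lesions. Every
# substitution event is recorded, so downstream stages can be validated
# against the true history.

sim_tables <- function(Q) {
  rates <- -diag(Q)
  n <- nrow(Q)
  Pj <- Q
  diag(Pj) <- 0
  pos <- rates > 0
  Pj[pos, ] <- Pj[pos, ] / rates[pos]
  list(rates = rates, cum = t(apply(Pj, 1, cumsum)), states = rownames(Q))
}

# Evolve a vector of sites (state indices) for duration tlen, with a
# first-waiting-time filter so untouched sites cost one rexp draw.
sim_sites <- function(states, tlen, tab) {
  n <- length(states)
  tw <- stats::rexp(n, pmax(tab$rates[states], 1e-300))
  tw[tab$rates[states] <= 0] <- Inf
  active <- which(tw <= tlen)
  events <- list()
  if (length(active)) {
    for (i in active) {
      # replay the site including the already-drawn first waiting time
      s <- states[i]
      t <- tw[i]
      ev_from <- integer(); ev_to <- integer(); ev_t <- numeric()
      while (t <= tlen) {
        u <- stats::runif(1L)
        s_new <- findInterval(u, tab$cum[s, ]) + 1L
        ev_from <- c(ev_from, s); ev_to <- c(ev_to, s_new); ev_t <- c(ev_t, t)
        s <- s_new
        r <- tab$rates[s]
        if (r <= 0) break
        t <- t + stats::rexp(1L, r)
      }
      states[i] <- s
      if (length(ev_from))
        events[[length(events) + 1L]] <-
          data.frame(site = i, time = ev_t,
                     from = tab$states[ev_from], to = tab$states[ev_to])
    }
  }
  list(states = states, events = if (length(events))
    do.call(rbind, events) else NULL)
}

resolve_edge_omegas <- function(tree_po, omega, foreground = NULL) {
  nedge <- nrow(tree_po$edge)
  if (length(omega) == 1L && is.null(names(omega)))
    return(rep(unname(omega), nedge))
  if (!is.null(foreground)) {
    stopifnot(length(omega) == 2L)
    om <- if (!is.null(names(omega)) && all(c("background", "foreground") %in% names(omega)))
      omega[c("background", "foreground")] else omega
    fg <- if (is.character(foreground)) edges_for_tips(tree_po, foreground)
          else as.integer(foreground)
    w <- rep(unname(om[1]), nedge)
    w[tree_po$edge[, 2] %in% fg] <- unname(om[2])
    return(w)
  }
  if (!is.null(names(omega))) {
    ids <- as.integer(names(omega))
    m <- match(tree_po$edge[, 2], ids)
    if (anyNA(m)) stop("omega missing for child node(s): ",
                       paste(tree_po$edge[is.na(m), 2], collapse = ", "))
    return(unname(omega)[m])
  }
  stopifnot(length(omega) == nedge)
  unname(omega)
}

#' Simulate a codon alignment on a tree
#'
#' Evolves codon sequences along a tree under a Goldman-Yang model with
#' branch-specific omega, by exact Gillespie sampling of the substitution
#' process. The root sequence is drawn from the codon equilibrium frequencies
#' (stop codons excluded); every substitution event is recorded.
#'
#' @param tree [ape::phylo] tree with branch lengths in expected
#'   substitutions per codon site (under each branch's own matrix for
#'   `scale = "expected"`, or in neutral-clock units for
#'   `scale = "neutral"`).
#' @param n_codons Number of codon sites (>= 1).
#' @param kappa Transition/transversion ratio.
#' @param omega Scalar omega for the whole tree; or a length-2
#'   (background, foreground) pair together with `foreground`; or a vector
#'   named by child node id.
#' @param foreground Optional foreground branch set (tip labels or child node
#'   ids) when `omega` has two entries.
#' @param freqs `"uniform"`, or a named codon frequency vector over the sense
#'   codons.
#' @param seed Optional integer seed (identical seeds give identical output).
#' @param scale Generator scaling convention, see [codon_rate_matrix()].
#' @param code A [genetic_code()].
#' @return Object of class `"codon_sim"`: list with `alignment` (a
#'   [codon_alignment()] of the tip sequences), `history` (data.frame of true
#'   substitution events: child node, site, time within branch, from, to),
#'   `tree` (postorder), `node_seqs` (all node sequences) and the parameters.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, omega = 0.2,
                                     foreground = NULL, freqs = "uniform",
                                     seed = NULL,
                                     scale = c("expected", "neutral"),
                                     code = genetic_code()) {
  scale <- match.arg(scale)
  stopifnot(n_codons >= 1)
  validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  nedge <- nrow(tree_po$edge)
  ntip <- length(tree_po$tip.label)
  omega_e <- resolve_edge_omegas(tree_po, omega, foreground)
  if (any(omega_e < 0)) stop("negative omega")

  pi_vec <- if (identical(freqs, "uniform")) NULL else freqs
  uom <- unique(omega_e)
  tabs <- lapply(uom, function(w)
    sim_tables(codon_rate_matrix(kappa, w, freqs = pi_vec, code = code,
                                 scale = scale)))
  st <- tabs[[1]]$states
  pi_draw <- if (is.null(pi_vec)) rep(1 / length(st), length(st)) else
    unname(pi_vec[st])

  node_states <- matrix(NA_integer_, ntip + tree_po$Nnode, n_codons)
  root <- ntip + 1L
  node_states[root, ] <- sample.int(length(st), n_codons, replace = TRUE,
                                    prob = pi_draw)
  hist <- list()
  for (e in rev(seq_len(nedge))) {   # preorder
    pa <- tree_po$edge[e, 1]; ch <- tree_po$edge[e, 2]
    tab <- tabs[[match(omega_e[e], uom)]]
    res <- sim_sites(node_states[pa, ], tree_po$edge.length[e], tab)
    node_states[ch, ] <- res$states
    if (!is.null(res$events)) {
      res$events$child <- ch
      hist[[length(hist) + 1L]] <- res$events
    }
  }
  seqs <- apply(node_states, 1, function(s) paste(st[s], collapse = ""))
  tips <- seqs[seq_len(ntip)]
  names(tips) <- tree_po$tip.label
  history <- if (length(hist)) do.call(rbind, hist)[, c("child", "site", "time",
                                                        "from", "to")]
             else data.frame(child = integer(), site = integer(),
                             time = numeric(), from = character(),
                             to = character())
  structure(list(
    alignment = codon_alignment(tips, code = code),
    history = history, tree = tree_po,
    node_seqs = stats::setNames(seqs, c(tree_po$tip.label,
                                        paste0("node", (ntip + 1L):(ntip + tree_po$Nnode)))),
    kappa = kappa, omega = omega_e, freqs = freqs, scale = scale
  ), class = "codon_sim")
}

#' @export
print.codon_sim <- function(x, ...) {
  cat("Simulated codon alignment:", length(x$alignment$seqs), "tips x",
      x$alignment$n_codon, "codons;", nrow(x$history), "substitution events\n")
  invisible(x)
}

# --- lesion injection -------------------------------------------------------

#' Inject loss-of-function lesions into an alignment
#'
#' Applies a table of lesions to a codon alignment: deletions replace bases
#' with gap characters (alignment length preserved); insertions add a gapped
#' column block to all other rows; `stop_substitution` rewrites one codon to
#' a stop (`TAA`). The returned ground-truth table records each lesion in the
#' coordinates of the *returned* alignment (codon column = alignment
#' nucleotide column / 3, the convention used by [scan_orf()]), with
#' `stop_substitution` reported as `premature_stop`.
#'
#' @param aln A [codon_alignment()].
#' @param lesions Data.frame with columns `taxon`, `kind`
#'   (`deletion` / `insertion` / `stop_substitution`), `position` (codon
#'   column in the input alignment) and `length_nt` (ignored for stops).
#' @param insert_bases Bases used to fill insertions (recycled; default
#'   `"A"`, keeping the injection deterministic).
#' @return List with `alignment` (gap-containing [codon_alignment()]) and
#'   `lesions` (the ground-truth table: taxon, kind, codon_column, length_nt,
#'   causes_frameshift).
#' @export
inject_lesions <- function(aln, lesions, insert_bases = "A") {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(lesions) || nrow(lesions) == 0L)
    return(list(alignment = aln,
                lesions = data.frame(taxon = character(), kind = character(),
                                     codon_column = integer(),
                                     length_nt = integer(),
                                     causes_frameshift = logical())))
  need <- c("taxon", "kind", "position", "length_nt")
  stopifnot(all(need %in% names(lesions)))
  lesions$length_nt[lesions$kind == "stop_substitution"] <- 3L
  bad_tax <- setdiff(lesions$taxon, names(aln$seqs))
  if (length(bad_tax)) stop("lesion taxa not in alignment: ",
                            paste(bad_tax, collapse = ", "))
  if (any(lesions$position < 1L | lesions$position > aln$n_codon))
    stop("lesion position outside alignment")
  if (any(lesions$length_nt < 1L)) stop("length_nt must be >= 1")

  # overlap check per taxon on input nt coordinates
  nt_start <- 3L * (lesions$position - 1L) + 1L
  nt_end <- ifelse(lesions$kind == "insertion", nt_start - 1L,
                   nt_start + lesions$length_nt - 1L)
  for (tx in unique(lesions$taxon)) {
    sel <- which(lesions$taxon == tx)
    if (length(sel) > 1L) {
      o <- order(nt_start[sel])
      s <- nt_start[sel][o]; e <- pmax(nt_end[sel][o], nt_start[sel][o])
      if (any(s[-1] <= e[-length(e)]))
        stop("overlapping lesions on taxon ", tx)
    }
  }

  rows <- strsplit(aln$seqs, "")
  # non-insertion lesions first (coordinates unaffected)
  for (i in which(lesions$kind != "insertion")) {
    tx <- lesions$taxon[i]
    s <- nt_start[i]; e <- nt_end[i]
    if (e > aln$length) stop("lesion runs past alignment end")
    if (lesions$kind[i] == "deletion") {
      rows[[tx]][s:e] <- "-"
    } else { # stop_substitution
      rows[[tx]][s:(s + 2L)] <- c("T", "A", "A")
    }
  }
  # insertions, right to left so earlier coordinates stay valid
  ins <- which(lesions$kind == "insertion")
  fill <- strsplit(insert_bases, "")[[1]]
  shift_of <- rep(0L, nrow(lesions))   # coordinate shift applied to each lesion
  if (length(ins)) {
    if (anyDuplicated(nt_start[ins]))
      stop("two insertions at the same position are not supported")
    for (i in ins[order(nt_start[ins], decreasing = TRUE)]) {
      s <- nt_start[i]; L <- lesions$length_nt[i]
      block_ins <- rep_len(fill, L)
      block_gap <- rep("-", L)
      for (tx in names(rows)) {
        block <- if (tx == lesions$taxon[i]) block_ins else block_gap
        rows[[tx]] <- append(rows[[tx]], block, after = s - 1L)
      }
    }
    for (i in seq_len(nrow(lesions))) {
      earlier <- ins[nt_start[ins] < nt_start[i] |
                       (nt_start[ins] == nt_start[i] & lesions$kind[i] != "insertion")]
      shift_of[i] <- sum(lesions$length_nt[earlier])
    }
  }
  seqs <- vapply(rows, paste, character(1), collapse = "")
  new_len <- unique(nchar(seqs))
  out_aln <- codon_alignment(seqs, code = aln$code, gap_char = aln$gap_char,
                             frame_strict = new_len %% 3L == 0L)
  truth <- data.frame(
    taxon = lesions$taxon,
    kind = ifelse(lesions$kind == "stop_substitution", "premature_stop",
                  lesions$kind),
    codon_column = (nt_start + shift_of - 1L) %/% 3L + 1L,
    length_nt = lesions$length_nt,
    causes_frameshift = lesions$kind != "stop_substitution" &
      lesions$length_nt %% 3L != 0L,
    stringsAsFactors = FALSE)
  list(alignment = out_aln, lesions = truth)
}

# --- pseudogenisation -------------------------------------------------------

node_ages <- function(tree) {
  # ages in the tree's length unit, measured back from the youngest tip
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Simulate pseudogenisation with sudden relaxation of constraint
#'
#' Evolves a codon alignment on a time tree (branch lengths in My) in which
#' selected lineages lose all selective constraint at a stated age: ancestral
#' to the loss point the chain runs on the sense codons with the background
#' omega; after the loss it runs neutrally (omega = 1) on all 64 codons, with
#' changes involving stop codons treated as neutral. The generator is scaled
#' so the neutral substitution rate is `rate` substitutions/site/My in both
#' eras, which keeps the synonymous clock era-independent - the assumption
#' the sudden-relaxation dating equation rests on. If a dead lineage reaches
#' its tip without a stop codon, one codon is rewritten to `TAA` so the
#' lesion scanner has something to find (recorded in the truth table).
#'
#' @param tree Ultrametric-ish [ape::phylo] time tree, branch lengths in My.
#' @param loss Data.frame with columns `lineage` (tip label or node id; the
#'   loss happens on the branch above it) and `age` (My before present; must
#'   lie within that branch's span).
#' @param n_codons Number of codon sites.
#' @param kappa,omega Background model parameters (omega as in
#'   [simulate_codon_alignment()]).
#' @param rate Neutral substitution rate in substitutions/site/My
#'   (default 0.005).
#' @param freqs `"uniform"` or named codon frequencies (sense codons).
#' @param seed Optional seed.
#' @param code A [genetic_code()].
#' @return List with `alignment`, `truth` (lineage, child node, loss age,
#'   true time-since-loss `T_p` at the tip(s), loss-branch duration `T`,
#'   whether a stop had to be injected), `tree` (postorder) and parameters.
#' @export
simulate_pseudogenization <- function(tree, loss, n_codons, kappa = 2,
                                      omega = 0.2, rate = 0.005,
                                      freqs = "uniform", seed = NULL,
                                      code = genetic_code()) {
  validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(loss)))
    loss <- data.frame(lineage = names(loss), age = as.numeric(loss))
  tree_po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree_po$tip.label)
  nedge <- nrow(tree_po$edge)
  ages <- node_ages(tree_po)
  omega_e <- resolve_edge_omegas(tree_po, omega)

  loss$child <- ifelse(loss$lineage %in% tree_po$tip.label,
                       match(loss$lineage, tree_po$tip.label),
                       suppressWarnings(as.integer(loss$lineage)))
  if (anyNA(loss$child)) stop("unknown loss lineage(s)")
  parent_of <- function(ch) tree_po$edge[match(ch, tree_po$edge[, 2]), 1]
  for (i in seq_len(nrow(loss))) {
    pa <- parent_of(loss$child[i])
    if (is.na(pa)) stop("loss cannot be placed on the root")
    if (loss$age[i] < ages[loss$child[i]] - 1e-9 ||
        loss$age[i] > ages[pa] + 1e-9)
      stop(sprintf("loss age %.3f outside branch span [%.3f, %.3f] for %s",
                   loss$age[i], ages[loss$child[i]], ages[pa],
                   loss$lineage[i]))
  }

  desc <- node_descendant_tips(tree_po)
  below_loss <- rep(FALSE, ntip + tree_po$Nnode)   # nodes at/below a loss child
  for (ch in loss$child) {
    below_loss[ch] <- TRUE
    for (e in rev(seq_len(nedge))) {   # preorder propagation
      pa <- tree_po$edge[e, 1]; c2 <- tree_po$edge[e, 2]
      if (below_loss[pa]) below_loss[c2] <- TRUE
    }
  }

  pi_vec <- if (identical(freqs, "uniform")) NULL else freqs
  uom <- unique(omega_e)
  tabs_bg <- lapply(uom, function(w)
    sim_tables(codon_rate_matrix(kappa, w, freqs = pi_vec, code = code,
                                 scale = "neutral")))
  tab_dead <- sim_tables(codon_rate_matrix(kappa, 1, freqs = NULL, code = code,
                                           scale = "neutral", states = "all64"))
  st61 <- tabs_bg[[1]]$states
  st64 <- tab_dead$states
  pi_draw <- if (is.null(pi_vec)) rep(1 / length(st61), length(st61)) else
    unname(pi_vec[st61])

  # states held as codon strings so the two state spaces interoperate
  node_seq <- vector("list", ntip + tree_po$Nnode)
  root <- ntip + 1L
  node_seq[[root]] <- st61[sample.int(length(st61), n_codons, TRUE, pi_draw)]
  loss_on_edge <- match(tree_po$edge[, 2], loss$child)  # row of loss or NA

  for (e in rev(seq_len(nedge))) {   # preorder
    pa <- tree_po$edge[e, 1]; ch <- tree_po$edge[e, 2]
    dur <- tree_po$edge.length[e]
    s0 <- node_seq[[pa]]
    li <- loss_on_edge[e]
    if (!is.na(li)) {
      t_pre <- (ages[pa] - loss$age[li]) * rate
      t_post <- (loss$age[li] - ages[ch]) * rate
      tab <- tabs_bg[[match(omega_e[e], uom)]]
      r1 <- sim_sites(match(s0, st61), t_pre, tab)
      mid <- st61[r1$states]
      r2 <- sim_sites(match(mid, st64), t_post, tab_dead)
      node_seq[[ch]] <- st64[r2$states]
    } else if (below_loss[pa]) {
      r <- sim_sites(match(s0, st64), dur * rate, tab_dead)
      node_seq[[ch]] <- st64[r$states]
    } else {
      tab <- tabs_bg[[match(omega_e[e], uom)]]
      r <- sim_sites(match(s0, st61), dur * rate, tab)
      node_seq[[ch]] <- st61[r$states]
    }
  }

  injected <- logical(nrow(loss))
  stops <- code$stop_codons
  for (i in seq_len(nrow(loss))) {
    for (tip in intersect(desc[[loss$child[i]]], seq_len(ntip))) {
      if (!any(node_seq[[tip]] %in% stops)) {
        # place the guaranteed lesion well inside the ORF so it is an
        # unambiguous disruption, not a tolerated C-terminal truncation
        hi <- max(2L, floor(0.8 * n_codons))
        pos <- if (hi > 2L) sample(2:hi, 1L) else 2L
        node_seq[[tip]][pos] <- "TAA"
        injected[i] <- TRUE
      }
    }
  }

  tips <- vapply(seq_len(ntip), function(i) paste(node_seq[[i]], collapse = ""),
                 character(1))
  names(tips) <- tree_po$tip.label
  truth <- data.frame(
    lineage = loss$lineage, child = loss$child, loss_age = loss$age,
    T_p = loss$age - ages[loss$child],
    T = ages[vapply(loss$child, parent_of, numeric(1))] - ages[loss$child],
    injected_stop = injected)
  list(alignment = codon_alignment(tips, code = code), truth = truth,
       tree = tree_po, rate = rate, kappa = kappa, omega = omega_e)
}

# --- simulate() from a fitted model ----------------------------------------

#' Simulate alignments from a fitted codon model
#'
#' Parametric-bootstrap style simulation: draws codon alignments from the
#' fitted parameters on the fitted tree. For branch models omegas follow the
#' fitted branch partition; for site-mixture models each site's omega class
#' is drawn from the fitted mixture first.
#'
#' @param object A `"codon_fit"`.
#' @param nsim Number of replicate alignments.
#' @param seed Optional seed.
#' @param n_codons Number of codon sites (default: as fitted).
#' @param ... Unused.
#' @return A list of `"codon_sim"` objects (length `nsim`).
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = NULL,
                               n_codons = object$n_codons, ...) {
  if (!is.null(seed)) set.seed(seed)
  tree <- object$tree
  nedge <- nrow(tree$edge)
  freqs <- object$freqs
  one <- function() {
    if (object$model %in% c("M0", "two_ratio", "free_ratio")) {
      omega_e <- switch(object$model,
        M0 = rep(object$omega, nedge),
        two_ratio = {
          w <- rep(object$omega[["background"]], nedge)
          w[tree$edge[, 2] %in% object$foreground] <- object$omega[["foreground"]]
          w
        },
        free_ratio = unname(object$omega))
      names(omega_e) <- tree$edge[, 2]
      return(simulate_codon_alignment(tree, n_codons, kappa = object$kappa,
                                      omega = omega_e, freqs = freqs))
    }
    # site models: draw a class per site, simulate class blocks, interleave
    if (object$model %in% c("M7", "M8")) {
      w <- beta_categories(object$beta[["p"]], object$beta[["q"]], object$ncat)
      pr <- rep(1 / object$ncat, object$ncat)
      if (object$model == "M8") {
        w <- c(w, object$omega[["omega_s"]])
        p0 <- object$proportions[["p0"]]
        pr <- c(rep(p0 / object$ncat, object$ncat), 1 - p0)
      }
    } else {
      w <- unname(object$omega)
      pr <- unname(object$proportions)
    }
    cls <- sample.int(length(w), n_codons, TRUE, pr)
    parts <- lapply(unique(cls), function(k)
      simulate_codon_alignment(tree, sum(cls == k), kappa = object$kappa,
                               omega = w[k], freqs = freqs))
    seqs <- stats::setNames(rep("", length(tree$tip.label)), tree$tip.label)
    mats <- lapply(parts, function(p) codon_matrix(p$alignment))
    full <- matrix("", length(tree$tip.label), n_codons,
                   dimnames = list(tree$tip.label, NULL))
    for (j in seq_along(unique(cls)))
      full[, cls == unique(cls)[j]] <- mats[[j]][rownames(full), ]
    aln <- codon_alignment(apply(full, 1, paste, collapse = ""))
    structure(list(alignment = aln, history = NULL, tree = tree,
                   kappa = object$kappa, omega = w, freqs = freqs,
                   site_class = cls), class = "codon_sim")
  }
  replicate(nsim, one(), simplify = FALSE)
}

# --- fixture presets --------------------------------------------------------

#' Bundled synthetic study presets
#'
#' Two 12-taxon synthetic fixtures mirroring the contrast groups of a
#' bat-opsin style analysis: an ultrametric 40-My time tree with one
#' high-duty-cycle ("hdc") echolocator clade, two cave-roosting lineages and
#' a diet annotation, plus suggested pseudogene loss events. These are
#' synthetic constructions for exercising the pipeline, not estimates for
#' any real taxa.
#'
#' @param name `"pteropodid_like"` (losses on the cave-roosting lineages) or
#'   `"mormoopid_like"` (loss inside the hdc clade).
#' @return List with `tree` (My), `tags` (annotation data.frame), `loss`
#'   (loss-event data.frame for [simulate_pseudogenization()]), and
#'   `background_omega`.
#' @export
opsin_preset <- function(name = c("pteropodid_like", "mormoopid_like")) {
  name <- match.arg(name)
  nw <- paste0(
    "((((sp01:5,sp02:5):10,(sp03:8,sp04:8):7):15,((sp05:10,sp06:10):12,",
    "(sp07:6,sp08:6):16):8):10,((sp09:12,sp10:12):13,(sp11:9,sp12:9):16):15);")
  tree <- read_newick(text = nw)
  tags <- data.frame(
    taxon = sprintf("sp%02d", 1:12),
    hdc  = sprintf("sp%02d", 1:12) %in% c("sp05", "sp06", "sp07", "sp08"),
    cave = sprintf("sp%02d", 1:12) %in% c("sp09", "sp10"),
    insectivore = sprintf("sp%02d", 1:12) %in%
      c("sp01", "sp02", "sp05", "sp06", "sp07", "sp08"),
    stringsAsFactors = FALSE)
  loss <- switch(name,
    pteropodid_like = data.frame(lineage = c("sp09", "sp10"),
                                 age = c(8, 6)),
    mormoopid_like = data.frame(lineage = "sp05", age = 7))
  list(tree = tree, tags = tags, loss = loss, background_omega = 0.15,
       name = name)
}
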