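# Dating loss of selective constraint under the sudden-relaxation model:
# constraint at omega_f up to the loss, strictly neutral (omega = 1) after.
# Because the synonymous clock is era-independent, the dN/dS ratio observed
# over a branch of duration T that lost constraint T_p ago is the
# time-weighted mixture
#     omega_m * T = omega_f * (T - T_p) + 1 * T_p
# which solves to  T_p = T * (omega_m - omega_f) / (1 - omega_f).

#' Categorise branches around pseudogenisation events
#'
#' Given the origin branches of first-appearance lesions (from
#' [place_lesions()]), branches are classed as: `nonfunctional` (wholly below
#' a lesion origin), `mixed` (the origin branch itself, containing both a
#' functional and a pseudogenic era), `premutation` (ancestral to an origin
#' with all descendant tips pseudogenised - constraint may already have been
#' lost before the first surviving lesion), and `functional` (everything
#' else). With no origins every branch is functional.
#'
#' @param tree An [ape::phylo] tree.
#' @param origins Integer child-node ids of lesion-origin branches, or a
#'   [place_lesions()] table (non-homoplastic origins are used).
#' @return Data.frame: child, parent, category.
#' @export
categorize_branches <- function(tree, origins) {
  validate_tree(tree, require_lengths = FALSE)
  if (is.data.frame(origins))
    origins <- unique(origins$origin_child[!is.na(origins$origin_child) &
                                             !origins$homoplastic])
  origins <- as.integer(origins)
  tree_po <- ape::reorder.phylo(tree, "postorder")
  edge <- tree_po$edge
  ntip <- length(tree_po$tip.label)
  nn <- ntip + tree_po$Nnode
  desc <- node_descendant_tips(tree_po)
  below <- rep(FALSE, nn)       # strictly below an origin branch
  for (og in origins) {
    if (!og %in% edge[, 2] && og != ntip + 1L)
      stop("origin child id not in tree: ", og)
    for (e in rev(seq_len(nrow(edge)))) {
      pa <- edge[e, 1]; ch <- edge[e, 2]
      if (pa == og || below[pa]) below[ch] <- TRUE
    }
  }
  pseudo_tips <- unique(unlist(lapply(origins, function(og) desc[[og]])))
  cat_of <- character(nrow(edge))
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2]
    cat_of[e] <-
      if (ch %in% origins) "mixed"
      else if (below[ch]) "nonfunctional"
      else if (length(pseudo_tips) && all(desc[[ch]] %in% pseudo_tips))
        "premutation"
      else "functional"
  }
  data.frame(child = edge[, 2], parent = edge[, 1], category = cat_of)
}

#' Time since relaxation of constraint on a mixed branch
#'
#' Solves the sudden-relaxation equation
#' `T_p = T * (omega_m - omega_f) / (1 - omega_f)` for the duration of the
#' neutral era, where `omega_m` is the dN/dS observed over the whole branch,
#' `omega_f` the constraint-era dN/dS taken from functional relatives, and
#' `T` the branch duration in My. Results outside `[0, T]` (sampling noise)
#' are clamped and flagged.
#'
#' @param omega_m Observed mixed-branch dN/dS (vectorised).
#' @param omega_f Functional-era dN/dS, `0 <= omega_f < 1`.
#' @param T Branch duration (My), > 0.
#' @return Numeric vector `T_p` (My) with logical attribute `clamped`.
#' @examples
#' date_relaxation(0.5116, 0.111, 30)   # ~13.5 My
#' @export
date_relaxation <- function(omega_m, omega_f, T) {
  if (any(omega_f >= 1)) stop("omega_f >= 1: no constraint era to date against")
  if (any(omega_f < 0) || any(omega_m < 0)) stop("omega values must be >= 0")
  if (any(T <= 0)) stop("branch duration T must be > 0")
  raw <- T * (omega_m - omega_f) / (1 - omega_f)
  out <- pmin(pmax(raw, 0), T)
  attr(out, "clamped") <- raw < 0 | raw > T
  out
}

#' Resolve mixed branches into functional and pseudogenic eras
#'
#' Applies [date_relaxation()] to every mixed branch of a calibrated time
#' tree: the branch duration `T` comes from the node ages, `omega_f` from
#' the functional branch category, and `omega_m` from the mixed branch's own
#' dN/dS estimate. The loss date (Ma before present) is the branch start
#' minus the functional era, equivalently the branch end plus `T_p`. When a
#' nonfunctional-category dN/dS is supplied it is reported as a diagnostic
#' (it should be close to 1 under the sudden-relaxation model).
#'
#' @param tree Calibrated [ape::phylo] tree, branch lengths in My.
#' @param categories Output of [categorize_branches()].
#' @param omega_f Functional-category dN/dS (scalar).
#' @param omega_m Mixed-branch dN/dS: scalar, or vector named by mixed-branch
#'   child node id.
#' @param omega_nonfunctional Optional nonfunctional-category dN/dS
#'   (diagnostic only).
#' @return Data.frame: lineage (tip label or node id), child, T, omega_f,
#'   omega_m, T_p, T_f, loss_age_Ma, clamped. Attribute
#'   `nonfunctional_omega` carries the diagnostic when supplied. Mixed
#'   branches without an omega_m are skipped with a warning.
#' @export
resolve_mixed <- function(tree, categories, omega_f, omega_m,
                          omega_nonfunctional = NULL) {
  tree_po <- ape::reorder.phylo(tree, "postorder")
  ages <- node_ages(tree_po)
  ntip <- length(tree_po$tip.label)
  mixed <- categories[categories$category == "mixed", ]
  if (!nrow(mixed)) {
    warning("no mixed branches to resolve")
    return(data.frame())
  }
  rows <- list()
  for (i in seq_len(nrow(mixed))) {
    ch <- mixed$child[i]; pa <- mixed$parent[i]
    wm <- if (length(omega_m) == 1L && is.null(names(omega_m)))
      unname(omega_m) else unname(omega_m[as.character(ch)])
    if (is.na(wm) || is.null(wm)) {
      warning("no omega_m for mixed branch above node ", ch, "; skipped")
      next
    }
    T <- ages[pa] - ages[ch]
    tp <- date_relaxation(wm, omega_f, T)
    rows[[length(rows) + 1L]] <- data.frame(
      lineage = if (ch <= ntip) tree_po$tip.label[ch] else paste0("node", ch),
      child = ch, T = T, omega_f = omega_f, omega_m = wm,
      T_p = as.numeric(tp), T_f = T - as.numeric(tp),
      loss_age_Ma = ages[ch] + as.numeric(tp),
      clamped = attr(tp, "clamped"))
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "nonfunctional_omega") <- omega_nonfunctional
  out
}
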