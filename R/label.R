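# Branch labelling: mapping tip-level trait annotations onto foreground /
# background branch partitions for the two-ratio codon models.

node_descendant_tips <- function(tree) {
  # list indexed by node id -> integer vector of descendant tip ids
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  res <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) res[[i]] <- i
  for (e in seq_len(nrow(tree$edge))) {
    pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    res[[pa]] <- c(res[[pa]], res[[ch]])
  }
  res
}

#' Branches implied by a set of tagged tips
#'
#' A branch is selected when every tip descending from it belongs to `tips`.
#' Terminal branches of tagged tips are always selected; internal branches are
#' selected only when their whole clade is tagged (so a single tagged tip
#' selects only its own terminal branch, and a paraphyletic tag set selects
#' each maximal all-tagged clade plus its internal branches).
#'
#' @param tree An [ape::phylo] tree.
#' @param tips Character vector of tip labels.
#' @return Integer vector of branch child-node ids.
#' @export
edges_for_tips <- function(tree, tips) {
  missing_tips <- setdiff(tips, tree$tip.label)
  if (length(missing_tips))
    stop("tips not in tree: ", paste(missing_tips, collapse = ", "))
  tip_ids <- match(tips, tree$tip.label)
  desc <- node_descendant_tips(tree)
  nn <- length(tree$tip.label) + tree$Nnode
  sel <- vapply(seq_len(nn), function(v) all(desc[[v]] %in% tip_ids), logical(1))
  sel[seq_along(tree$tip.label)] <- seq_along(tree$tip.label) %in% tip_ids
  children <- tree$edge[, 2]
  children[sel[children]]
}

#' Attach foreground/background branch tags to a tree
#'
#' Reads per-tip trait columns from an annotation table (see
#' [read_annotation()]) and tags branches: a branch carries a tag when all of
#' its descendant tips carry it. The tagging is attached to the tree as the
#' `"branch_tags"` attribute, a data.frame of (child node id, tag), and is
#' consumed by [fit_codon_model()] two-ratio fits via `foreground = "<tag>"`.
#'
#' @param tree An [ape::phylo] tree.
#' @param annotation Data.frame with a `taxon` column plus trait columns.
#'   Trait columns may be logical, 0/1, or `"yes"/"no"`.
#' @param tags Which trait columns to use (default: all non-taxon columns).
#' @return The tree, with a `"branch_tags"` attribute.
#' @export
label_branches <- function(tree, annotation, tags = NULL) {
  stopifnot(inherits(tree, "phylo"), is.data.frame(annotation))
  if (!"taxon" %in% names(annotation)) names(annotation)[1] <- "taxon"
  if (is.null(tags)) tags <- setdiff(names(annotation), "taxon")
  missing_tags <- setdiff(tags, names(annotation))
  if (length(missing_tags))
    stop("tag(s) absent from annotation: ", paste(missing_tags, collapse = ", "))
  truthy <- function(x) {
    if (is.logical(x)) return(!is.na(x) & x)
    if (is.numeric(x)) return(!is.na(x) & x != 0)
    tolower(trimws(as.character(x))) %in% c("yes", "true", "1", "y")
  }
  rows <- lapply(tags, function(tg) {
    tagged <- annotation$taxon[truthy(annotation[[tg]])]
    tagged <- intersect(tagged, tree$tip.label)
    if (!length(tagged)) return(NULL)
    data.frame(child = edges_for_tips(tree, tagged), tag = tg,
               stringsAsFactors = FALSE)
  })
  attr(tree, "branch_tags") <- do.call(rbind, rows)
  tree
}

#' Branch child-node ids carrying a tag
#'
#' @param tree A tree processed by [label_branches()].
#' @param tag Tag name.
#' @return Integer vector of child node ids.
#' @export
tagged_branches <- function(tree, tag) {
  bt <- attr(tree, "branch_tags")
  if (is.null(bt)) stop("tree has no branch tags; run label_branches() first")
  out <- bt$child[bt$tag == tag]
  if (!length(out)) stop("tag '", tag, "' not present on any branch")
  out
}
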