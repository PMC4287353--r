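#' Non-trivial bipartitions of a tree
#'
#' Treats the tree as unrooted and returns its non-trivial splits of the leaf
#' set. Each internal edge splits the leaves in two; a split is represented
#' canonically by the side that does not contain the alphabetically first
#' leaf, sorted and collapsed to a single string. Trivial splits (one leaf on
#' a side) are excluded, as is the root split duplicate of a rooted binary
#' tree.
#'
#' @param tree An [ape::phylo] object, an [stats::hclust] object, or a Newick
#'   string.
#' @return Character vector of canonical split keys (unordered set).
#' @export
tree_bipartitions <- function(tree) {
  phy <- as_phylo_tree(tree)
  tips <- phy$tip.label
  n <- length(tips)
  if (n < 4L) return(character(0))
  ref <- sort(tips)[1L]
  ntot <- n + phy$Nnode
  # leaf sets by postorder accumulation over the edge matrix
  children <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(ntot)))
  clade <- vector("list", ntot)
  fill <- function(node) {
    if (node <= n) return(tips[node])
    out <- unlist(lapply(children[[node]], fill), use.names = FALSE)
    clade[[node]] <<- out
    out
  }
  root <- setdiff(unique(phy$edge[, 1L]), phy$edge[, 2L])[1L]
  fill(root)
  splits <- character(0)
  for (node in setdiff(which(!vapply(clade, is.null, logical(1))), root)) {
    side <- clade[[node]]
    if (length(side) <= 1L || length(side) >= n - 1L) next  # trivial unrooted
    if (ref %in% side) side <- setdiff(tips, side)
    splits <- c(splits, paste(sort(side), collapse = "\r"))
  }
  unique(splits)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "hclust")) return(read_newick(text = to_newick(tree)))
  if (is.character(tree) && length(tree) == 1L) {
    return(read_newick(text = tree))
  }
  stop("tree must be a phylo, hclust, or Newick string", call. = FALSE)
}

#' Robinson-Foulds distance between two trees
#'
#' Compares the branching patterns of two trees on the same leaf set,
#' treating both as unrooted: the RF distance is the size of the symmetric
#' difference of their non-trivial bipartition sets. The normalized variant
#' divides by `2(n - 3)`, the maximum for two binary trees on `n` leaves.
#'
#' @param t1,t2 Trees ([ape::phylo], [stats::hclust], or Newick strings) on
#'   identical leaf sets.
#' @return List with `rf` (non-negative integer), `normalized` (in `[0, 1]`,
#'   `NA` when `n < 4`), and `n_leaves`.
#' @export
#' @examples
#' rf_distance("((A,B),(C,D));", "((A,C),(B,D));")$rf  # 2
rf_distance <- function(t1, t2) {
  p1 <- as_phylo_tree(t1)
  p2 <- as_phylo_tree(t2)
  l1 <- sort(p1$tip.label)
  l2 <- sort(p2$tip.label)
  if (!identical(l1, l2)) {
    diff <- union(setdiff(l1, l2), setdiff(l2, l1))
    stop("trees have different leaf sets; symmetric difference: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  b1 <- tree_bipartitions(p1)
  b2 <- tree_bipartitions(p2)
  rf <- length(setdiff(b1, b2)) + length(setdiff(b2, b1))
  n <- length(l1)
  list(rf = rf,
       normalized = if (n >= 4L) rf / (2 * (n - 3)) else NA_real_,
       n_leaves = n)
}
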