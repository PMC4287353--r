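#' Ward hierarchical clustering of an LMS distance matrix
#'
#' Runs agglomerative clustering with Ward's minimum-variance criterion in
#' its classic form: the Lance-Williams Ward update applied directly to the
#' supplied distances (`stats::hclust(method = "ward.D")`, the behaviour of
#' the original `"ward"` method of hclust). The input must satisfy the LMS
#' distance-matrix invariants: symmetric, zero diagonal, entries in
#' `[0, 1]`.
#'
#' @param d Symmetric numeric matrix with identifier dimnames, or a
#'   [stats::dist] object with entries in `[0, 1]`.
#' @return An object of class [stats::hclust]. Note that Ward merge heights
#'   may exceed 1 even for distances in `[0, 1]`; [cut_tree()] rescales them.
#' @export
ward_linkage <- function(d) {
  if (inherits(d, "dist")) {
    dd <- d
    vals <- as.vector(d)
    n <- attr(d, "Size")
  } else {
    if (!is.matrix(d) || nrow(d) != ncol(d)) {
      stop("d must be a square matrix or a dist object", call. = FALSE)
    }
    if (max(abs(d - t(d))) > 1e-12) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    if (any(diag(d) != 0)) {
      stop("distance matrix must have a zero diagonal", call. = FALSE)
    }
    dd <- as.dist(d)
    vals <- as.vector(dd)
    n <- nrow(d)
  }
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(vals) || any(vals < 0) || any(vals > 1)) {
    stop("distances must lie in [0, 1]", call. = FALSE)
  }
  hclust(dd, method = "ward.D")
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights: each child branch is
#' the parent's merge height minus the child's own height (leaves sit at
#' height 0), so the depth of every internal node equals its merge height and
#' leaf-to-leaf path lengths are twice the cophenetic heights. Labels that
#' contain characters outside `[A-Za-z0-9_.|/-]` are single-quoted per the
#' Newick convention.
#'
#' @param hc An [stats::hclust] object (e.g. from [ward_linkage()]).
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string, terminated by `";"`.
#' @export
to_newick <- function(hc, digits = 10L) {
  stopifnot(inherits(hc, "hclust"))
  labels <- hc$labels
  if (is.null(labels)) labels <- as.character(seq_len(nrow(hc$merge) + 1L))
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  node_str <- function(node, parent_height) {
    if (node < 0L) {
      paste0(quote_label(labels[-node]), ":", fmt(parent_height))
    } else {
      h <- hc$height[node]
      paste0("(", node_str(hc$merge[node, 1L], h), ",",
             node_str(hc$merge[node, 2L], h), "):",
             fmt(parent_height - h))
    }
  }
  root <- nrow(hc$merge)
  h <- hc$height[root]
  paste0("(", node_str(hc$merge[root, 1L], h), ",",
         node_str(hc$merge[root, 2L], h), ");")
}

quote_label <- function(x) {
  ifelse(grepl("[^A-Za-z0-9_.|/-]", x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] that also strips the single quotes
#' ape leaves on quoted labels, so trees written by [to_newick()] round-trip.
#'
#' @param path Path to a Newick file, or `NULL` if `text` is given.
#' @param text Newick string (alternative to `path`).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input", call. = FALSE)
  unquote <- function(x) {
    q <- grepl("^'.*'$", x)
    x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
    x
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}

#' Cut a dendrogram into flat clusters at a normalized cut-off
#'
#' Merge heights are first rescaled by the maximum merge height, so the root
#' sits at 1; clusters are then the connected components that remain after
#' removing every merge whose rescaled height exceeds `x`. `x = 1` yields a
#' single cluster; `x = 0` yields one cluster per leaf whenever all merge
#' heights are positive. Clusters are numbered 1..K in order of first leaf
#' appearance in the input.
#'
#' @param hc An [stats::hclust] object.
#' @param x Cut-off in `[0, 1]` on the rescaled height axis.
#' @return An object of class `cluster_assignment`: a list with `cutoff`,
#'   `labels` (named integer vector of 1-based cluster indices) and
#'   `n_clusters`.
#' @export
cut_tree <- function(hc, x) {
  stopifnot(inherits(hc, "hclust"))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop("cut-off x must be a number in [0, 1]", call. = FALSE)
  }
  hmax <- max(hc$height)
  labels <- if (hmax <= 0) {
    # all merges at height 0: everything is one cluster at any cut-off
    structure(rep(1L, length(hc$labels)), names = hc$labels)
  } else {
    cutree(hc, h = x * hmax)
  }
  structure(
    list(cutoff = x,
         labels = labels,
         n_clusters = max(labels)),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: ", x$n_clusters, " cluster(s) at cut-off ",
      x$cutoff, " (", length(x$labels), " proteins)\n", sep = "")
  invisible(x)
}
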