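#' Jaccard index of two domain architectures
#'
#' Ratio of shared domain types to distinct domain types across the two
#' proteins: `J = |types(P) intersect types(Q)| / |types(P) union types(Q)|`.
#' Repeated domains count once (copy-number similarity is what
#' [duplication_similarity()] measures). Two empty architectures are
#' trivially identical and score 1.
#'
#' @param p,q Character vectors of domain identifiers in N-to-C order.
#' @return Number in `[0, 1]`.
#' @export
#' @examples
#' jaccard_index(c("A", "B", "C"), c("B", "C", "D"))  # 0.5
jaccard_index <- function(p, q) {
  tp <- unique(as.character(p))
  tq <- unique(as.character(q))
  u <- length(union(tp, tq))
  if (u == 0L) return(1)
  length(intersect(tp, tq)) / u
}

#' Rescaled Goodman-Kruskal gamma of two domain architectures
#'
#' Measures how well the N-terminal-to-C-terminal order of the shared domain
#' types is conserved. Over all unordered pairs of distinct shared types,
#' `S` counts pairs whose relative order (by first occurrence) agrees in both
#' proteins and `R` pairs whose order is reversed; `gamma = (S - R)/(S + R)`
#' is returned rescaled to `[0, 1]` as `(gamma + 1)/2`. When fewer than two
#' types are shared (`S + R = 0`) order conservation is vacuously true and
#' the score is 1.
#'
#' @inheritParams jaccard_index
#' @return Number in `[0, 1]`.
#' @export
#' @examples
#' gk_gamma(c("A", "B", "C"), c("C", "B", "A"))       # 0
#' gk_gamma(c("A", "B", "C", "D"), c("B", "A", "C", "D"))  # 5/6
gk_gamma <- function(p, q) {
  p <- as.character(p)
  q <- as.character(q)
  shared <- intersect(unique(p), unique(q))
  if (length(shared) < 2L) return(1)
  pos_p <- vapply(shared, function(d) match(d, p), integer(1))
  pos_q <- vapply(shared, function(d) match(d, q), integer(1))
  s <- 0L
  r <- 0L
  n <- length(shared)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same <- sign(pos_p[i] - pos_p[j]) == sign(pos_q[i] - pos_q[j])
      if (same) s <- s + 1L else r <- r + 1L
    }
  }
  gamma <- (s - r) / (s + r)
  (gamma + 1) / 2
}

#' Duplication similarity of two domain architectures
#'
#' Compares per-type copy numbers: the mean, over the shared domain types,
#' of `min(c_P, c_Q) / max(c_P, c_Q)` where `c` is the occurrence count of
#' the type in each protein. 1 for identical copy-number profiles over a
#' shared type set (two empty architectures are trivially identical and score
#' 1), 0 when no type is shared.
#'
#' @inheritParams jaccard_index
#' @return Number in `[0, 1]`.
#' @export
#' @examples
#' duplication_similarity(c("A", "A", "B"), c("A", "B"))  # (1/2 + 1)/2
duplication_similarity <- function(p, q) {
  p <- as.character(p)
  q <- as.character(q)
  shared <- intersect(unique(p), unique(q))
  if (length(shared) == 0L) {
    return(if (length(p) == 0L && length(q) == 0L) 1 else 0)
  }
  cp <- table(p)[shared]
  cq <- table(q)[shared]
  mean(pmin(cp, cq) / pmax(cp, cq))
}

#' All three architecture indices for one protein pair
#'
#' @inheritParams jaccard_index
#' @return Named numeric vector `c(jc, gk, ds)`, each in `[0, 1]`.
#' @export
arch_pair_scores <- function(p, q) {
  c(jc = jaccard_index(p, q),
    gk = gk_gamma(p, q),
    ds = duplication_similarity(p, q))
}

#' Per-cluster domain-architecture similarity report
#'
#' For every cluster, computes the Jaccard, rescaled Goodman-Kruskal gamma
#' and duplication-similarity indices over all unordered pairs of members
#' that have a known architecture, and reports the mean and population
#' standard deviation of each index. Members without an architecture are
#' counted but not scored; clusters with fewer than two annotated members
#' get `NA` means and SDs.
#'
#' @param assignment A `cluster_assignment` from [cut_tree()], or a named
#'   integer vector of 1-based cluster indices.
#' @param archs Named list of domain-identifier vectors (see
#'   [read_architectures()]); may cover only a subset of the members.
#' @return A data frame with one row per cluster: `cluster`, `n_members`,
#'   `n_annotated`, `n_pairs`, and `jc_mean`, `jc_sd`, `gk_mean`, `gk_sd`,
#'   `ds_mean`, `ds_sd`.
#' @export
cluster_report <- function(assignment, archs) {
  labels <- if (inherits(assignment, "cluster_assignment")) {
    assignment$labels
  } else {
    assignment
  }
  stopifnot(!is.null(names(labels)))
  n_missing <- sum(!names(labels) %in% names(archs))
  if (n_missing > 0L) {
    message(n_missing, " protein(s) in the clustering have no architecture ",
            "entry and are not scored")
  }
  clusters <- sort(unique(as.integer(labels)))
  rows <- lapply(clusters, function(cl) {
    members <- names(labels)[labels == cl]
    annotated <- members[members %in% names(archs)]
    n_ann <- length(annotated)
    n_pairs <- as.integer(n_ann * (n_ann - 1L) / 2L)
    if (n_pairs == 0L) {
      return(data.frame(cluster = cl, n_members = length(members),
                        n_annotated = n_ann, n_pairs = 0L,
                        jc_mean = NA_real_, jc_sd = NA_real_,
                        gk_mean = NA_real_, gk_sd = NA_real_,
                        ds_mean = NA_real_, ds_sd = NA_real_))
    }
    scores <- matrix(NA_real_, n_pairs, 3L,
                     dimnames = list(NULL, c("jc", "gk", "ds")))
    row <- 0L
    for (i in seq_len(n_ann - 1L)) {
      for (j in (i + 1L):n_ann) {
        row <- row + 1L
        scores[row, ] <- arch_pair_scores(archs[[annotated[i]]],
                                          archs[[annotated[j]]])
      }
    }
    pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
    data.frame(cluster = cl, n_members = length(members),
               n_annotated = n_ann, n_pairs = n_pairs,
               jc_mean = mean(scores[, "jc"]), jc_sd = pop_sd(scores[, "jc"]),
               gk_mean = mean(scores[, "gk"]), gk_sd = pop_sd(scores[, "gk"]),
               ds_mean = mean(scores[, "ds"]), ds_sd = pop_sd(scores[, "ds"]))
  })
  report <- do.call(rbind, rows)
  if (all(report$n_pairs == 0L)) {
    warning("no cluster has two or more annotated members; ",
            "report contains no scores", call. = FALSE)
  }
  report
}

#' Write a cluster architecture-similarity report as TSV
#'
#' @param report Data frame from [cluster_report()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cluster_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
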