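#' Run the full classification pipeline
#'
#' Mirrors the server workflow: read sequences, compute the normalized LMS
#' distance matrix, build the Ward dendrogram, and optionally parse it into
#' clusters at a cut-off and score within-cluster domain-architecture
#' similarity. The distance matrix and the Newick dendrogram are always
#' written; the cluster assignment file requires `cutoff`, and the
#' architecture report requires both `cutoff` and `arch`. All outputs are
#' additionally bundled into a tar archive.
#'
#' @param fasta Path to the input FASTA file.
#' @param arch Optional path to the tab-delimited architecture file.
#' @param cutoff Optional tree-parsing cut-off in `[0, 1]`.
#' @param out_dir Output directory (created if needed).
#' @param k Fragment length (default 5).
#' @param m Substitution matrix (default [blosum62()]).
#' @param archive Whether to bundle outputs into `results.tar`.
#' @param verbose Emit a message per stage.
#' @return Invisibly, a list with the computed objects (`records`,
#'   `distances`, `dendrogram`, and when applicable `assignment`, `report`)
#'   and the vector of written `paths`.
#' @export
run_pipeline <- function(fasta, arch = NULL, cutoff = NULL,
                         out_dir = ".", k = 5L, m = blosum62(),
                         archive = TRUE, verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (!is.null(cutoff) && (cutoff < 0 || cutoff > 1)) {
    stop("cutoff must lie in [0, 1]", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  say("Reading sequences from ", fasta)
  records <- read_fasta(fasta)
  say("  ", length(records), " sequences")

  say("Computing pairwise LMS distances (k = ", k, ")")
  d <- distance_matrix(records, m = m, k = k)
  paths["distances"] <- file.path(out_dir, "distance_matrix.tsv")
  write_distance_matrix(d, paths[["distances"]])

  say("Ward hierarchical clustering")
  hc <- ward_linkage(d)
  paths["dendrogram"] <- file.path(out_dir, "dendrogram.nwk")
  writeLines(to_newick(hc), paths[["dendrogram"]])

  result <- list(records = records, distances = d, dendrogram = hc)

  if (!is.null(cutoff)) {
    say("Cutting tree at x = ", cutoff)
    assignment <- cut_tree(hc, cutoff)
    say("  ", assignment$n_clusters, " clusters")
    if (assignment$n_clusters == length(records) ||
        assignment$n_clusters == 1L) {
      warning("cut-off ", cutoff, " produced a degenerate clustering (",
              assignment$n_clusters, " cluster(s))", call. = FALSE)
    }
    paths["clusters"] <- file.path(out_dir, "clusters.tsv")
    write_cluster_assignments(assignment, paths[["clusters"]])
    result$assignment <- assignment

    if (!is.null(arch)) {
      say("Scoring within-cluster domain-architecture similarity")
      archs <- read_architectures(arch)
      unmatched <- sum(!names(archs) %in% names(records))
      if (unmatched > 0L) {
        say("  ", unmatched, " architecture entries have no matching sequence")
      }
      archs <- archs[names(archs) %in% names(records)]
      report <- cluster_report(assignment, archs)
      paths["report"] <- file.path(out_dir, "architecture_report.tsv")
      write_cluster_report(report, paths[["report"]])
      result$report <- report
    }
  }

  if (archive) {
    tarball <- file.path(out_dir, "results.tar")
    withr::with_dir(out_dir, tar("results.tar", files = basename(paths)))
    paths["archive"] <- tarball
  }
  result$paths <- paths
  say("Done; outputs in ", out_dir)
  invisible(result)
}
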