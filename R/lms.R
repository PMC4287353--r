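#' Enumerate the k-mer fragments of a sequence
#'
#' Builds the index of consecutive k-residue fragments of one sequence: a
#' mapping from each distinct fragment string to the sorted 1-based start
#' positions at which it occurs. A sequence shorter than `k` yields an empty
#' index.
#'
#' @param seq A single amino-acid string.
#' @param k Fragment length; the method's default, and the length used
#'   throughout, is 5.
#' @return Named list of sorted integer start-position vectors.
#' @export
#' @examples
#' fragment_index("ACDEFG")      # ACDEF at 1, CDEFG at 2
#' fragment_index("AAAAAA")      # AAAAA at 1 and 2
fragment_index <- function(seq, k = 5L) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != as.integer(k)) {
    stop("k must be a positive integer", call. = FALSE)
  }
  k <- as.integer(k)
  n <- nchar(seq)
  if (n < k) return(structure(list(), names = character(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  split(starts, factor(kmers, levels = unique(kmers)))
}

# k-mers of one sequence, X-containing ones dropped: unknown residues must
# never create a match (not even against another X).
matchable_kmers <- function(seq, k) {
  idx <- fragment_index(seq, k)
  if (length(idx) == 0L) return(idx)
  idx[!grepl("X", names(idx), fixed = TRUE)]
}

#' Residue positions covered by shared fragments
#'
#' For two sequences, finds every k-mer that occurs (as an exact string) in
#' both, and returns the residue positions of each sequence that lie inside
#' at least one such shared fragment. These covered positions are the
#' "matched" residues whose substitution-score diagonals the local matching
#' score sums. Fragments containing `X` never match.
#'
#' @param a,b Amino-acid strings.
#' @param k Fragment length (default 5).
#' @return List with sorted integer vectors `a` and `b` of 1-based covered
#'   positions; both empty when no fragment is shared.
#' @export
#' @examples
#' matched_coverage("ACDEFGH", "MMACDEFYY")  # a: 1..5, b: 3..7
matched_coverage <- function(a, b, k = 5L) {
  ia <- matchable_kmers(as.character(a), k)
  ib <- matchable_kmers(as.character(b), k)
  shared <- intersect(names(ia), names(ib))
  if (length(shared) == 0L) {
    return(list(a = integer(0), b = integer(0)))
  }
  cover <- function(idx, keys) {
    starts <- unlist(idx[keys], use.names = FALSE)
    sort(unique(as.vector(outer(starts, 0:(as.integer(k) - 1L), `+`))))
  }
  list(a = cover(ia, shared), b = cover(ib, shared))
}

#' Local Matching Score between two sequences
#'
#' Sums the substitution-matrix diagonal score `M[r, r]` over every residue
#' `r` of either sequence that is covered by a shared k-mer (see
#' [matched_coverage()]). Returns 0 when the sequences share no fragment.
#' Exact integer arithmetic throughout.
#'
#' @param a,b Amino-acid strings.
#' @param m Substitution matrix (default [blosum62()]); only its diagonal is
#'   used.
#' @param k Fragment length (default 5).
#' @return Integer score.
#' @export
#' @examples
#' lms_score("ACDEFGH", "MMACDEFYY")  # 60
lms_score <- function(a, b, m = blosum62(), k = 5L) {
  cov <- matched_coverage(a, b, k)
  diag_sum(as.character(a), cov$a, m) + diag_sum(as.character(b), cov$b, m)
}

# Sum of M[r,r] over the residues of seq at the given positions.
diag_sum <- function(seq, positions, m) {
  if (length(positions) == 0L) return(0L)
  res <- strsplit(seq, "", fixed = TRUE)[[1L]][positions]
  bad <- setdiff(unique(res), rownames(m))
  if (length(bad) > 0L) {
    stop("no diagonal score for residue(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sum(as.integer(m[cbind(res, res)]))
}

# Self-score used as the normalization denominator: the full diagonal sum of
# the sequence when it is long enough to contain at least one fragment, else
# 0. X residues count here (with their own diagonal) even though X-containing
# fragments never match.
self_score <- function(seq, m, k) {
  seq <- as.character(seq)
  if (nchar(seq) < k) return(0L)
  diag_sum(seq, seq_len(nchar(seq)), m)
}

#' Normalized LMS distance between two sequences
#'
#' `d(a, b) = 1 - LMS(a, b) / (S(a) + S(b))` where `S(x)` is the full
#' diagonal self-score of `x` (0 for sequences shorter than `k`). The result
#' lies in `[0, 1]`: 0 for identical sequences of length >= `k` over the
#' standard alphabet, 1 when no fragment is shared. When both self-scores
#' vanish (both sequences shorter than `k`, or degenerate all-`X` input) the
#' distance is defined as 1 with a warning.
#'
#' @inheritParams lms_score
#' @return Numeric distance in `[0, 1]`.
#' @export
#' @examples
#' pairwise_distance("ACDEFGH", "MMACDEFYY")  # 1 - 60/98
pairwise_distance <- function(a, b, m = blosum62(), k = 5L) {
  denom <- self_score(a, m, k) + self_score(b, m, k)
  if (denom <= 0L) {
    warning("both self-scores are non-positive; distance defined as 1",
            call. = FALSE)
    return(1)
  }
  d <- 1 - lms_score(a, b, m, k) / denom
  min(max(d, 0), 1)
}

#' Pairwise LMS distance matrix
#'
#' Computes the normalized LMS distance for all unordered pairs of a sequence
#' set. The result is a symmetric matrix with zero diagonal and entries in
#' `[0, 1]`, in the input sequence order.
#'
#' @param records Named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences with unique identifiers.
#' @param m Substitution matrix (default [blosum62()]).
#' @param k Fragment length (default 5).
#' @return Symmetric numeric matrix with identifier dimnames.
#' @export
#' @examples
#' recs <- c(p1 = "ACDEFGH", p2 = "ACDEFGH", p3 = "MMMMMMM")
#' distance_matrix(recs)
distance_matrix <- function(records, m = blosum62(), k = 5L) {
  records <- as_aa_set(records)
  seqs <- as.character(records)
  ids <- names(records)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  validate_score_matrix(m)
  k <- as.integer(k)

  idx <- lapply(seqs, matchable_kmers, k = k)
  selfs <- vapply(seqs, self_score, numeric(1), m = m, k = k,
                  USE.NAMES = FALSE)
  chars <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1L]])
  diags <- lapply(chars, function(cc) as.integer(m[cbind(cc, cc)]))

  d <- matrix(0, n, n, dimnames = list(ids, ids))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- selfs[i] + selfs[j]
      if (denom <= 0) {
        warned <- TRUE
        d[i, j] <- d[j, i] <- 1
        next
      }
      shared <- intersect(names(idx[[i]]), names(idx[[j]]))
      if (length(shared) == 0L) {
        d[i, j] <- d[j, i] <- 1
        next
      }
      num <- coverage_score(idx[[i]], shared, diags[[i]], k) +
        coverage_score(idx[[j]], shared, diags[[j]], k)
      dij <- 1 - num / denom
      d[i, j] <- d[j, i] <- min(max(dij, 0), 1)
    }
  }
  if (warned) {
    warning("some sequence pairs had non-positive self-scores; ",
            "their distance was defined as 1", call. = FALSE)
  }
  d
}

# Diagonal sum over positions covered by the shared k-mers, from a
# precomputed fragment index and per-position diagonal vector.
coverage_score <- function(idx, shared, diag_vec, k) {
  starts <- unlist(idx[shared], use.names = FALSE)
  pos <- unique(as.vector(outer(starts, 0:(k - 1L), `+`)))
  sum(diag_vec[pos])
}
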