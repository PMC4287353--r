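# Independent oracles, deliberately naive: these re-derive expected values by
# brute force and must stay structurally different from the package code they
# check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_seq <- function(len, alphabet = AA20) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Quadratic brute force: compare every k-mer of a against every k-mer of b by
# direct string equality; k-mers containing X never match. Returns the covered
# position sets.
bf_coverage <- function(a, b, k = 5L) {
  la <- nchar(a)
  lb <- nchar(b)
  pos_a <- logical(la)
  pos_b <- logical(lb)
  if (la >= k && lb >= k) {
    for (i in seq_len(la - k + 1L)) {
      ka <- substr(a, i, i + k - 1L)
      if (grepl("X", ka, fixed = TRUE)) next
      for (j in seq_len(lb - k + 1L)) {
        if (ka == substr(b, j, j + k - 1L)) {
          pos_a[i:(i + k - 1L)] <- TRUE
          pos_b[j:(j + k - 1L)] <- TRUE
        }
      }
    }
  }
  list(a = which(pos_a), b = which(pos_b))
}

bf_diag_sum <- function(seq, positions, m) {
  if (length(positions) == 0L) return(0L)
  res <- strsplit(seq, "")[[1L]][positions]
  sum(m[cbind(res, res)])
}

bf_lms_score <- function(a, b, m, k = 5L) {
  cov <- bf_coverage(a, b, k)
  bf_diag_sum(a, cov$a, m) + bf_diag_sum(b, cov$b, m)
}

bf_distance <- function(a, b, m, k = 5L) {
  sa <- if (nchar(a) >= k) bf_diag_sum(a, seq_len(nchar(a)), m) else 0L
  sb <- if (nchar(b) >= k) bf_diag_sum(b, seq_len(nchar(b)), m) else 0L
  if (sa + sb <= 0) return(1)
  1 - bf_lms_score(a, b, m, k) / (sa + sb)
}

# Naive Lance-Williams agglomeration with Ward coefficients applied to the
# distances as given (classic "ward" semantics). Returns the cophenetic
# matrix: cophenetic(a, b) = height of the merge that first joins a and b.
naive_ward_cophenetic <- function(d) {
  n <- nrow(d)
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  cur <- d
  active <- seq_len(n)
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    best_val <- Inf
    for (ai in seq_along(active)[-length(active)]) {
      for (aj in (ai + 1L):length(active)) {
        v <- cur[active[ai], active[aj]]
        if (v < best_val) {
          best_val <- v
          best <- c(active[ai], active[aj])
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- coph[b, a] <- best_val
    }
    # Lance-Williams Ward update for every other active cluster
    for (kk in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[kk]
      cur[i, kk] <- cur[kk, i] <-
        ((ni + nk) * cur[i, kk] + (nj + nk) * cur[j, kk] - nk * best_val) /
        (ni + nj + nk)
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  coph
}

random_distance_matrix <- function(n) {
  d <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  vals <- runif(n * (n - 1) / 2)
  d[lower.tri(d)] <- vals
  d <- d + t(d)
  d
}

# Brute-force bipartitions of an unrooted tree: delete each internal edge in
# turn and read the two connected components off the remaining edge list.
bf_bipartitions <- function(phy) {
  phy <- ape::unroot(phy)
  tips <- phy$tip.label
  n <- length(tips)
  edges <- phy$edge
  splits <- character(0)
  for (e in seq_len(nrow(edges))) {
    remaining <- edges[-e, , drop = FALSE]
    # component containing the child endpoint, by fixed-point expansion
    comp <- edges[e, 2L]
    repeat {
      hit <- remaining[, 1L] %in% comp | remaining[, 2L] %in% comp
      grown <- union(comp, c(remaining[hit, 1L], remaining[hit, 2L]))
      if (length(grown) == length(comp)) break
      comp <- grown
    }
    side <- sort(tips[comp[comp <= n]])
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (sort(tips)[1L] %in% side) side <- sort(setdiff(tips, side))
    splits <- c(splits, paste(side, collapse = "\r"))
  }
  unique(splits)
}

bf_rf <- function(t1, t2) {
  b1 <- bf_bipartitions(t1)
  b2 <- bf_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

random_architecture <- function(types = LETTERS[1:6], max_len = 8L) {
  len <- sample(0:max_len, 1L)
  if (len == 0L) return(character(0))
  sample(types, len, replace = TRUE)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)
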