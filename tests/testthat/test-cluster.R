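two_point_hc <- function(d12 = 0.4) {
  ward_linkage(matrix(c(0, d12, d12, 0), 2, 2,
                      dimnames = list(c("p1", "p2"), c("p1", "p2"))))
}

test_that("two points merge at their distance", {
  hc <- two_point_hc(0.4)
  expect_equal(hc$height, 0.4)
  expect_identical(sort(hc$labels), c("p1", "p2"))
})

test_that("three-point merge heights follow the Lance-Williams Ward update", {
  d <- matrix(c(0, 0.1, 0.9,
                0.1, 0, 0.9,
                0.9, 0.9, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  hc <- ward_linkage(d)
  # {a,b} first at 0.1; then c joins at (2*0.9 + 2*0.9 - 1*0.1)/3
  expect_equal(hc$height, c(0.1, 3.5 / 3))
  expect_equal(unname(as.matrix(cophenetic(hc))),
               unname(naive_ward_cophenetic(d)))
})

test_that("ward_linkage matches the naive Ward oracle on random matrices", {
  set.seed(42)
  for (rep in 1:30) {
    d <- random_distance_matrix(8)
    hc <- ward_linkage(d)
    expect_lt(max(abs(as.matrix(cophenetic(hc)) - naive_ward_cophenetic(d))),
              1e-9)
  }
})

test_that("ward_linkage validates its input matrix", {
  d <- random_distance_matrix(4)
  bad <- d; bad[1, 2] <- bad[1, 2] + 0.01
  expect_error(ward_linkage(bad), "symmetric")
  bad <- d; bad[1, 1] <- 0.2
  expect_error(ward_linkage(bad), "zero diagonal")
  bad <- d; bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(ward_linkage(bad), "\\[0, 1\\]")
})

test_that("tied distances cluster deterministically", {
  d <- matrix(0.5, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  hc1 <- ward_linkage(d)
  hc2 <- ward_linkage(d)
  expect_identical(hc1$merge, hc2$merge)
  expect_identical(hc1$height, hc2$height)
  expect_identical(to_newick(hc1), to_newick(hc2))
})

test_that("to_newick writes heights as depths, quoting awkward labels", {
  expect_identical(to_newick(two_point_hc(0.4)), "(p1:0.4,p2:0.4);")
  hc <- ward_linkage(matrix(c(0, 0.4, 0.4, 0), 2, 2,
                            dimnames = list(c("p 1", "p;2"), c("p 1", "p;2"))))
  nwk <- to_newick(hc)
  expect_match(nwk, "'p 1'", fixed = TRUE)
  expect_match(nwk, "'p;2'", fixed = TRUE)
  expect_setequal(read_newick(text = nwk)$tip.label, c("p 1", "p;2"))
})

test_that("Newick round-trip preserves the cophenetic structure", {
  set.seed(7)
  for (rep in 1:10) {
    d <- random_distance_matrix(8)
    hc <- ward_linkage(d)
    phy <- read_newick(text = to_newick(hc))
    # leaf-to-leaf path length in the tree is twice the merge height
    coph_tree <- as.matrix(cophenetic(phy)) / 2
    coph_hc <- as.matrix(cophenetic(hc))
    ids <- rownames(coph_hc)
    expect_lt(max(abs(coph_tree[ids, ids] - coph_hc)), 1e-8)
  }
})

test_that("Newick round-trip preserves every flat partition", {
  set.seed(8)
  d <- random_distance_matrix(10)
  hc <- ward_linkage(d)
  phy <- read_newick(text = to_newick(hc))
  expect_identical(rf_distance(hc, phy)$rf, 0L)
})

test_that("cut_tree respects the rescaled cut-off contract", {
  set.seed(9)
  d <- random_distance_matrix(12)
  hc <- ward_linkage(d)
  expect_identical(cut_tree(hc, 1)$n_clusters, 1L)
  expect_identical(cut_tree(hc, 0)$n_clusters, 12L)
  counts <- vapply(seq(0, 1, by = 0.05),
                   function(x) cut_tree(hc, x)$n_clusters, integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_error(cut_tree(hc, 1.2), "\\[0, 1\\]")
  expect_error(cut_tree(hc, -0.1), "\\[0, 1\\]")
})

test_that("cluster labels are 1..K in order of first leaf appearance", {
  set.seed(10)
  d <- random_distance_matrix(9)
  hc <- ward_linkage(d)
  ct <- cut_tree(hc, 0.4)
  labs <- ct$labels[rownames(d)]  # input order
  expect_identical(sort(unique(unname(labs))), seq_len(ct$n_clusters))
  first_seen <- labs[!duplicated(labs)]
  expect_identical(unname(first_seen), seq_len(ct$n_clusters))
})
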