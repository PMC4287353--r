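B62 <- blosum62()

test_that("fragment_index enumerates k-mers with positions", {
  expect_identical(fragment_index("ACDEFG"),
                   list(ACDEF = 1L, CDEFG = 2L))
  expect_length(fragment_index("ACD"), 0L)
  expect_identical(fragment_index("AAAAAA"), list(AAAAA = 1:2))
  expect_error(fragment_index("ACDEF", k = 0), "positive integer")
})

test_that("matched_coverage finds positions inside shared 5-mers", {
  expect_identical(matched_coverage("ACDEFGH", "MMACDEFYY"),
                   bf_coverage("ACDEFGH", "MMACDEFYY"))
  expect_identical(matched_coverage("ACDEFGH", "MMACDEFYY"),
                   list(a = 1:5, b = 3:7))
  s <- "ARNDCQEGH"
  expect_identical(matched_coverage(s, s), list(a = 1:9, b = 1:9))
  expect_identical(matched_coverage("AAAAAA", "RRRRRR"),
                   list(a = integer(0), b = integer(0)))
})

test_that("lms_score sums BLOSUM62 diagonals over covered residues", {
  # A4 + C9 + D6 + E5 + F6 = 30 on each side
  expect_identical(lms_score("ACDEFGH", "MMACDEFYY"), 60L)
  expect_identical(lms_score("AAAAA", "RRRRR"), 0L)
  # the score sums covered positions of BOTH sequences, so self-comparison
  # yields twice the diagonal sum (the normalization denominator is S(a)+S(b))
  s <- "WYHKMFPST"
  expect_equal(lms_score(s, s),
               2 * sum(B62[cbind(strsplit(s, "")[[1]], strsplit(s, "")[[1]])]),
               ignore_attr = TRUE)
})

test_that("coverage and score agree with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:60) {
    # small alphabets force repeated k-mers and overlapping matches
    alpha <- sample(AA20, sample(c(3, 4, 20), 1))
    a <- random_seq(sample(5:60, 1), alpha)
    b <- random_seq(sample(5:60, 1), alpha)
    expect_identical(matched_coverage(a, b), bf_coverage(a, b))
    expect_identical(as.integer(lms_score(a, b, B62)),
                     as.integer(bf_lms_score(a, b, B62)))
  }
})

test_that("pairwise_distance normalizes to [0,1] with the stated limits", {
  expect_equal(pairwise_distance("ACDEFGH", "MMACDEFYY"), 1 - 60 / 98)
  s <- random_seq(30)
  expect_identical(pairwise_distance(s, s), 0)
  expect_identical(pairwise_distance("AAAAAA", "RRRRRR"), 1)
  expect_warning(d <- pairwise_distance("ACD", "WY"), "self-scores")
  expect_identical(d, 1)
})

test_that("distance_matrix satisfies the distance axioms", {
  set.seed(77)
  for (rep in 1:5) {
    recs <- setNames(vapply(rep(30, 8), random_seq, character(1)),
                     paste0("s", 1:8))
    d <- distance_matrix(recs)
    expect_identical(d, t(d))
    expect_identical(unname(diag(d)), rep(0, 8))
    expect_true(all(d >= 0 & d <= 1))
  }
})

test_that("distance_matrix handles duplicates and unrelated sequences", {
  s <- random_seq(40)
  d <- distance_matrix(c(a = s, a2 = s, u = strrep("W", 40)))
  expect_identical(d["a", "a2"], 0)
  expect_identical(d["a", "u"], 1)
  expect_error(distance_matrix(c(a = "ACDEF")), "at least 2")
  expect_error(distance_matrix(Biostrings::AAStringSet(c(a = "ACDEF", a = "ACDEF"))),
               "duplicate")
})

test_that("distance_matrix equals the quadratic brute-force oracle", {
  set.seed(202)
  recs <- setNames(vapply(rep(30, 10), random_seq, character(1)),
                   paste0("s", 1:10))
  d <- distance_matrix(recs)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(d[i, j], bf_distance(recs[i], recs[j], B62),
                   tolerance = 1e-12)
    }
  }
})

test_that("appending a shared novel block never increases the distance", {
  set.seed(303)
  for (rep in 1:20) {
    a <- random_seq(sample(10:40, 1))
    b <- random_seq(sample(10:40, 1))
    block <- random_seq(sample(5:15, 1))
    d0 <- pairwise_distance(a, b)
    d1 <- pairwise_distance(paste0(a, block), paste0(b, block))
    expect_lte(d1, d0 + 1e-12)
  }
})

test_that("X residues never match but still count in the self-score", {
  # identical X-containing 5-mers do not match each other
  expect_identical(lms_score("AXCDEF", "AXCDEF"), 0L)
  # denominator includes the X diagonal (-1): self of "ACDEFXG" = 44 - 1 + 6
  a <- "ACDEFGH"
  ax <- "ACDEFGHXW"  # shared block ACDEFGH, X blocks nothing downstream
  d <- pairwise_distance(a, ax)
  sa <- 44
  sax <- 44 + B62["X", "X"] + B62["W", "W"]
  expect_equal(d, 1 - (44 + 44) / (sa + sax))
})

test_that("NCBI-format substitution matrices can be read and substituted", {
  path <- withr::local_tempfile(fileext = ".txt")
  m <- blosum62()
  writeLines(c("# test matrix",
               paste(c(" ", colnames(m)), collapse = "  "),
               vapply(rownames(m), function(r) {
                 paste(c(r, m[r, ]), collapse = "  ")
               }, character(1))), path)
  m2 <- read_score_matrix(path)
  expect_identical(m2[rownames(m), colnames(m)], m)
  expect_identical(lms_score("ACDEFGH", "MMACDEFYY", m = m2), 60L)
})
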