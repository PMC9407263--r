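test_that("column distributions count residues over non-gap species", {
  expect_equal(column_distribution(c("A", "A", "C", "C")),
               c(A = 0.5, C = 0.5))
  expect_equal(column_distribution(c("A", "A", "A", "C")),
               c(A = 0.75, C = 0.25))
  expect_equal(column_distribution(c("A", "-", "A", "-")), c(A = 1))
  expect_equal(column_distribution(c("A", "X", "B", "A")), c(A = 1))
  expect_length(column_distribution(c("-", "-")), 0L)
})

test_that("pair_mi reproduces hand-computed values", {
  # perfect covariation of two equifrequent residues
  expect_equal(pair_mi(c("A", "A", "C", "C"), c("D", "D", "E", "E")),
               log(2))
  # exact independence gives exactly zero
  expect_identical(pair_mi(c("A", "A", "C", "C"), c("D", "E", "D", "E")),
                   0)
  # marginal filter removes the rare-residue terms
  expect_equal(pair_mi(c("A", "A", "A", "C"), c("D", "D", "D", "E"),
                       filter_params(min_px = 0.3)),
               0.75 * log(0.75 / 0.5625))
  # degenerate columns score zero
  expect_identical(pair_mi(c("-", "-"), c("A", "C")), 0)
})

test_that("pair_mi matches the naive brute-force oracle", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:10, 1)
    c1 <- random_column(n, n_res = sample(2:5, 1), gap_prob = 0.15)
    c2 <- random_column(n, n_res = sample(2:5, 1), gap_prob = 0.15)
    tau <- sample(c(0, 0.1, 0.25, 0.4), 1)
    r <- sample(c(0, 10, 35, 60), 1)
    expect_equal(pair_mi(c1, c2, filter_params(tau, r)),
                 naive_mi(c1, c2, tau, r),
                 tolerance = 1e-12)
  }
})

test_that("with filters zeroed pair_mi is the textbook mutual information", {
  set.seed(7)
  for (i in 1:50) {
    c1 <- random_column(12, n_res = 3)
    c2 <- random_column(12, n_res = 3)
    # textbook MI of the empirical joint, computed from entropies
    pj <- table(c1, c2) / 12
    px <- rowSums(pj); py <- colSums(pj)
    h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
    expect_equal(pair_mi(c1, c2), h(px) + h(py) - h(pj),
                 tolerance = 1e-12)
    # and it is never negative once the joint filter is active
    expect_gte(pair_mi(c1, c2, filter_params(0, 35)), 0)
  }
})

test_that("normalization divides by the comparison mean and scales by 1e4", {
  raw <- matrix(c(1, 3, 2, 2), 2, 2)   # [[1,2],[3,2]] row-wise
  norm <- coevolink:::.normalize_scores(raw)
  expect_false(norm$no_signal)
  expect_equal(norm$normalized,
               matrix(c(5000, 15000, 10000, 10000), 2, 2))
  expect_equal(mean(norm$normalized), 10000)
  top <- coevolink:::.top_cell(norm$normalized)
  expect_equal(c(top$position1, top$position2, top$score),
               c(2, 1, 15000))
})

test_that("top-cell ties break toward the smallest position pair", {
  m <- matrix(5, 3, 3)
  top <- coevolink:::.top_cell(m)
  expect_equal(c(top$position1, top$position2), c(1, 1))
  m[2, 3] <- 9; m[3, 1] <- 9
  top <- coevolink:::.top_cell(m)
  expect_equal(c(top$position1, top$position2), c(2, 3))
})

test_that("score_comparison is symmetric under protein swap", {
  sim <- simulate_pair(simulation_spec(
    n_species = 60, len1 = 6, len2 = 8,
    planted = data.frame(col1 = 2, col2 = 5, eps = 0.1),
    gap_rate = 0.05, seed = 11))
  pa <- pair_alignments(sim$alignment1, sim$alignment2, "sp0001",
                        min_common = 10)
  ab <- score_comparison(pa, filter_params(0.1, 20))
  pa_rev <- pair_alignments(sim$alignment2, sim$alignment1, "sp0001",
                            min_common = 10)
  ba <- score_comparison(pa_rev, filter_params(0.1, 20))
  expect_equal(ba$normalized, t(ab$normalized))
  expect_equal(ba$top$score, ab$top$score)
})

test_that("normalized scores do not depend on the logarithm base", {
  sim <- simulate_pair(simulation_spec(
    n_species = 80, len1 = 8, len2 = 8,
    planted = data.frame(col1 = 1, col2 = 1, eps = 0), seed = 3))
  pa <- pair_alignments(sim$alignment1, sim$alignment2, "sp0001",
                        min_common = 10)
  nat <- score_comparison(pa, filter_params(0.1, 20), base = exp(1))
  bit <- score_comparison(pa, filter_params(0.1, 20), base = 2)
  expect_equal(bit$normalized, nat$normalized, tolerance = 1e-12)
  expect_equal(mean(nat$normalized), 10000)
})

test_that("an all-zero comparison is flagged as carrying no signal", {
  # fully conserved columns everywhere -> every raw MI is 0
  a1 <- protein_alignment(setNames(rep("AAA", 12), sprintf("s%d", 1:12)))
  a2 <- protein_alignment(setNames(rep("CC", 12), sprintf("s%d", 1:12)))
  sm <- score_comparison(pair_alignments(a1, a2, "s1", min_common = 5))
  expect_true(sm$no_signal)
  expect_true(all(sm$normalized == 0))
  expect_equal(sm$top$score, 0)
  expect_true(is.na(sm$top$position1))
})

test_that("substitution noise never increases planted-pair raw MI", {
  eps_grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- sapply(eps_grid, function(eps) {
    mean(sapply(1:20, function(s) {
      sim <- simulate_pair(simulation_spec(
        n_species = 150, len1 = 1, len2 = 1,
        planted = data.frame(col1 = 1, col2 = 1, eps = eps),
        gap_rate = 0, seed = 5000 + s))
      pair_mi(unname(sim$alignment1$records),   # single-column alignments
              unname(sim$alignment2$records))
    }))
  })
  expect_true(all(diff(means) <= 1e-6))
})
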