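test_that("the default filter grid enumerates 36 x 40 combinations", {
  g <- filter_grid()
  expect_equal(nrow(g), 1440L)
  expect_equal(length(unique(g$min_px)), 36L)
  expect_equal(length(unique(g$pct_above_random)), 40L)
  expect_equal(range(g$min_px), c(0, 0.35))
  expect_equal(range(g$pct_above_random), c(10, 49))
  # row-major: min_px varies slowest
  expect_equal(g$min_px[1:40], rep(0, 40))
  expect_equal(g$pct_above_random[1:3], c(10, 11, 12))
})

test_that("grid edge cases and validation", {
  expect_equal(nrow(filter_grid(tau = 0, r = 10)), 1L)
  expect_equal(nrow(filter_grid(tau = c(0, 0.01, 0.02), r = c(10, 11))),
               6L)
  expect_error(filter_grid(tau = numeric(0)),
               class = "coevolink_domain_error")
  expect_error(filter_grid(tau = 2), class = "coevolink_domain_error")
})

test_that("evaluation statistics match hand computations", {
  st <- evaluate_combination(labeled_scores(c(2, 4, 6), c(1, 3, 5)))
  expect_equal(st$auc, 6 / 9)
  st2 <- evaluate_combination(labeled_scores(c(4, 4, 6, 6), c(3, 3, 5, 5)))
  expect_equal(st2$cohens_d, 1 / sqrt(4 / 3))
  # perfect separation: precision 1 at recall 1
  st3 <- evaluate_combination(labeled_scores(c(10, 10), c(1, 1)))
  expect_equal(st3$precision, 1)
  expect_equal(st3$recall, 1)
  # zero variance in both groups: t-test undefined, reported as NA
  st4 <- evaluate_combination(labeled_scores(c(2, 2), c(2, 2)))
  expect_true(is.na(st4$t_p))
})

test_that("rank AUC equals the brute-force concordant-pair count", {
  set.seed(21)
  for (i in 1:50) {
    known <- sample(0:6, sample(2:8, 1), replace = TRUE)
    unknown <- sample(0:6, sample(2:8, 1), replace = TRUE)
    st <- evaluate_combination(labeled_scores(known, unknown))
    expect_equal(st$auc, naive_auc(known, unknown))
  }
})

test_that("AUC grows with the class separation", {
  aucs <- sapply(c(0, 0.5, 1, 2), function(shift) {
    mean(sapply(1:5, function(s) {
      sc <- simulate_labeled_scores(300, 300, shift = shift,
                                    seed = 900 + 10 * shift + s)
      evaluate_combination(sc)$auc
    }))
  })
  expect_true(all(diff(aucs) > 0))
  expect_equal(aucs[1], 0.5, tolerance = 0.05)
})

test_that("Welch and Student t variants both run and differ when they should", {
  sc <- simulate_labeled_scores(40, 80, shift = 1, seed = 33)
  w <- evaluate_combination(sc, t_variant = "welch")
  s <- evaluate_combination(sc, t_variant = "student")
  expect_true(is.finite(w$t_p) && is.finite(s$t_p))
  expect_false(identical(w$t_p, s$t_p))
})

test_that("filter selection maximizes precision with the documented tie-breaks", {
  res <- data.frame(
    min_px = c(0.1, 0.2, 0.3, 0.05),
    pct_above_random = c(10, 20, 30, 15),
    precision = c(0.8, 0.9, 0.9, 0.9),
    recall = c(0.5, 0.5, 0.5, 0.1),
    auc = c(0.9, 0.6, 0.7, 0.99))
  # 0.05 row excluded by recall; 0.2 vs 0.3 tie on precision -> higher AUC
  pick <- select_filters(res)
  expect_equal(pick$min_px, 0.3)
  expect_equal(pick$pct_above_random, 30)
  # equal AUC too -> smaller (tau, r)
  res$auc[2] <- 0.7
  pick <- select_filters(res)
  expect_equal(pick$min_px, 0.2)
  # permutation invariance
  for (i in 1:5) {
    perm <- res[sample(nrow(res)), ]
    expect_equal(select_filters(perm)$min_px, 0.2)
  }
  # nothing reaches the recall floor
  res$recall <- 0.05
  expect_error(select_filters(res), class = "coevolink_selection_error")
})

test_that("bonferroni_alpha divides the family-wise level", {
  expect_equal(bonferroni_alpha(0.05, 2880), 0.05 / 2880)
  expect_equal(signif(bonferroni_alpha(0.05, 2880), 3), 1.74e-5)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), class = "coevolink_domain_error")
})

test_that("grid tuning rescoring separates planted from background pairs", {
  make_sims <- function(seeds, planted) {
    lapply(seeds, function(s) {
      sim <- simulate_pair(simulation_spec(
        n_species = 80, len1 = 6, len2 = 6, planted = planted, seed = s))
      pair_alignments(sim$alignment1, sim$alignment2, "sp0001",
                      min_common = 10)
    })
  }
  coevolving <- data.frame(col1 = 2, col2 = 4, eps = 0.05)
  none <- data.frame(col1 = integer(0), col2 = integer(0),
                     eps = numeric(0))
  known <- make_sims(101:105, coevolving)
  unknown <- make_sims(201:205, none)
  grid <- filter_grid(tau = c(0.1, 0.17), r = c(20, 35))
  res <- tune_filters(known, unknown, grid)
  expect_s3_class(res, "tuning_result")
  expect_equal(nrow(res), 4L)
  expect_true(all(res$auc > 0.5))
  best <- select_filters(res)
  expect_s3_class(best, "filter_params")
})

test_that("labeled scores round-trip through the TSV reader", {
  kf <- withr::local_tempfile(fileext = ".tsv")
  uf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pairA\t12.5", "pairB\t3.25"), kf)
  writeLines(c("pairC\t0.5"), uf)
  sc <- read_labeled_scores(kf, uf)
  expect_equal(unname(sc$known), c(12.5, 3.25))
  expect_equal(unname(sc$unknown), 0.5)
})
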