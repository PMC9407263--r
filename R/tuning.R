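#' Labeled score sets
#'
#' Top normalized scores for protein pairs known to interact and for
#' pairs with no known interaction, used to tune filters and calibrate
#' probability tables.
#'
#' @param known,unknown Non-negative numeric score vectors.
#' @return An object of class `labeled_scores`.
#' @export
labeled_scores <- function(known, unknown) {
  for (v in list(known, unknown))
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      .stop("scores must be finite and non-negative",
            "coevolink_domain_error")
  structure(list(known = as.numeric(known),
                 unknown = as.numeric(unknown)),
            class = "labeled_scores")
}

#' Read labeled score sets from two-column TSV files
#'
#' Each file holds one class: column 1 a pair identifier, column 2 the
#' top normalized score, no header.
#'
#' @param known_path,unknown_path Paths to the TSV files.
#' @return A [labeled_scores()] object.
#' @export
read_labeled_scores <- function(known_path, unknown_path) {
  rd <- function(p) {
    d <- utils::read.delim(p, header = FALSE)
    if (ncol(d) < 2L)
      .stop(sprintf("'%s' needs two columns (pair id, score)", p),
            "coevolink_format_error")
    stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
  }
  labeled_scores(rd(known_path), rd(unknown_path))
}

#' Filter-parameter grid
#'
#' Cartesian product of marginal-frequency thresholds and
#' percent-above-random values, in row-major order (`min_px` outer). The
#' default grid spans `min_px` 0 to 0.35 in steps of 0.01 and
#' `pct_above_random` 10 to 49% in steps of 1%, i.e. 36 x 40 = 1440
#' combinations. Grid values are built by integer arithmetic so no
#' floating-point drift can change the grid size.
#'
#' @param tau Vector of `min_px` values (default `(0:35)/100`).
#' @param r Vector of `pct_above_random` values (default `10:49`).
#' @return A data frame of class `filter_grid` with columns `min_px` and
#'   `pct_above_random`, one row per combination.
#' @export
filter_grid <- function(tau = (0:35) / 100, r = 10:49) {
  if (length(tau) == 0L || length(r) == 0L)
    .stop("empty parameter range", "coevolink_domain_error")
  if (any(tau < 0 | tau > 1) || any(r < 0 | r >= 100))
    .stop("tau must lie in [0, 1] and r in [0, 100)",
          "coevolink_domain_error")
  grid <- data.frame(min_px = rep(tau, each = length(r)),
                     pct_above_random = rep(r, times = length(tau)))
  class(grid) <- c("filter_grid", "data.frame")
  grid
}

# Pooled-sd Cohen's d.
.cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

# Rank (Mann-Whitney) AUC with half-credit for ties.
.rank_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos); n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Best precision over score cutoffs subject to recall >= min_recall;
# ties broken toward higher recall.
.best_precision <- function(pos, neg, min_recall = 0.20) {
  cuts <- sort(unique(c(pos, neg)))
  prec <- rec <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    tp <- sum(pos >= cuts[i]); fp <- sum(neg >= cuts[i])
    rec[i] <- tp / length(pos)
    prec[i] <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  }
  ok <- which(rec >= min_recall & !is.na(prec))
  if (length(ok) == 0L)
    return(list(precision = NA_real_, recall = NA_real_))
  best <- ok[order(-prec[ok], -rec[ok])][1L]
  list(precision = prec[best], recall = rec[best])
}

#' Evaluation statistics for one filter combination
#'
#' Given the labeled top scores produced under one filter setting,
#' computes the two-sample t-test p-value (Welch by default), Cohen's d
#' with the pooled standard deviation, the ROC AUC in its rank
#' (Mann-Whitney) formulation with half-credit for ties, and the best
#' precision achievable over score cutoffs while keeping recall at or
#' above `min_recall` (ties toward higher recall).
#'
#' @param scores A [labeled_scores()] object.
#' @param min_recall Recall floor for the precision search (default 0.20).
#' @param t_variant `"welch"` (default) or `"student"` (pooled variance).
#' @return A one-row data frame: `n_known`, `n_unknown`, `t_p`,
#'   `cohens_d`, `auc`, `precision`, `recall`. With zero variance in both
#'   groups the t-test is undefined and `t_p` is `NA`.
#' @export
evaluate_combination <- function(scores, min_recall = 0.20,
                                 t_variant = c("welch", "student")) {
  stopifnot(inherits(scores, "labeled_scores"))
  t_variant <- match.arg(t_variant)
  pos <- scores$known; neg <- scores$unknown
  if (length(pos) == 0L || length(neg) == 0L)
    .stop("both classes must be non-empty", "coevolink_domain_error")
  t_p <- tryCatch(
    stats::t.test(pos, neg, var.equal = t_variant == "student")$p.value,
    error = function(e) NA_real_)
  pr <- .best_precision(pos, neg, min_recall)
  data.frame(n_known = length(pos), n_unknown = length(neg),
             t_p = t_p, cohens_d = .cohens_d(pos, neg),
             auc = .rank_auc(pos, neg),
             precision = pr$precision, recall = pr$recall)
}

#' Grid search over filter combinations
#'
#' For each filter combination, rescores every labeled alignment pair
#' with [score_comparison()], takes each pair's top normalized score, and
#' evaluates the resulting labeled score sets with
#' [evaluate_combination()]. This is the expensive step of filter tuning;
#' runtime scales with `nrow(grid) * (number of pairs) * (columns^2)`.
#'
#' @param known_pairs,unknown_pairs Lists of [pair_alignments()] objects
#'   for interacting and not-known-to-interact protein pairs.
#' @param grid A [filter_grid()] (default: the full 1440-combination grid).
#' @param min_recall Recall floor for the precision search.
#' @return A data frame of class `tuning_result`: one row per
#'   combination, the grid columns followed by the evaluation statistics.
#' @seealso [select_filters()] to pick the default filters from the
#'   result, [plot.tuning_result()] for the metric heatmaps.
#' @export
tune_filters <- function(known_pairs, unknown_pairs, grid = filter_grid(),
                         min_recall = 0.20) {
  stopifnot(inherits(grid, "filter_grid"),
            length(known_pairs) > 0L, length(unknown_pairs) > 0L)
  top_scores <- function(pairs, filters)
    vapply(pairs,
           function(pa) score_comparison(pa, filters)$top$score,
           numeric(1))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    filters <- filter_params(grid$min_px[i], grid$pct_above_random[i])
    sc <- labeled_scores(top_scores(known_pairs, filters),
                         top_scores(unknown_pairs, filters))
    cbind(grid[i, , drop = FALSE],
          evaluate_combination(sc, min_recall = min_recall))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("tuning_result", "data.frame")
  out
}

#' Select default filters from a tuning result
#'
#' Picks the combination with the highest precision (already constrained
#' to recall at or above the floor during evaluation); ties are broken by
#' higher AUC, then by the smaller `(min_px, pct_above_random)` pair.
#'
#' @param results A `tuning_result` data frame (or any data frame with
#'   columns `min_px`, `pct_above_random`, `precision`, `recall`, `auc`).
#' @param min_recall Combinations whose recall fell below this floor are
#'   ineligible.
#' @return A [filter_params()] object.
#' @export
select_filters <- function(results, min_recall = 0.20) {
  stopifnot(is.data.frame(results), nrow(results) > 0L)
  ok <- !is.na(results$precision) & !is.na(results$recall) &
    results$recall >= min_recall
  if (!any(ok))
    .stop(sprintf("no filter combination reaches %.0f%% recall",
                  100 * min_recall), "coevolink_selection_error")
  cand <- results[ok, , drop = FALSE]
  pick <- cand[order(-cand$precision, -cand$auc, cand$min_px,
                     cand$pct_above_random), , drop = FALSE][1L, ]
  filter_params(pick$min_px, pick$pct_above_random)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests (e.g. 2880 for a 1440-combination grid
#'   run on two taxa).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_alpha(0.05, 2880)  # 1.74e-05
#' @export
bonferroni_alpha <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    .stop("alpha must be in (0, 1]", "coevolink_domain_error")
  if (!.is_count(n_tests, 1L))
    .stop("n_tests must be a positive integer", "coevolink_domain_error")
  alpha / n_tests
}

#' Heatmaps of tuning statistics over the filter grid
#'
#' Draws the per-combination metric as an image over the
#' (`min_px`, `pct_above_random`) grid, mirroring the precision / AUC /
#' -log10 p panels used to locate the optimal filters.
#'
#' @param x A `tuning_result`.
#' @param metric `"precision"`, `"auc"` or `"neglogp"`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.tuning_result <- function(x, metric = c("precision", "auc",
                                             "neglogp"), ...) {
  metric <- match.arg(metric)
  z <- switch(metric, precision = x$precision, auc = x$auc,
              neglogp = -log10(x$t_p))
  taus <- sort(unique(x$min_px)); rs <- sort(unique(x$pct_above_random))
  m <- matrix(NA_real_, length(taus), length(rs))
  m[cbind(match(x$min_px, taus), match(x$pct_above_random, rs))] <- z
  graphics::image(taus, rs, m, xlab = "min residue frequency",
                  ylab = "% above random", main = metric,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
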