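#' Construct a probability table
#'
#' A probability table is a step function from normalized top score to the
#' percent chance that the two proteins truly interact, calibrated from
#' labeled score sets. Thresholds must be strictly descending in score;
#' scores below the lowest threshold fall back to the baseline (50%, "no
#' better than random").
#'
#' @param scores Numeric vector of score thresholds, strictly descending.
#' @param percents Percent chance of interaction at each threshold.
#' @param taxon Label for the table.
#' @param baseline Percent returned below the lowest threshold (default 50).
#' @return An object of class `probability_table`.
#' @export
new_probability_table <- function(scores, percents, taxon = "custom",
                                  baseline = 50) {
  if (length(scores) != length(percents))
    .stop("scores and percents must have equal length",
          "coevolink_domain_error")
  if (length(scores) > 1L && any(diff(scores) >= 0))
    .stop("thresholds must be strictly descending in score",
          "coevolink_domain_error")
  structure(list(taxon = taxon,
                 thresholds = data.frame(score = as.numeric(scores),
                                         percent = as.numeric(percents)),
                 baseline = baseline,
                 baseline_label = "no better than random"),
            class = "probability_table")
}

#' Embedded taxon probability tables
#'
#' Returns the calibrated score-threshold table for the chosen taxon,
#' shipped with the package as a TSV resource. The bacteria table is
#' stored exactly as calibrated, including one cell (score 23.93 mapping
#' to 75.58%) that breaks the otherwise monotone descent between its
#' neighbours — most likely a transcription error in the calibration
#' output. Requesting the bacteria table as-is emits a warning;
#' `monotonize = TRUE` replaces any such cell by the mean of its
#' neighbouring percents.
#'
#' @param taxon `"vertebrate"` or `"bacteria"`.
#' @param monotonize Repair monotonicity-breaking percent cells by
#'   neighbour interpolation (default `FALSE`: fidelity to the calibrated
#'   values comes first).
#' @return A `probability_table`.
#' @examples
#' vt <- probability_table("vertebrate")
#' lookup_probability(500, vt)
#' @export
probability_table <- function(taxon = c("vertebrate", "bacteria"),
                              monotonize = FALSE) {
  taxon <- match.arg(taxon)
  path <- system.file("extdata", paste0(taxon, "_thresholds.tsv"),
                      package = "coevolink", mustWork = TRUE)
  rows <- utils::read.delim(path, header = FALSE)
  stopifnot(rows[1, 1] == "score", rows[2, 1] == "percent")
  scores <- as.numeric(rows[1, -1])
  percents <- as.numeric(rows[2, -1])
  viol <- which(diff(percents) > 0)   # percent rising as score falls
  if (length(viol) > 0L) {
    if (monotonize) {
      for (v in viol) {
        lo <- if (v > 1L) percents[v - 1L] else percents[v + 1L]
        hi <- percents[v + 1L]
        percents[v] <- mean(c(lo, hi))
      }
      # the violation is at index v when percents[v] < percents[v+1];
      # the anomalous cell is v, repaired from its neighbours
    } else {
      warning(sprintf(
        "'%s' table is non-monotonic at score %s (percent %s); use monotonize = TRUE to interpolate",
        taxon, paste(scores[viol], collapse = ", "),
        paste(percents[viol], collapse = ", ")), call. = FALSE)
    }
  }
  new_probability_table(scores, percents, taxon = taxon)
}

#' Convert a normalized score into a percent chance of interaction
#'
#' Step-function lookup: a score receives the percent of the largest
#' threshold it reaches (boundary inclusive: a score exactly at a
#' threshold receives that threshold's percent). Scores below the lowest
#' threshold return the baseline 50% — no better than random. Scores above
#' the highest threshold return the top percent (tables are open-ended
#' upward).
#'
#' @param score Numeric vector of normalized scores, all >= 0.
#' @param table A `probability_table`.
#' @return Numeric vector of percents, with a logical attribute
#'   `no_better_than_random` marking baseline fallbacks.
#' @export
lookup_probability <- function(score, table) {
  stopifnot(inherits(table, "probability_table"))
  if (!is.numeric(score) || any(is.na(score)) || any(score < 0))
    .stop("scores must be non-negative numbers", "coevolink_domain_error")
  thr <- table$thresholds
  out <- vapply(score, function(s) {
    hit <- which(thr$score <= s)
    if (length(hit) == 0L) table$baseline else thr$percent[hit[1L]]
  }, numeric(1))
  random <- vapply(score, function(s) all(thr$score > s) ||
                     nrow(thr) == 0L, logical(1))
  attr(out, "no_better_than_random") <- random
  out
}

#' Calibrate a probability table from labeled score sets
#'
#' Bins both score lists into `n_bins` equal-width bins spanning
#' `[0, max(all scores)]` and estimates, per bin, the probability that a
#' score in it belongs to a known interaction:
#' `known / (known + unknown)`. Bins at or below 50% — random, since the
#' labeling is far likelier to miss true interactions than to invent
#' them — and empty bins at the bottom of the range are merged into the
#' baseline region. Above it, empty bins are pooled with the bin below and
#' adjacent bins violating monotonicity (a higher-score bin with a lower
#' probability) are pooled until the step function is monotone
#' non-decreasing in score. Surviving bins are emitted as
#' (bin lower edge, percent) thresholds.
#'
#' @param known Scores of pairs known to interact.
#' @param unknown Scores of pairs not known to interact.
#' @param n_bins Number of equal-width bins (default 20).
#' @param taxon Label for the resulting table.
#' @return A `probability_table`. If every bin is at or below 50% the
#'   table has no thresholds and every lookup returns the baseline.
#' @examples
#' tab <- build_probability_table(known = c(9, 9, 9), unknown = c(1, 1, 1))
#' lookup_probability(c(9, 1), tab)
#' @export
build_probability_table <- function(known, unknown, n_bins = 20,
                                    taxon = "custom") {
  if (length(known) == 0L || length(unknown) == 0L)
    .stop("both labeled score sets must be non-empty",
          "coevolink_calibration_error")
  if (any(!is.finite(c(known, unknown))) || any(c(known, unknown) < 0))
    .stop("scores must be finite and non-negative",
          "coevolink_calibration_error")
  if (!.is_count(n_bins, 1L))
    .stop("n_bins must be a positive integer", "coevolink_domain_error")
  top <- max(known, unknown)
  if (top <= 0)
    .stop("all scores are zero; nothing to calibrate",
          "coevolink_calibration_error")
  breaks <- seq(0, top, length.out = n_bins + 1)
  bin_of <- function(x) pmin(pmax(findInterval(x, breaks,
                                               rightmost.closed = TRUE),
                                  1L), n_bins)
  kc <- tabulate(bin_of(known), n_bins)
  uc <- tabulate(bin_of(unknown), n_bins)
  prob <- ifelse(kc + uc > 0, 100 * kc / (kc + uc), NA_real_)

  # baseline region: contiguous run of (<= 50% or empty) bins from the
  # bottom of the score range
  first <- 1L
  while (first <= n_bins && (is.na(prob[first]) || prob[first] <= 50))
    first <- first + 1L
  if (first > n_bins)
    return(new_probability_table(numeric(0), numeric(0), taxon = taxon))

  # pool the surviving bins into blocks: empty bins join the block below;
  # adjacent-violator pooling enforces probability non-decreasing in score
  lo <- integer(0); k <- integer(0); u <- integer(0)
  for (b in first:n_bins) {
    if (kc[b] + uc[b] == 0L) next     # empty: absorbed by the block below
    lo <- c(lo, b); k <- c(k, kc[b]); u <- c(u, uc[b])
    repeat {
      m <- length(lo)
      if (m < 2L) break
      if (100 * k[m] / (k[m] + u[m]) >=
          100 * k[m - 1L] / (k[m - 1L] + u[m - 1L])) break
      k[m - 1L] <- k[m - 1L] + k[m]
      u[m - 1L] <- u[m - 1L] + u[m]
      lo <- lo[-m]; k <- k[-m]; u <- u[-m]
    }
  }
  p <- 100 * k / (k + u)
  # after pooling the lowest block may have dropped to random; absorb it
  while (length(p) > 0L && p[1L] <= 50) {
    p <- p[-1L]; lo <- lo[-1L]
  }
  if (length(p) == 0L)
    return(new_probability_table(numeric(0), numeric(0), taxon = taxon))
  new_probability_table(rev(breaks[lo]), rev(p), taxon = taxon)
}

#' @export
print.probability_table <- function(x, ...) {
  cat(sprintf("Probability table (%s): %d thresholds, baseline %.4g%% (%s)\n",
              x$taxon, nrow(x$thresholds), x$baseline, x$baseline_label))
  if (nrow(x$thresholds) > 0L) print(x$thresholds, row.names = FALSE)
  invisible(x)
}
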