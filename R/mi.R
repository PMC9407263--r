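#' Filter parameters for partial mutual-information terms
#'
#' Two per-term filters control which residue combinations enter the
#' mutual-information sum for a column pair:
#' \describe{
#'   \item{`min_px`}{minimum marginal residue frequency: a combination
#'     (x, y) contributes only if both p(x) and p(y) are at least this
#'     value. In `[0, 1]`.}
#'   \item{`pct_above_random`}{percent by which the joint frequency must
#'     exceed its independence expectation: p(x, y) >= (1 + r/100) p(x)
#'     p(y). In `[0, 100)`. At `r = 0` this filter is off and all observed
#'     combinations contribute (plain empirical mutual information).}
#' }
#'
#' @param min_px Marginal frequency threshold (default 0).
#' @param pct_above_random Percent above the random expectation (default 0).
#' @return An object of class `filter_params`.
#' @seealso [filter_preset()] for the tuned vertebrate/bacteria defaults.
#' @export
filter_params <- function(min_px = 0, pct_above_random = 0) {
  if (!is.numeric(min_px) || length(min_px) != 1L || is.na(min_px) ||
      min_px < 0 || min_px > 1)
    .stop("min_px must be a single value in [0, 1]", "coevolink_domain_error")
  if (!is.numeric(pct_above_random) || length(pct_above_random) != 1L ||
      is.na(pct_above_random) || pct_above_random < 0 ||
      pct_above_random >= 100)
    .stop("pct_above_random must be a single value in [0, 100)",
          "coevolink_domain_error")
  structure(list(min_px = min_px, pct_above_random = pct_above_random),
            class = "filter_params")
}

#' Tuned filter presets
#'
#' Default filter settings obtained by grid search against labeled
#' interaction sets: vertebrates `min_px = 0.17`, `pct_above_random = 35`;
#' bacteria `min_px = 0.29`, `pct_above_random = 22`.
#'
#' @param taxon `"vertebrate"` or `"bacteria"`.
#' @return A [filter_params()] object.
#' @export
filter_preset <- function(taxon = c("vertebrate", "bacteria")) {
  taxon <- match.arg(taxon)
  switch(taxon,
         vertebrate = filter_params(0.17, 35),
         bacteria   = filter_params(0.29, 22))
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("Filters: min residue frequency %.3g, %.3g%% above random\n",
              x$min_px, x$pct_above_random))
  invisible(x)
}

#' Residue frequency distribution of one alignment column
#'
#' Gaps and non-standard residues are excluded; frequencies are taken
#' over the remaining species and sum to 1. An all-excluded column gives
#' an empty distribution.
#'
#' @param column Character vector of single residues (one per species).
#' @return Named numeric vector of residue frequencies.
#' @examples
#' column_distribution(c("A", "A", "C", "C"))
#' column_distribution(c("A", "-", "A", "-"))
#' @export
column_distribution <- function(column) {
  keep <- column %in% .AA
  column <- column[keep]
  if (length(column) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  tab <- table(column)
  stats::setNames(as.numeric(tab) / length(column), names(tab))
}

# Core scorer on integer-coded columns (1..20; 0 = excluded).
# rmul = 1 + r/100; rmul <= 1 disables the joint filter.
.pair_mi_codes <- function(c1, c2, tau, rmul, base) {
  ok <- c1 > 0L & c2 > 0L
  n <- sum(ok)
  if (n == 0L) return(0)
  c1 <- c1[ok]; c2 <- c2[ok]
  joint <- tabulate((c1 - 1L) * .N_AA + c2, nbins = .N_AA * .N_AA) / n
  px <- tabulate(c1, nbins = .N_AA) / n
  py <- tabulate(c2, nbins = .N_AA) / n
  idx <- which(joint > 0)
  xi <- (idx - 1L) %/% .N_AA + 1L
  yi <- (idx - 1L) %% .N_AA + 1L
  pxy <- joint[idx]; pxv <- px[xi]; pyv <- py[yi]
  keep <- pxv >= tau & pyv >= tau
  if (rmul > 1) keep <- keep & pxy >= rmul * pxv * pyv
  if (!any(keep)) return(0)
  sum(pxy[keep] * log(pxy[keep] / (pxv[keep] * pyv[keep]), base = base))
}

#' Filtered mutual information between two alignment columns
#'
#' Evaluates the mutual information
#' \deqn{MI(X, Y) = \sum_{x} \sum_{y} p(x, y) \log \frac{p(x, y)}{p(x)\,p(y)}}
#' over the residue combinations surviving the per-term filters (see
#' [filter_params()]). Species showing a gap or non-standard residue at
#' either column are excluded from that pair's counts. Degenerate columns
#' (nothing to count, or every term filtered) score 0.
#'
#' @param col1,col2 Character vectors of residues over the same species.
#' @param filters A [filter_params()] object.
#' @param base Logarithm base (default natural log). Normalized scores are
#'   invariant to this choice.
#' @return A single numeric MI value (non-negative whenever
#'   `pct_above_random > 0`).
#' @examples
#' pair_mi(c("A", "A", "C", "C"), c("D", "D", "E", "E"))  # log(2)
#' pair_mi(c("A", "A", "C", "C"), c("D", "E", "D", "E"))  # independent: 0
#' @export
pair_mi <- function(col1, col2, filters = filter_params(), base = exp(1)) {
  stopifnot(inherits(filters, "filter_params"))
  if (length(col1) != length(col2))
    .stop("columns must cover the same species", "coevolink_domain_error")
  .pair_mi_codes(match(col1, .AA, nomatch = 0L),
                 match(col2, .AA, nomatch = 0L),
                 filters$min_px, 1 + filters$pct_above_random / 100, base)
}

# Normalize raw scores by the comparison-wide mean, x 10,000.
.normalize_scores <- function(raw) {
  m <- mean(raw)
  if (m > 0) {
    list(normalized = raw / m * 10000, no_signal = FALSE)
  } else {
    list(normalized = array(0, dim(raw), dimnames = dimnames(raw)),
         no_signal = TRUE)
  }
}

# Deterministic argmax: smallest pos1, then smallest pos2.
.top_cell <- function(normalized) {
  hits <- which(normalized == max(normalized), arr.ind = TRUE)
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  list(position1 = unname(hits[1L, 1L]), position2 = unname(hits[1L, 2L]),
       score = max(normalized))
}

#' Score every cross-protein residue-position pair
#'
#' Computes the filtered mutual information for each pair of reference
#' positions (protein 1 x protein 2; intra-protein pairs are never
#' scored), then normalizes each cell by the mean over the whole
#' comparison and multiplies by 10,000 so scores are comparable across
#' analyses. The mean is taken over all cross-protein cells, zeros
#' included. The highest normalized cell is reported as the top
#' interaction (ties broken toward the smallest position pair).
#'
#' @param pa A [pair_alignments()] result.
#' @param filters A [filter_params()] object (see [filter_preset()]).
#' @param base Logarithm base passed to [pair_mi()].
#' @return An object of class `score_matrix`: `raw` and `normalized`
#'   matrices (rows = protein-1 reference positions, columns = protein-2),
#'   `top` (list `position1`, `position2`, `score`), `no_signal` flag, and
#'   the filters used. When every raw score is 0 the comparison carries no
#'   signal: all normalized scores are 0 and `no_signal` is `TRUE`.
#' @export
score_comparison <- function(pa, filters = filter_params(),
                             base = exp(1)) {
  stopifnot(inherits(pa, "paired_alignment"),
            inherits(filters, "filter_params"))
  m1 <- .encode_alignment(pa$seq1, pa$refcols1)
  m2 <- .encode_alignment(pa$seq2, pa$refcols2)
  L1 <- ncol(m1); L2 <- ncol(m2)
  tau <- filters$min_px
  rmul <- 1 + filters$pct_above_random / 100
  raw <- matrix(0, L1, L2,
                dimnames = list(as.character(seq_len(L1)),
                                as.character(seq_len(L2))))
  for (i in seq_len(L1)) {
    ci <- m1[, i]
    for (j in seq_len(L2)) {
      raw[i, j] <- .pair_mi_codes(ci, m2[, j], tau, rmul, base)
    }
  }
  norm <- .normalize_scores(raw)
  top <- if (norm$no_signal) {
    list(position1 = NA_integer_, position2 = NA_integer_, score = 0)
  } else {
    .top_cell(norm$normalized)
  }
  structure(list(raw = raw, normalized = norm$normalized, top = top,
                 no_signal = norm$no_signal, filters = filters),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("Score matrix: %d x %d reference positions\n",
              nrow(x$raw), ncol(x$raw)))
  if (x$no_signal) {
    cat("  no signal: every raw mutual-information score is 0\n")
  } else {
    cat(sprintf("  top normalized score %.2f at positions %d / %d\n",
                x$top$score, x$top$position1, x$top$position2))
  }
  invisible(x)
}
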