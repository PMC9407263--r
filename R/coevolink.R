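#' Scan two proteins for coevolving residue pairs
#'
#' The main entry point: reads (or accepts) two multiple sequence
#' alignments of orthologs, restricts them to their common species, scores
#' every cross-protein residue-position pair with filtered mutual
#' information, normalizes by the comparison-wide average (x 10,000), and
#' converts the top normalized score into a calibrated percent chance
#' that the two proteins interact.
#'
#' @param alignment1,alignment2 Paths to aligned FASTA files or
#'   [protein_alignment()] objects, one per protein.
#' @param reference Header of the reference species; residue positions in
#'   the output are 1-based positions in this species' ungapped sequence.
#' @param taxon `"vertebrate"` or `"bacteria"`: selects both the tuned
#'   filter preset and the embedded probability table.
#' @param filters Optional [filter_params()] overriding the preset.
#' @param table Optional `probability_table` overriding the embedded one.
#' @param min_common Minimum number of shared species (default 100).
#' @param base Logarithm base for the mutual information (immaterial after
#'   normalization).
#' @param name1,name2 Protein names for reporting; default to the file
#'   base names (or `"protein1"` / `"protein2"`).
#' @return An object of class `coevolink`: the paired alignment, the
#'   [score_comparison()] result (`$scores`), the top interaction
#'   (`$top`), and the interaction likelihood in percent
#'   (`$probability`, with `$random = TRUE` when the top score is no
#'   better than random). Methods: [print()], [summary()],
#'   [plot.coevolink()] (score heatmap) and [predict.coevolink()]
#'   (probability lookup for new scores).
#' @examples
#' sim <- simulate_pair(simulation_spec(
#'   n_species = 120, len1 = 12, len2 = 12,
#'   planted = data.frame(col1 = 4, col2 = 9, eps = 0.05), seed = 7))
#' fit <- coevolink(sim$alignment1, sim$alignment2, reference = "sp0001")
#' fit
#' @export
coevolink <- function(alignment1, alignment2, reference,
                      taxon = c("vertebrate", "bacteria"),
                      filters = NULL, table = NULL, min_common = 100,
                      base = exp(1), name1 = NULL, name2 = NULL) {
  taxon <- match.arg(taxon)
  cl <- match.call()
  load <- function(x, default_name) {
    if (inherits(x, "protein_alignment"))
      return(list(aln = x, name = default_name))
    if (is.character(x) && length(x) == 1L)
      return(list(aln = read_alignment(x),
                  name = sub("\\.[^.]*$", "", basename(x))))
    .stop("alignments must be file paths or protein_alignment objects",
          "coevolink_domain_error")
  }
  in1 <- load(alignment1, "protein1")
  in2 <- load(alignment2, "protein2")
  if (is.null(name1)) name1 <- in1$name
  if (is.null(name2)) name2 <- in2$name
  if (is.null(filters)) filters <- filter_preset(taxon)
  if (is.null(table))
    table <- suppressWarnings(probability_table(taxon))
  pa <- pair_alignments(in1$aln, in2$aln, ref = reference,
                        min_common = min_common)
  sm <- score_comparison(pa, filters = filters, base = base)
  prob <- lookup_probability(max(sm$top$score, 0), table)
  structure(list(call = cl, name1 = name1, name2 = name2,
                 reference = reference, taxon = taxon, filters = filters,
                 table = table, paired = pa, scores = sm, top = sm$top,
                 no_signal = sm$no_signal,
                 probability = as.numeric(prob),
                 random = attr(prob, "no_better_than_random")[1L]),
            class = "coevolink")
}

#' @export
print.coevolink <- function(x, ...) {
  cat(sprintf("Coevolution scan: %s vs %s\n", x$name1, x$name2))
  cat(sprintf("  %d common species; reference '%s' (%d x %d residues)\n",
              length(x$paired$species), x$reference,
              x$paired$nref1, x$paired$nref2))
  cat(sprintf("  filters (%s): min residue frequency %.2f, %.0f%% above random\n",
              x$taxon, x$filters$min_px, x$filters$pct_above_random))
  if (x$no_signal) {
    cat("  no signal: every mutual-information score is 0\n")
  } else {
    cat(sprintf("  top normalized score: %.2f at residues %d (%s) / %d (%s)\n",
                x$top$score, x$top$position1, x$name1,
                x$top$position2, x$name2))
  }
  cat(sprintf("  chance of interaction: %.2f%%%s\n", x$probability,
              if (isTRUE(x$random)) " (no better than random)" else ""))
  invisible(x)
}

#' @export
summary.coevolink <- function(object, ...) {
  norm <- object$scores$normalized
  structure(list(fit = object,
                 quantiles = stats::quantile(
                   norm, c(0, 0.5, 0.9, 0.99, 1)),
                 n_pairs = length(norm),
                 n_positive = sum(norm > 0),
                 mean_normalized = mean(norm)),
            class = "summary.coevolink")
}

#' @export
print.summary.coevolink <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d position pairs scored, %d with positive score (mean %.0f)\n",
              x$n_pairs, x$n_positive, x$mean_normalized))
  cat("  normalized score quantiles:\n")
  print(round(x$quantiles, 2))
  invisible(x)
}

#' Heatmap of the normalized score matrix
#'
#' @param x A [coevolink()] fit.
#' @param ... Passed to [render_heatmap()].
#' @return The rendered array, invisibly (see [render_heatmap()]).
#' @export
plot.coevolink <- function(x, ...) {
  render_heatmap(x, path = NULL,
                 xlab = sprintf("%s residue position", x$name1),
                 ylab = sprintf("%s residue position", x$name2), ...)
}

#' Interaction likelihood for new scores
#'
#' Looks up normalized scores in the fit's probability table.
#'
#' @param object A [coevolink()] fit.
#' @param newscores Numeric vector of normalized scores; defaults to the
#'   fit's own top score.
#' @param ... Unused.
#' @return Percent chance of interaction per score.
#' @export
predict.coevolink <- function(object, newscores = NULL, ...) {
  if (is.null(newscores)) newscores <- object$top$score
  lookup_probability(newscores, object$table)
}
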