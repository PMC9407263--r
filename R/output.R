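# Output writers: summary TSV (append), detailed CSV, heatmap image.

.summary_header <- c("protein1", "protein2", "position1", "position2",
                     "score", "likelihood")

#' Append one scan result to a summary TSV
#'
#' Writes a single tab-separated line — protein names, top-scoring
#' residue positions, top normalized score and percent likelihood — to
#' `path`. The file is appended to, never overwritten, so one file can
#' accumulate the results of many analyses; the header is written only
#' when the file is created.
#'
#' @param x A [coevolink()] fit, or a list with fields `protein1`,
#'   `protein2`, `position1`, `position2`, `score`, `likelihood`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(x, path) {
  rec <- if (inherits(x, "coevolink")) {
    list(protein1 = x$name1, protein2 = x$name2,
         position1 = x$top$position1, position2 = x$top$position2,
         score = x$top$score, likelihood = x$probability)
  } else {
    x
  }
  if (!all(.summary_header %in% names(rec)))
    .stop(paste("summary record needs fields:",
                paste(.summary_header, collapse = ", ")),
          "coevolink_domain_error")
  new <- !file.exists(path) || file.size(path) == 0L
  con <- tryCatch(file(path, open = "a"),
                  error = function(e) .stop(
                    sprintf("cannot open '%s' for appending", path),
                    "coevolink_io_error"))
  on.exit(close(con))
  if (new)
    writeLines(paste(.summary_header, collapse = "\t"), con)
  line <- paste(rec$protein1, rec$protein2, rec$position1, rec$position2,
                format(rec$score, digits = 10),
                sprintf("%.2f", rec$likelihood), sep = "\t")
  writeLines(line, con)
  invisible(path)
}

.score_matrix_of <- function(x) {
  if (inherits(x, "coevolink")) return(x$scores$normalized)
  if (inherits(x, "score_matrix")) return(x$normalized)
  if (is.matrix(x)) return(x)
  .stop("expected a coevolink fit, score_matrix or matrix",
        "coevolink_domain_error")
}

#' Write the position-wise score matrix as CSV
#'
#' Matrix layout: the first row holds protein-2 reference positions, the
#' first column protein-1 reference positions, cells the normalized
#' scores at full precision. Overwrites `path`.
#'
#' @param x A [coevolink()] fit, `score_matrix`, or plain matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_detail <- function(x, path) {
  m <- .score_matrix_of(x)
  if (length(m) == 0L)
    .stop("score matrix is empty", "coevolink_domain_error")
  cn <- colnames(m); if (is.null(cn)) cn <- as.character(seq_len(ncol(m)))
  rn <- rownames(m); if (is.null(rn)) rn <- as.character(seq_len(nrow(m)))
  lines <- c(paste(c("", cn), collapse = ","),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rn[i], sprintf("%.17g", m[i, ])), collapse = ","),
               character(1)))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE)
  if (!ok)
    .stop(sprintf("cannot write '%s'", path), "coevolink_io_error")
  invisible(path)
}

#' Render the score matrix as a heatmap
#'
#' Protein-1 reference positions run along the x axis, protein-2
#' positions along the y axis, and cell colour encodes the normalized
#' score; a colour bar is drawn alongside. With `path` set, the image is
#' written as PNG; otherwise it is drawn on the current device.
#'
#' @param x A [coevolink()] fit, `score_matrix`, or plain matrix.
#' @param path Optional PNG output path.
#' @param xlab,ylab Axis labels.
#' @param n_colors Number of colour bins (default 100).
#' @param width,height PNG size in pixels.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, a list with the score matrix (`scores`), the
#'   per-cell colour bin indices (`color_index`, same shape) and the
#'   palette (`colors`) — the rendered array before encoding.
#' @export
render_heatmap <- function(x, path = NULL, xlab = "protein 1 position",
                           ylab = "protein 2 position", n_colors = 100,
                           width = 800, height = 700, ...) {
  m <- .score_matrix_of(x)
  if (length(m) == 0L)
    .stop("score matrix is empty", "coevolink_domain_error")
  zlim <- range(m)
  if (zlim[1] == zlim[2]) zlim <- zlim + c(-0.5, 0.5)  # constant matrix
  pal <- grDevices::hcl.colors(n_colors, "viridis")
  idx <- matrix(pmin(pmax(findInterval(
    m, seq(zlim[1], zlim[2], length.out = n_colors + 1),
    rightmost.closed = TRUE), 1L), n_colors),
    nrow(m), ncol(m), dimnames = dimnames(m))
  if (!is.null(path)) {
    ok <- tryCatch({
      grDevices::png(path, width = width, height = height)
      TRUE
    }, error = function(e) FALSE)
    if (!ok)
      .stop(sprintf("cannot write '%s'", path), "coevolink_io_error")
    on.exit(grDevices::dev.off())
  }
  pos1 <- suppressWarnings(as.numeric(rownames(m)))
  pos2 <- suppressWarnings(as.numeric(colnames(m)))
  if (length(pos1) == 0L || anyNA(pos1)) pos1 <- seq_len(nrow(m))
  if (length(pos2) == 0L || anyNA(pos2)) pos2 <- seq_len(ncol(m))
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  graphics::layout(matrix(1:2, 1L), widths = c(5, 1))
  graphics::par(mar = c(4.5, 4.5, 2, 1))
  graphics::image(pos1, pos2, m, zlim = zlim, col = pal,
                  xlab = xlab, ylab = ylab, ...)
  # colour bar
  graphics::par(mar = c(4.5, 1, 2, 3))
  ticks <- seq(zlim[1], zlim[2], length.out = n_colors)
  graphics::image(1, ticks, matrix(ticks, 1L), zlim = zlim, col = pal,
                  axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4)
  invisible(list(scores = m, color_index = idx, colors = pal))
}
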