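#' Construct a protein alignment object
#'
#' An alignment is an ordered set of equal-length aligned amino-acid
#' sequences keyed by their full FASTA headers. Sequences are upper-cased
#' and `.` gaps are converted to `-`. Duplicate headers are collapsed to
#' the first occurrence with a warning.
#'
#' @param records Named character vector of aligned sequences (may contain
#'   `-` gaps).
#' @return An object of class `protein_alignment` with elements `records`
#'   (named character vector) and `width` (number of alignment columns).
#' @examples
#' aln <- protein_alignment(c(sp1 = "AC-D", sp2 = "ACAD"))
#' aln$width
#' @export
protein_alignment <- function(records) {
  if (length(records) == 0L)
    .stop("alignment contains no sequences", "coevolink_format_error")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    .stop("every sequence needs a non-empty header", "coevolink_format_error")
  records <- toupper(chartr(".", "-", records))
  widths <- nchar(records)
  if (length(unique(widths)) != 1L)
    .stop(sprintf(
      "ragged alignment: sequence lengths range from %d to %d",
      min(widths), max(widths)), "coevolink_format_error")
  bad <- grepl("[^A-Z-]", records)
  if (any(bad))
    .stop(sprintf("non-residue characters in sequence '%s'",
                  names(records)[bad][1L]), "coevolink_format_error")
  dup <- duplicated(names(records))
  if (any(dup)) {
    warning(sprintf(
      "%d duplicate header(s) dropped, keeping first occurrence: %s",
      sum(dup), paste(unique(names(records)[dup]), collapse = ", ")),
      call. = FALSE)
    records <- records[!dup]
  }
  structure(list(records = records, width = unname(widths[1L])),
            class = "protein_alignment")
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned FASTA file (one protein, orthologs across
#'   species; headers identify species).
#' @return A [protein_alignment()] object.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-", ">s2", "AAG"), f)
#' read_alignment(f)
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    .stop(sprintf("file not found: %s", path), "coevolink_io_error")
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) .stop(
      sprintf("could not parse '%s' as FASTA: %s", path,
              conditionMessage(e)),
      "coevolink_format_error")
  )
  if (length(set) == 0L)
    .stop(sprintf("no FASTA records in '%s'", path),
          "coevolink_format_error")
  seqs <- as.character(set)
  names(seqs) <- names(set)
  protein_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param alignment A [protein_alignment()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  stopifnot(inherits(alignment, "protein_alignment"))
  set <- Biostrings::BStringSet(alignment$records)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d sequences x %d columns\n",
              length(x$records), x$width))
  show <- utils::head(names(x$records), 3L)
  cat("  headers:", paste(show, collapse = ", "),
      if (length(x$records) > 3L) "..." else "", "\n")
  invisible(x)
}

#' Pair two alignments on their common species
#'
#' Restricts both alignments to the species (exact full-header match)
#' present in both files, in the order of the first file, and builds
#' reference-coordinate maps: alignment columns where the chosen reference
#' species has a gap are dropped, and the remaining columns are numbered
#' 1..n along the ungapped reference sequence.
#'
#' @param a1,a2 [protein_alignment()] objects for protein 1 and protein 2.
#' @param ref Header of the reference species; must be present in both
#'   alignments. Reported residue positions are 1-based positions in this
#'   species' ungapped sequence.
#' @param min_common Minimum number of shared species required (default
#'   100, the sampling depth needed for stable column frequencies).
#' @return An object of class `paired_alignment` with elements `species`,
#'   `seq1`, `seq2` (named aligned sequences restricted to the common
#'   species), `refcols1`, `refcols2` (alignment column indices kept),
#'   `ref`, and `nref1`, `nref2` (reference sequence lengths).
#' @examples
#' a1 <- protein_alignment(c(r = "A-C", s2 = "AGC", s3 = "TGC"))
#' a2 <- protein_alignment(c(r = "DE", s3 = "DD", s4 = "EE"))
#' pair_alignments(a1, a2, ref = "r", min_common = 2)
#' @export
pair_alignments <- function(a1, a2, ref, min_common = 100) {
  stopifnot(inherits(a1, "protein_alignment"),
            inherits(a2, "protein_alignment"))
  n1 <- names(a1$records); n2 <- names(a2$records)
  if (!(ref %in% n1) || !(ref %in% n2))
    .stop(sprintf("reference species '%s' absent from %s", ref,
                  if (ref %in% n1) "alignment 2" else
                    if (ref %in% n2) "alignment 1" else "both alignments"),
          "coevolink_missing_reference")
  species <- n1[n1 %in% n2]            # protein-1 file order
  if (length(species) < min_common)
    .stop(sprintf(
      "only %d species shared between the alignments (minimum %d)",
      length(species), min_common), "coevolink_insufficient_species")
  seq1 <- a1$records[species]
  seq2 <- a2$records[species]
  refcols <- function(seq) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    which(ch != "-")
  }
  rc1 <- refcols(seq1[[ref]])
  rc2 <- refcols(seq2[[ref]])
  if (length(rc1) == 0L || length(rc2) == 0L)
    .stop("reference sequence is all gaps", "coevolink_format_error")
  structure(list(species = species, seq1 = seq1, seq2 = seq2,
                 refcols1 = rc1, refcols2 = rc2, ref = ref,
                 nref1 = length(rc1), nref2 = length(rc2)),
            class = "paired_alignment")
}

#' Reference coordinate map of a paired alignment
#'
#' @param pa A [pair_alignments()] result.
#' @param protein 1 or 2.
#' @return Data frame with columns `column` (alignment column index) and
#'   `position` (1-based reference residue position).
#' @export
refmap <- function(pa, protein = 1) {
  stopifnot(inherits(pa, "paired_alignment"), protein %in% c(1, 2))
  cols <- if (protein == 1) pa$refcols1 else pa$refcols2
  data.frame(column = cols, position = seq_along(cols))
}

#' @export
print.paired_alignment <- function(x, ...) {
  cat(sprintf(paste0(
    "Paired alignment: %d common species\n",
    "  reference '%s': protein 1 has %d residues, protein 2 has %d\n"),
    length(x$species), x$ref, x$nref1, x$nref2))
  invisible(x)
}
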