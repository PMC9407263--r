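# Shared constants and condition helpers.

# The 20 standard amino acids; anything else (gaps, B/J/O/U/X/Z ambiguity
# codes) is excluded from frequency counts.
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.N_AA <- 20L

.stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "coevolink_error"),
                      call = call))
}

#' @noRd
.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min &&
    x == as.integer(x)
}

# Encode aligned sequences as an integer matrix (species x columns):
# 1..20 for the standard residues, 0 for gap or ambiguity.
.encode_alignment <- function(seqs, columns = NULL) {
  chars <- strsplit(unname(seqs), "", fixed = TRUE)
  width <- length(chars[[1L]])
  m <- matrix(
    match(unlist(chars), .AA, nomatch = 0L),
    nrow = length(seqs), ncol = width, byrow = TRUE,
    dimnames = list(names(seqs), NULL)
  )
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  m
}
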