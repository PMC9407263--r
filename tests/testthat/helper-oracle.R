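# Independent oracles and fixture builders, deliberately naive.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Brute-force evaluation of the filtered mutual-information sum by
# looping over residue combinations. Mirrors only the *definition*:
# marginal filter tau on p(x) and p(y); joint filter active for r > 0.
naive_mi <- function(col1, col2, tau = 0, r = 0, base = exp(1)) {
  keep <- col1 %in% AA20 & col2 %in% AA20
  col1 <- col1[keep]; col2 <- col2[keep]
  if (length(col1) == 0L) return(0)
  total <- 0
  for (x in unique(col1)) {
    for (y in unique(col2)) {
      pxy <- mean(col1 == x & col2 == y)
      if (pxy == 0) next
      px <- mean(col1 == x)
      py <- mean(col2 == y)
      if (px < tau || py < tau) next
      if (r > 0 && pxy < (1 + r / 100) * px * py) next
      total <- total + pxy * log(pxy / (px * py), base = base)
    }
  }
  total
}

# Brute-force AUC: proportion of (known, unknown) pairs where the known
# score wins, half-credit for ties.
naive_auc <- function(known, unknown) {
  wins <- 0
  for (k in known) for (u in unknown)
    wins <- wins + (k > u) + 0.5 * (k == u)
  wins / (length(known) * length(unknown))
}

# Random column over a restricted alphabet, with optional gaps.
random_column <- function(n, n_res = 4, gap_prob = 0) {
  col <- sample(AA20[seq_len(n_res)], n, replace = TRUE)
  if (gap_prob > 0) col[runif(n) < gap_prob] <- "-"
  col
}

# Small paired alignment built from explicit per-species column strings.
make_pair <- function(seqs1, seqs2, ref = names(seqs1)[1L],
                      min_common = 2) {
  pair_alignments(protein_alignment(seqs1), protein_alignment(seqs2),
                  ref = ref, min_common = min_common)
}

# Alignment whose columns are supplied as a list of residue vectors.
alignment_from_columns <- function(cols, species = NULL) {
  n <- length(cols[[1L]])
  if (is.null(species)) species <- sprintf("s%03d", seq_len(n))
  m <- do.call(cbind, cols)
  protein_alignment(setNames(apply(m, 1L, paste, collapse = ""), species))
}
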