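#' Specification of a synthetic paired-alignment simulation
#'
#' Describes a pair of ortholog-style alignments sharing `n_species`
#' species, with independently drawn background columns and one or more
#' planted coevolving column pairs. A planted pair is generated by drawing
#' protein-1 residues from a variable-column profile and mapping them into
#' protein 2 through a fixed random bijection of the amino-acid alphabet;
#' a fraction `eps` of species is then resampled independently, degrading
#' the signal from perfect covariation (`eps = 0`) to independence
#' (`eps = 1`).
#'
#' Background columns default to per-column Dirichlet "conserved" profiles
#' (most columns dominated by a few residues, as in real ortholog
#' alignments); `background = "uniform"` draws every column uniformly over
#' the 20 amino acids instead. Gaps are inserted independently at
#' `gap_rate` in every row except the reference (species 1), which stays
#' ungapped so alignment columns coincide with reference positions.
#'
#' @param n_species Number of species (default 150).
#' @param len1,len2 Column counts of the two alignments (default 30).
#' @param planted Data frame (or list of length-3 vectors) with columns
#'   `col1`, `col2`, `eps`: planted coevolving column pairs and their
#'   noise levels in `[0, 1]`.
#' @param background `"conserved"` (default) or `"uniform"`.
#' @param gap_rate Per-cell gap probability in non-reference rows
#'   (default 0.02).
#' @param seed Integer seed; identical seeds give identical alignments.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_species = 150, len1 = 30, len2 = 30,
                            planted = data.frame(col1 = integer(0),
                                                 col2 = integer(0),
                                                 eps = numeric(0)),
                            background = c("conserved", "uniform"),
                            gap_rate = 0.02, seed = NULL) {
  background <- match.arg(background)
  if (!.is_count(n_species, 1L) || !.is_count(len1, 1L) ||
      !.is_count(len2, 1L))
    .stop("n_species, len1 and len2 must be positive integers",
          "coevolink_domain_error")
  if (is.list(planted) && !is.data.frame(planted))
    planted <- do.call(rbind, lapply(planted, function(p)
      data.frame(col1 = p[[1L]], col2 = p[[2L]], eps = p[[3L]])))
  if (nrow(planted) > 0L) {
    if (any(planted$col1 < 1 | planted$col1 > len1) ||
        any(planted$col2 < 1 | planted$col2 > len2))
      .stop("planted columns out of bounds", "coevolink_domain_error")
    if (any(planted$eps < 0 | planted$eps > 1))
      .stop("noise eps must lie in [0, 1]", "coevolink_domain_error")
    if (anyDuplicated(planted$col1) || anyDuplicated(planted$col2))
      .stop("each column may carry at most one planted pair",
            "coevolink_domain_error")
  }
  if (!is.numeric(gap_rate) || gap_rate < 0 || gap_rate >= 1)
    .stop("gap_rate must lie in [0, 1)", "coevolink_domain_error")
  structure(list(n_species = as.integer(n_species),
                 len1 = as.integer(len1), len2 = as.integer(len2),
                 planted = planted, background = background,
                 gap_rate = gap_rate, seed = seed),
            class = "simulation_spec")
}

# Column residue profile. Background "conserved": Dirichlet(0.3) over the
# 20 residues, so most columns are dominated by a handful of residues.
# Planted columns use 4 effective residues with Dirichlet(3) weights:
# coevolving positions must be variable to carry covariation signal, and
# the moderate frequencies keep individual residues observable.
.bg_profile <- function(background) {
  if (background == "uniform") return(rep(1 / .N_AA, .N_AA))
  w <- stats::rgamma(.N_AA, shape = 0.3)
  if (sum(w) == 0) w[sample.int(.N_AA, 1L)] <- 1
  w / sum(w)
}

.planted_profile <- function(n_states = 4L) {
  states <- sample.int(.N_AA, n_states)
  w <- stats::rgamma(n_states, shape = 3)
  p <- rep(0, .N_AA)
  p[states] <- w / sum(w)
  p
}

#' Simulate a paired alignment with planted coevolving columns
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `simulated_pair`: `alignment1`, `alignment2`
#'   ([protein_alignment()] objects), `truth` (data frame `col1`, `col2`,
#'   `eps`, `ref_pos1`, `ref_pos2` — reference positions equal column
#'   indices because the reference row is ungapped), and `spec`.
#' @examples
#' sp <- simulation_spec(n_species = 50, len1 = 8, len2 = 8,
#'                       planted = data.frame(col1 = 3, col2 = 5, eps = 0),
#'                       gap_rate = 0, seed = 1)
#' sim <- simulate_pair(sp)
#' sim$truth
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_species
  m1 <- matrix("", n, spec$len1)
  m2 <- matrix("", n, spec$len2)
  for (j in seq_len(spec$len1))
    m1[, j] <- sample(.AA, n, replace = TRUE,
                      prob = .bg_profile(spec$background))
  for (j in seq_len(spec$len2))
    m2[, j] <- sample(.AA, n, replace = TRUE,
                      prob = .bg_profile(spec$background))
  if (nrow(spec$planted) > 0L) {
    for (k in seq_len(nrow(spec$planted))) {
      c1 <- spec$planted$col1[k]; c2 <- spec$planted$col2[k]
      eps <- spec$planted$eps[k]
      prof <- .planted_profile()
      sigma <- sample(.AA)               # bijection of the alphabet
      draw <- sample(.AA, n, replace = TRUE, prob = prof)
      partner <- sigma[match(draw, .AA)]
      flip <- stats::runif(n) < eps      # resample a fraction independently
      if (any(flip))
        partner[flip] <- sample(sigma, sum(flip), replace = TRUE,
                                prob = prof)
      m1[, c1] <- draw
      m2[, c2] <- partner
    }
  }
  if (spec$gap_rate > 0 && n > 1L) {
    gap <- function(m) {
      hit <- matrix(stats::runif(length(m)) < spec$gap_rate,
                    nrow(m), ncol(m))
      hit[1L, ] <- FALSE                 # reference row stays ungapped
      m[hit] <- "-"
      m
    }
    m1 <- gap(m1); m2 <- gap(m2)
  }
  species <- sprintf("sp%04d", seq_len(n))
  collapse <- function(m) stats::setNames(
    apply(m, 1L, paste, collapse = ""), species)
  truth <- spec$planted
  truth$ref_pos1 <- truth$col1
  truth$ref_pos2 <- truth$col2
  structure(list(alignment1 = protein_alignment(collapse(m1)),
                 alignment2 = protein_alignment(collapse(m2)),
                 truth = truth, spec = spec),
            class = "simulated_pair")
}

#' Simulate labeled score sets
#'
#' Draws `n_unknown` scores from a right-skewed log-normal base
#' distribution and `n_known` scores from the same distribution with its
#' log-mean shifted by the effect size, emulating the score separation
#' between interacting and not-known-to-interact protein pairs.
#'
#' @param n_known,n_unknown Sample sizes (>= 1).
#' @param shift Effect size on the log scale (0 gives AUC ~ 0.5; large
#'   values approach complete separation).
#' @param seed Optional integer seed.
#' @return A [labeled_scores()] object.
#' @export
simulate_labeled_scores <- function(n_known, n_unknown, shift = 1,
                                    seed = NULL) {
  if (!.is_count(n_known, 1L) || !.is_count(n_unknown, 1L))
    .stop("sample sizes must be positive integers",
          "coevolink_domain_error")
  if (!is.null(seed)) set.seed(seed)
  labeled_scores(stats::rlnorm(n_known, meanlog = shift, sdlog = 1),
                 stats::rlnorm(n_unknown, meanlog = 0, sdlog = 1))
}
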