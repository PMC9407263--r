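---
title: "Scanning for inter-protein residue coevolution with filtered mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning for inter-protein residue coevolution with filtered mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevolink)
```

## The problem and the model

Residues that participate in a functional contact between two proteins
tend to change together across evolution: a substitution on one side is
compensated on the other, and the compensated pair becomes fixed. Given
multiple sequence alignments of orthologs for two proteins — one file per
protein, headers naming the species — this covariation is measurable
column by column. `coevolink` scores every cross-protein pair of residue
positions with the mutual information of their empirical residue
distributions,

$$MI(X, Y) = \sum_{x \in X} \sum_{y \in Y} p_{XY}(x,y)\,
  \log \frac{p_{XY}(x,y)}{p_X(x)\,p_Y(y)},$$

where $X$ and $Y$ are the residue sets observed at a position of protein
1 and protein 2, $p_X(x)$ and $p_Y(y)$ are per-column residue
frequencies, and $p_{XY}(x,y)$ is the frequency of the species carrying
$x$ and $y$ simultaneously. Only cross-protein position pairs are
scored; intra-protein pairs are never computed, because the aim is
interaction prioritization, not fold prediction.

The two alignments must share at least 100 species (exact, full-header
matching) so that column frequencies are estimated from a reasonable
sample; species absent from either file are dropped. Positions are
reported in the coordinates of a user-chosen reference species: columns
where the reference carries a gap are removed, and the remaining columns
are numbered 1..n along its ungapped sequence, which is the numbering a
biologist can map onto the actual protein.

## Per-term filters

Empirical MI is noisy upward: finite sampling makes $p_{XY}$ deviate
from $p_X p_Y$ even for independent columns, and each deviation
contributes a small positive artifact. Two filters are therefore applied
to each *partial* term (each residue combination) before summation:

* **`min_px`** ($\tau$): a combination counts only if both marginal
  frequencies reach $\tau$. Rare residues carry the least reliable
  frequency estimates.
* **`pct_above_random`** ($r$): the joint frequency must exceed its
  independence expectation by at least $r$ percent,
  $p_{XY} \ge (1 + r/100)\, p_X p_Y$. Every retained term then has
  $p_{XY} > p_X p_Y$, so filtered scores are non-negative.

A column pair whose every term is filtered scores 0. With $r = 0$ the
joint filter is off and all observed combinations enter the sum, which
makes `pair_mi()` coincide with the textbook mutual information of the
empirical joint distribution — the natural limiting behaviour, and the
one property tests pin down. (An always-on $\ge p_X p_Y$ predicate
would silently discard the negative partial terms of plain MI.)

Species with a gap or a non-standard residue (anything outside the 20
amino acids) at either column of a pair are excluded from that pair's
counts, and frequencies are renormalized over the remaining species. A
gap is the absence of a residue; treating it as a 21st coevolving state
would reward shared indel patterns rather than residue covariation.

Defaults are taxon presets from the grid search described below:
vertebrates $\tau = 0.17$, $r = 35$; bacteria $\tau = 0.29$, $r = 22$.

## Normalization

Raw MI values are not comparable across protein pairs: column diversity,
alignment depth and composition all shift the scale. Each cell is
therefore divided by the mean raw score of the *entire* comparison
(all cross-protein cells, zeros included — the whole comparison is the
background being corrected for, in the spirit of the average-product
correction) and multiplied by 10,000 for readability. Consequences worth
knowing:

* the mean normalized score is exactly 10,000 whenever any raw score is
  positive;
* the logarithm base cancels in the ratio, so natural log (the default)
  and log2 give identical normalized matrices — the suite asserts this;
* if every raw score is 0 the comparison is flagged `no_signal` and all
  normalized scores are defined as 0.

The highest normalized cell is the reported interaction; ties break
deterministically toward the smallest (position 1, position 2) pair so
that repeated runs append identical summary lines.

## From score to probability

The top normalized score is mapped to a percent chance of true
interaction through a step-function table calibrated on labeled score
sets (pairs known to interact vs pairs with no known interaction).
Tables for vertebrates and bacteria ship with the package as TSV
resources. Lookup is inclusive at the boundary (a score equal to a
threshold receives that threshold's percent), open-ended upward, and
falls back to a 50% baseline — "no better than random" — below the
lowest threshold. The baseline reflects that the labeling is far more
likely to miss true interactions than to invent false ones, so a low
score is uninformative rather than evidence against interaction.

The bacteria table contains one cell (score 23.93 → 75.58%) that breaks
the otherwise monotone descent between its neighbours (96.56 above,
95.09 below) — almost certainly a transcription error in the calibrated
output. Fidelity comes first: the table is embedded as calibrated and
requesting it as-is warns; `probability_table("bacteria", monotonize =
TRUE)` replaces the cell by the mean of its neighbours (95.825%).
Whether printed thresholds are bin lower edges or midpoints is not
documented either; lookups treat them as inclusive lower edges.

`build_probability_table()` reconstructs such tables from labeled
scores: 20 equal-width bins spanning `[0, max score]`, per-bin
probability `known / (known + unknown)`, bins at or below 50% (and empty
bins) at the bottom of the range merged into the baseline region. Above
it, empty bins pool with the bin below, and adjacent bins violating
monotonicity pool their counts until the step is monotone non-decreasing
in score — raw bin proportions are not guaranteed monotone, and a
probability that dipped as the score rose would be uninterpretable as a
calibration. Pooling by summed counts is the adjacent-violators
estimator, so well-separated inputs are left untouched.

## Filter tuning

`tune_filters()` reruns the scoring for every combination of a filter
grid — by default $\tau$ from 0 to 0.35 in steps of 0.01 and $r$ from 10
to 49% in steps of 1, i.e. $36 \times 40 = 1440$ combinations, with the
grid built from integer sequences so floating-point drift can never
change its size — and summarizes each combination's labeled scores with
`evaluate_combination()`:

* a two-sample *t*-test p-value (Welch by default, since group sizes and
  variances differ in practice; Student's pooled variant is an option);
* Cohen's d with the pooled standard deviation (the classic definition);
* ROC AUC in the rank (Mann–Whitney) formulation with half-credit for
  ties, which equals the probability that a random interacting pair
  outscores a random non-interacting one;
* the best precision over score cutoffs subject to recall ≥ 20%, ties
  broken toward higher recall.

`select_filters()` picks the combination with the highest constrained
precision — precision is prioritized because the tool's job is to rank
candidates for expensive follow-up — breaking ties by higher AUC and
then by the smaller $(\tau, r)$ pair, so the selection is invariant to
the order rows are supplied. `bonferroni_alpha(0.05, 2880)` gives the
corrected significance level ($1.74 \times 10^{-5}$) for judging the
grid's t-tests across two taxa. Running the full grid on real alignment
sets is expensive (it rescoring every pair 1440 times); the test suite
exercises the machinery on small grids and synthetic pairs.

## What the simulator emulates — and what it does not

`simulate_pair()` generates paired ortholog-style alignments with known
ground truth so every stage is testable without downloads:

* **Background columns** are drawn independently per species from
  per-column Dirichlet(0.3) profiles over the 20 amino acids, so most
  columns are dominated by a few residues — the conservation spread of
  real ortholog alignments. A `background = "uniform"` option draws all
  residues equally; it is useful for exercising the $\tau$ filter
  (uniform columns put every frequency near 0.05, below any realistic
  $\tau$), but it is not the default precisely because real columns are
  not uniform.
* **Planted coevolving pairs** draw the protein-1 column from a profile
  over 4 effective residues (Dirichlet(3) weights) and map it into
  protein 2 through a fixed random bijection of the alphabet; a fraction
  $\varepsilon$ of species is then resampled independently. At
  $\varepsilon = 0$ the joint distribution is a bijection and the raw MI
  equals the entropy of the column-1 distribution (an analytically known
  ceiling); at $\varepsilon = 1$ the pair is independent. Coevolving
  columns are modeled as variable (a conserved column carries no
  covariation signal), with frequencies around 0.25 so individual
  residues are observable above the vertebrate $\tau$.
* **Gaps** are inserted independently at a per-cell rate (default 0.02)
  in every row except the reference species (species 1), which stays
  ungapped so that alignment columns coincide with reference positions
  and the planted truth table needs no coordinate translation.

Deliberate simplifications: species are exchangeable — there is no
phylogeny, no rate heterogeneity, no indel process, no tree-structured
covariance. The MI statistic under test is itself phylogeny-agnostic, so
these simulations probe exactly what the statistic can and cannot do;
passing them says nothing about confounding by shared ancestry in real
alignments, where related species contribute correlated observations.
`simulate_labeled_scores()` similarly fakes calibration inputs from a
log-normal base distribution with a log-scale shift for the interacting
class.

Under the default study conditions — 150 species, 30 × 30 columns, one
planted pair at $\varepsilon = 0.1$, vertebrate preset — the pipeline
recovers the planted coordinates as the top interaction in at least 9 of
10 seeds; the acceptance suite measures this end to end.

## Numerical and design choices

* Natural log by default; immaterial after normalization (asserted).
* Header matching is exact full-string equality; no tokenization. The
  first occurrence of a duplicated header wins, with a warning.
* Lower-case residues are upper-cased on read; `.` is accepted as a gap
  synonym.
* `min_common` is a parameter (default 100) so small fixtures can run;
  the CLI default enforces 100.
* Scores are computed in a single pass over integer-coded columns
  (`tabulate` over a 400-cell joint table per pair); a naive triple-loop
  evaluation of the definition lives in the test suite as the oracle and
  agrees to below 1e-12 on a thousand random column pairs.
* Test and acceptance problem sizes (150 species, 30 × 30 columns, 10
  seeds; 300–1000 oracle pairs) are chosen so the whole suite runs in
  seconds while keeping the planted-signal and sampling-noise regimes
  honest.

## Limitations

Shared phylogeny, alignment errors and paralog contamination all inflate
MI in real data and are not modeled here. The probability tables were
calibrated against interaction databases whose negatives are merely
"not known to interact", so the reported percent is an upper-bounded
prioritization aid, not a posterior from a clean labeled sample. Low
scores do not rule an interaction out. The scanner reports a single top
pair per comparison; proteins interacting through several interfaces
will surface only the strongest.
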