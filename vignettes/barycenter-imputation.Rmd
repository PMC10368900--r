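---
title: "Barycenter imputation of missing peptide intensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barycenter imputation of missing peptide intensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baryimpute)
```

## The problem

Label-free LC-MS quantification reports peptide intensities across runs,
and a substantial fraction of the resulting matrix is missing. The
mechanisms are heterogeneous. Stochastic precursor sampling (especially in
DDA) loses peptides essentially at random with respect to their abundance
in a given run: these entries are *missing at random* (MAR) and are well
predicted from the between-run correlation structure. Detection-limit
censoring loses low-abundance signal: these entries are *missing not at
random* (MNAR), and in a designed experiment they are often concentrated in
one experimental group, because a protein is down-regulated there. An
imputation method tuned to one mechanism damages data dominated by the
other: low-rank or neighbour-based methods pull censored values up towards
the observed mean (over-smoothing, inflated false positives downstream),
while left-censored imputation pushes randomly-missing values of abundant
peptides down by several standard deviations.

baryimpute imputes each missing entry under both assumptions and combines
the two estimates as a convex combination whose weights come from an
entropy-based classification of each peptide's missingness pattern.

## The procedure

The pipeline is: read, collapse features, log2, filter, impute, quantile
normalize. All modelling happens on the log2 scale.

### MAR estimate: softImpute-ALS

With `X` the m×n log2 matrix and Ω the observed entries, we fit factors
A (m×r) and B (n×r) minimizing

$$\tfrac12 \lVert P_\Omega(X - AB^T)\rVert_F^2 +
  \tfrac{\lambda}{2}\,(\lVert A\rVert_F^2 + \lVert B\rVert_F^2).$$

`softimpute_als()` initializes A = UD with a random orthonormal U and
D = I, and alternates two *exact* multiresponse ridge solves on a working
matrix whose missing entries hold the current fitted values: given A = UD,

$$\tilde B^T = (D^2 + \lambda I)^{-1} D U^T X^\ast,$$

then an SVD of \(\tilde B D\) re-orthogonalizes the factors; the step for A
is symmetric. We apply the rotation that keeps the product \(AB^T\)
unchanged by the re-orthogonalization, so each half-step can only lower the
objective (each solves its subproblem exactly on a surrogate that touches
the true objective at the current iterate). This monotonicity is asserted
in the test suite. X~MAR~ = AB^T^.

Assumptions worth stating: runs are exchangeable observations of a shared
low-dimensional structure. Runs from one offline-fractionated sample are
*not* independent; merge them into a single per-sample profile before
imputation, or the low-rank model is misspecified.

### Rank selection

`select_rank()` uses a rank-2 model whenever the study has fewer than 20
runs: with so few columns the spectrum of the completed matrix is estimated
too noisily to set the rank from it, and rank-2 reconstructions track
low-abundance variability better (visible in the mean–CV² diagnostic, see
below). For larger studies the rank is the rounded *effective rank*

$$\mathrm{erank}(X) = \exp\{H(p_1,\dots,p_Q)\}, \qquad
  p_k = \xi_k / \textstyle\sum_j \xi_j,$$

with ξ the singular values and H the Shannon entropy (natural log; zero
singular values contribute nothing). erank is scale-invariant and lies in
[1, min(m, n)].

The SVD needs a complete matrix, but the rank must be chosen *before*
imputing. We compute erank on a provisional completion that fills each
missing entry with its peptide's observed mean (column mean for a
pathological empty row). This choice is deliberately simple — it adds no
spurious between-run structure — but it is a design decision, not a
mathematically forced one; a different provisional fill can move erank by a
fraction of a unit. Rounding is round-half-to-even, then clipped to
[2, min(m, n) − 1] so the model is never trivial or saturated.

### MNAR estimate: the down-shift

`downshift_impute()` replaces the missing values of run k with independent
draws from

$$\mathcal N\!\left(\bar x_k - s\,\hat\sigma_k,\; (w\,\hat\sigma_k)^2\right),
  \qquad s = 1.8,\; w = 0.3,$$

where \(\bar x_k, \hat\sigma_k\) are the mean and sample standard deviation
(n−1 denominator) of the run's *observed* log2 intensities. The defaults
are the conventional left-censoring calibration: imputed values sit well
below the bulk of the observed distribution, in a band narrow enough not to
inflate within-group variance. Statistics are per run, the standard
Perseus-style convention; only a mean vector and an sd vector are
parameterized, so the draws use a diagonal covariance (runs independent). A
degenerate run with \(\hat\sigma_k = 0\) imputes the shifted constant
exactly.

### Classification and combination

For peptide i with observed fraction \(m_{ig}\) in group g,

$$\mathrm{EBM}_i = \sum_{g=1}^{G} m_{ig}\,\log m_{ig}.$$

If every group retains at least one observation, EBM is finite (0 for a
fully observed peptide): missingness is spread over groups, which is the
signature of a random mechanism. If any group is entirely missing,
EBM = −∞: the group-specific MNAR signature. The natural log is used; the
base only rescales finite values and the weight rule depends on finiteness
alone.

The final estimate at each missing entry is

$$X'_{ik} = \alpha_i^{\mathrm{MAR}}\, X^{\mathrm{MAR}}_{ik} +
            \alpha_i^{\mathrm{MNAR}}\, X^{\mathrm{MNAR}}_{ik},$$

with fixed weights \(\alpha^{\mathrm{MAR}} = 0.8\) when EBM is finite and
0.2 otherwise (`alpha_when_finite`, exposed for sensitivity analyses).
This elementwise convex combination *is* the barycenter (Fréchet mean) of
the two estimated distributions under squared-Euclidean distance; no
optimal-transport machinery is involved, and we do not resample from an
interpolated distribution. The weights are not estimated adaptively; the
argument accepts the full [0, 1] range so the boundary values recover the
pure single-mechanism imputers exactly (a property the tests exercise).

Observed entries pass through the pipeline bit-unchanged; this is asserted
at several levels of the test suite.

### Single-group designs

With G = 1, EBM is finite for every peptide with at least one observation,
so the pipeline degrades gracefully to 0.8·low-rank + 0.2·down-shift. This
is permitted but worth knowing about: with no replication structure the
group-specific MNAR signal is undetectable by construction.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `min_observed` | 4 | observations/peptide | smallest count that meaningfully constrains a rank-2 factor row; peptides below it are discarded by `filter_min_observed()` because no stable low-rank solution exists for them |
| `rank` | auto | — | 0 = `select_rank()`; override to force a rank |
| `lam` | 0.1 | log2-intensity² | ridge penalty; rank is controlled by `rank`, so a small λ just stabilizes the solves; larger values shrink the solution's spectrum (never increasing its numerical rank) |
| `shift` (s) | 1.8 | observed-run sd | downward displacement of the MNAR draw |
| `width` (w) | 0.3 | — | sd multiplier of the MNAR draw |
| `alpha_when_finite` | 0.8 | — | MAR weight for finite-EBM peptides |
| `tol`, `max_iter` | 1e-5, 100 | — | ALS stops when the relative objective change drops below `tol`; hitting `max_iter` warns and returns `converged = FALSE` rather than failing |
| `seed` | 1 | — | ALS initialization uses `seed`, the down-shift draws `seed + 1`; identical seeds give bit-identical results |

Normalization order is `log2 → impute → quantile-normalize`. A
`normalize = "before"` flag normalizes the incomplete matrix from observed
entries only (limma's NA-tolerant quantile interpolation) for users who
prefer normalizing first; whether normalization statistics should exclude
imputed entries has no settled answer, so both orders are exposed and
neither is asserted as correct. Quantile normalization itself delegates to
`limma::normalizeQuantiles(ties = TRUE)`: every column's sorted values
become the across-column mean of sorted values, ties receiving the mean of
the reference values over the tied span.

## Numerical choices

* ALS convergence is measured on the objective, with
  \(|f_{t-1}-f_t| \le \mathrm{tol}\cdot f_{t-1}\); the trace is recorded
  every iteration and stored in the result's provenance.
* Ridge coefficients \(d_j/(d_j^2+\lambda)\) with \(d_j = \lambda = 0\)
  (a null component at zero penalty) are set to 0 rather than NaN.
* erank of an all-zero matrix is undefined and errors.
* `mean_cv_table()` computes CV = sd/mean on the log2 values (the
  diagnostic pairs average log intensity with the CV of those same
  values); a linear-scale option exists but is off by default. A peptide
  with mean 0 gets an NA CV² and is excluded from the loess trend
  (span 0.75, visualization only — no statistical claim attaches to it).
* Readers treat `""`, `NA`, `NaN` and `0` as missing by default (zeros are
  the common LFQ export convention for "not quantified"); the token set is
  configurable. Matrices are written with 17 significant digits so a
  write/read round trip reproduces the doubles exactly.
* Peptide identity in evidence tables is the modified sequence (falling
  back to the plain sequence), with charge states collapsed by keeping the
  maximum intensity per (peptide, run).

## The synthetic-data generator

`simulate_dataset()` emulates the data model the method assumes: Gaussian
peptide baselines (mean 20, sd 2 on the log2 scale — typical MS1 intensity
magnitudes), additive group effects of ±3 log2 units on a 10% DE subset
(spike-in scale), iid Gaussian noise (sd 0.5), and three disjoint
missingness mechanisms — uniform MAR masking, logistic intensity-dependent
censoring \(P(\text{miss}\mid x) = 1/(1+\exp((x-q)/\tau))\) around a low
quantile q (τ = 0.3 log2 units), and wholesale deletion of the
down-regulated group for a subset of DE peptides. Deleted groups force the
effect sign negative, so the censoring is biologically coherent (signal
lost *because* the protein is down).

What it does **not** emulate: quantification-software artifacts
(match-between-runs misidentifications, ragged peak integration),
peptide-level correlation within proteins, heteroscedastic noise, or batch
effects. Passing tests on this generator therefore demonstrate the
algorithm's internal correctness and its behaviour under the assumed
missingness mechanisms — not performance on any particular real dataset.

The test suite uses 1000 peptides × 12 runs (two groups of six) for the
recovery-ordering experiments and 2000 peptides × 10 replicate runs with
about 15% mixed missingness for the null-calibration experiment, each over
five seeds with a majority criterion; these sizes are the package's chosen
compromise between statistical resolution and a fast default test run. The
null experiment assigns technical replicates randomly to two groups of
five, imputes under that design, and compares the Kolmogorov–Smirnov
distance of the two-sample t-test p-values from uniformity — imputation
should not manufacture differential abundance.

The differential-abundance plumbing in `recovery_metrics()` uses classical
pooled two-sample t-tests with Benjamini–Hochberg correction. Moderated
(empirical-Bayes) test statistics would change absolute TP/FP counts;
the metrics here are for comparing imputation settings within the package,
not for benchmarking against published counts.

## Known limitations

* The weights are fixed (0.8/0.2), not estimated from the data; the EBM
  rule is binary and cannot express "mostly MAR with mild censoring" at
  the peptide level.
* Imputed values carry no uncertainty estimate, and downstream tests treat
  them as observed; empirical FDR can therefore exceed the nominal level.
* The low-rank model assumes independent runs — merge offline fractions
  first.
* Group-specific MNAR detection requires the group to be *entirely*
  missing; a group with a single surviving observation is classified
  random.
* The down-shift calibration (1.8/0.3) is a convention, not a fit to any
  particular instrument; inspect `mean_cv_table()` and
  `missingness_summary()` output before trusting defaults on unusual data.
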