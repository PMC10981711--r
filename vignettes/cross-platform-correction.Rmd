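---
title: "Per-gene regression transfer between RNA-seq platforms: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-gene regression transfer between RNA-seq platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procrustes)
```

## The problem

Clinical tumor specimens are usually preserved as FFPE blocks, whose
degraded RNA is sequenced with exome-capture (EC) protocols, while the
large public expression compendia (TCGA and similar) were produced with
poly-A selection from fresh-frozen tissue. The two library preparations
measure the same transcriptome through different lenses: per gene, the
EC readout is approximately an affine distortion of the poly-A readout,
plus platform noise, and for a substantial set of genes the capture
probes cover too little of the transcript for the EC signal to exist at
all. Joint analysis — and in particular projecting a *single* clinical
sample onto a reference poly-A cohort — requires removing this batch
effect gene by gene.

This package implements a per-gene regression transfer: models are
trained on a paired cohort (the same samples sequenced with both
protocols) and then applied to new EC profiles, one column at a time.
Because each prediction is a per-gene linear map of one sample's values,
the transform needs no cohort context at application time; that
column-wise independence is what makes single-sample projection work,
and it is asserted as a test invariant.

## Models

All modeling happens in `log2(TPM + 1)` space. With `y` the poly-A
expression of a gene and `x` the EC expression of predictor genes, the
model family is

$$ y = w_0 + w_1 x_1 + \dots + w_p x_p, $$

fit by elastic net, i.e. minimizing

$$ \frac{1}{2 n} \lVert X w - y \rVert_2^2
   + \alpha \rho \lVert w \rVert_1
   + \frac{\alpha (1 - \rho)}{2} \lVert w \rVert_2^2 $$

with an unpenalized intercept. Two model layouts are provided:

* **sProcrustes** (`fit_sprocrustes()`): one predictor, the gene itself
  on the EC side. `mode = "elasticnet_cv"` (default) selects
  `(alpha, rho)` by internal 3-fold cross-validation; `mode = "ols"` is
  the plain least-squares limit. Both are provided because the
  single-gene model is described both as a simple linear regression and
  as a cross-validated elastic net; on noiseless data they coincide.
* **mProcrustes** (`fit_mprocrustes()`): predictors are the gene itself
  plus its co-expression partners (below), with cross-validated
  penalties. Penalization is what keeps the `p >> n` regime (up to ~56
  partners against ~100 training pairs) well behaved.
* **Ridge / Lasso variants** (`fit_penalized_variant()`): the
  single-gene layout with an l2-only or l1-only penalty over a
  grid-search cross-validation, kept as benchmarking comparators.

Genes with zero source variance get an intercept-only model (predicting
the target mean) and are flagged; they are never silently imputed.
Predictions are clipped below at 0, since `log2(TPM + 1)` is
non-negative (`clip = FALSE` disables this).

### Co-expression partner selection

`build_coexpression_map()` nominates, for every gene, the `k_cohort = 5`
most correlated genes (Pearson, on `log2(TPM+1)`) from each cohort with
at least `min_samples = 50` samples, requiring `r >= r_min = 0.7` of
every nominee, plus the `k_reference = 10` most correlated genes from a
reference cohort; the nominations are merged into one deduplicated list
per gene. The correlation floor applies to every nominee individually
(the stricter of the two readings of "the five most correlated genes
with correlation at least 0.7"). Genes with no partner anywhere are
absent from the map and fall back to the single-gene model downstream.
Partner lists carry no hard cap by default; the observed maximum on real
cohorts (~56) is an empirical outcome, not a rule. Lists are stored
sorted so the map is invariant to cohort input order. Spearman
correlation is available as an option; Pearson is the default because
partner selection is defined in the same space as model fitting.

### Baseline correctors

Three per-gene baselines are implemented exactly as their printed
formulas, for benchmarking:

* **Z-score** (`zscore_transform()`):
  `out = ((x - mu_src) / sd_src) * sd_tgt + mu_tgt`, with per-gene
  moments taken from training data on each platform. Standard deviations
  use the population (1/n) convention; a gene with zero source SD is
  passed through as the target mean with a warning.
* **BMC** (`bmc_transform()`): `out = x - mu_src + mu_tgt`.
* **Coefficient scaling** (`dasc_transform()`): `out = x * m / d` from an
  externally supplied per-gene coefficient pair, then values below zero
  are set to zero and values above mean + 3 SD are clipped to
  mean + 3 SD. The clipping statistics are computed per gene over the
  scaled values of the matrix being transformed (the source of those
  statistics is ambiguous in the method's description; computing them on
  the matrix at hand is the self-contained choice, and it is documented
  rather than configurable). Estimating the coefficients themselves is
  out of scope; they are an input.

No clipping is applied to the z-score and BMC outputs: those transforms
are the plain formulas, and the exact mean identity of BMC (per-gene
mean of the transformed training source equals the target training
mean) is kept as a numerical test.

### A structural fact about CCC and per-gene linear maps

Among per-gene *linear* transforms `c*x + d`, Lin's concordance
correlation coefficient is maximized at `c = sd(y)/sd(x)` with means
matched — i.e. the z-score transform is the CCC-optimal member of that
family, for any joint distribution. A single-gene regression (which is
MSE-optimal, hence attenuated by the correlation) can therefore approach
but never strictly beat a well-estimated z-score on within-gene CCC; its
deficit is bounded by `r (1 - r)^2 / (1 + r^2)`, which is below 0.005
for `r > 0.9`. The multi-gene model is not a per-gene linear map and
does beat both baselines on simulated data whenever partner genes carry
independent information (heavy EC platform noise, probe dropout,
distortion that mixes co-expressed genes). This bound is verified as a
property test, and the benchmarking test asserts the ordering
accordingly: multi-gene above everything, single-gene above the
moment-baseline family, baselines above uncorrected data.

## Gene filtering

The gene universe is built in three steps. First, biotype exclusion:
non-coding biotypes, histone genes (user list or the
`HIST*/H1-/H2A*/H2B*/H3-/H4-` symbol patterns), and genes on the
mitochondrial contig (`chrM`/`MT`) are dropped. Unknown biotype strings
pass through with a warning, since annotation releases keep inventing
them. Second, the probe effective-length fraction: per transcript, exons
are merged (so no base is double-counted within a transcript) and
intersected with the merged capture-probe intervals; effective and
actual transcript lengths are summed within each gene and divided.
Transcripts are summed without cross-transcript merging — a deliberate
reading of "sums within each gene". Genes with a fraction strictly below
0.5 are *problematic* (a fraction of exactly 0.5 is not). Third, an
optional low-expression filter (default: exclude genes above 1 TPM in
fewer than 10% of samples — the cutoff is not prescribed anywhere, so it
is conservative and configurable).

Coordinates: GTF input is 1-based closed, BED input 0-based half-open;
both are normalized by `rtracklayer` into `GRanges`, so interval
arithmetic needs no manual convention juggling. Strand is ignored
throughout, since capture coverage is positional. The interval logic is
cross-checked against a brute-force per-base oracle in the tests.

The four named groups are `AG` (all genes), `AGEP` (all minus
problematic), `BMG` (a curated "biologically meaningful" list,
restricted to `AG`), and `BMGEP` (`BMG` minus problematic). Whether TPM
renormalization should be recomputed after excluding problematic genes
is left open by the method's description; `tpm_renormalize()` takes the
gene universe as an argument so both orders are expressible.

## Evaluation

`lins_ccc()` implements Lin's estimator with population (1/n) moments
(sample moments behind a flag). Degenerate cases: two identical
constants have CCC 1; a constant against a non-constant vector has CCC
0. `paired_ccc()` evaluates a paired cohort per gene (across paired
samples) or per sample pair (across genes) and bins the CCCs as low
(< 0.5), medium ([0.5, 0.8], closed on both ends — the published labels
are ambiguous at the boundaries, so the convention is fixed and the
edges are configurable), and high (> 0.8).

`paired_difference_test()` is the two-sided Wilcoxon signed-rank test on
per-unit metrics before and after transformation: for up to 25 non-zero
differences the exact null is enumerated (dynamic programming over
doubled midranks, so ties are handled); beyond that the normal
approximation with continuity correction is used.

`anova_power_sample_size()` inverts the exact noncentral-F power of a
one-way ANOVA by integer bisection. Two noncentrality conventions
circulate in power software: `lambda = f^2 (n - k)` (proportional to the
residual sample size) and the textbook `lambda = f^2 n`. The default is
the former, which reproduces the reference post hoc result (n = 108 for
f = 0.56, alpha = 1e-4, power = 0.95, k = 2); the latter (which yields
106 for the same inputs) is available via `ncp = "total"`. The solver's
minimality contract — `power(n) >= target`, `power(n - 1) < target` — is
tested against a linear-scan oracle.

## Cohort projection

`fit_reference_space()` centers the reference cohort per gene (no
variance scaling by default; a flag enables it) and computes a truncated
SVD basis, either exactly or by a randomized range finder with subspace
iterations and a recorded seed. Per-cohort class-mean centroids live in
the retained component space. New samples are projected into the frozen
space — never refit — and assigned to the nearest centroid by Euclidean
distance, ties broken lexicographically with a warning. At reference
scale the published analysis retains 4,000 components; the package
default is whatever the caller asks for, and the test suite uses at most
20, which is plenty at simulation scale.

## The simulator

`simulate_paired_cohort()` generates a paired EC/poly-A cohort with
known ground truth:

* **Target (poly-A-like)**: per gene, baseline + loading x latent factor
  score + Gaussian biological noise, rectified at 0. Factor scores carry
  cohort structure: cohort centers are random directions in factor space
  rescaled so the *minimum* pairwise distance equals
  `cohort_separation` (in units of the within-cohort factor SD).
* **Source (EC-like)**: per gene, `intercept + slope * signal +` platform
  noise, rectified at 0, with `slope ~ LogNormal(meanlog, sdlog)` and
  `intercept ~ Normal`. `distortion_mixing` replaces a fraction of
  `signal` by the average of the gene's factor mates, emulating capture
  distortion that is not purely gene-autonomous. Problematic genes lose
  the source signal entirely (replaced by rectified low-level noise) —
  signal loss, not added noise, matching the probe-coverage-gap
  mechanism. `zero_inflation` adds per-entry dropout on the source side.

Defaults are the package's reference study conditions: 2,000 genes x 100
pairs, 3 cohorts at 5-sigma separation, 10 factors with loadings in
[0.8, 1.2], baselines in [3, 9] log2 units, slopes LogNormal(0, 0.3),
intercepts N(0, 0.5^2), biological noise SD 0.5, source platform noise
SD 0.2, and no dropout. Under these conditions the uncorrected
within-gene concordance is mediocre (median CCC ~0.7) and the
single-gene model restores it above 0.95 while recovering the true
inverse-distortion slopes to a median absolute error well under 0.05.
One master seed drives independent sub-streams for structure, cohorts,
target noise, distortion, and source noise, so varying one component
does not perturb the others, and equal seeds give bitwise-identical
cohorts.

What the simulator deliberately does **not** model: read-level
sampling, count overdispersion (negative binomial realism),
gene-length/GC bias, fragment-level coverage profiles, or correlated
sample quality. Consequently, passing tests demonstrate that the
estimators recover the generative model they assume and that the method
ordering holds under Gaussian latent-factor structure — not that any
particular real cohort will reach the same numbers.

## Numerical choices

* `elastic_net_fit()` routes through `glmnet` for two or more
  predictors. glmnet standardizes the response internally, which rescales
  the l1 part of the penalty by `sd(y)` but not the l2 part; the wrapper
  standardizes `y` explicitly and remaps `(alpha, rho)` so the stated
  objective is solved exactly (verified to machine precision against an
  independent coordinate-descent oracle in the tests). Single-predictor
  fits use the exact closed-form soft-threshold solution; `alpha = 0` is
  ordinary least squares.
* Cross-validation grids: the per-gene penalty path is data-driven (20
  log-spaced values over four decades from the per-gene maximum); the
  l1-ratio grid defaults to {0.1, 0.5, 0.7, 0.9, 0.95, 0.99, 1.0}; the
  ridge/lasso strength grid to 13 log-spaced values in [1e-3, 1e3]. All
  grids are arguments. The test suite and the benchmarking analysis use
  a reduced l1-ratio grid {0.5, 1} and 120-300 genes per run to keep
  runtimes in seconds-to-minutes; these sizes are stated here as the
  package's validation scale.
* Fold assignments derive from a recorded seed, shared across genes, so
  model sets are exactly reproducible.
* Serialized models, projection spaces, and coefficient tables are plain
  TSV/JSON with 17 significant digits, so a reloaded model produces
  bit-identical predictions — also a test.
* Stratified splits use the largest-remainder method per cohort, so the
  global holdout fraction is respected to the rounding limit; singleton
  cohorts stay in training.
* "Scaled from 0 to 1" for tissue-specific calling is read as per-gene
  min-max scaling within each source group — the only scaling that
  guarantees the [0, 1] range the 0.5/0.2 thresholds presuppose.
  Tissue-specific means median >= 0.5 (inclusive) in every selected
  cohort and < 0.2 (strict) in every other cohort; the sample-size gate
  (canonically >50 tumor / >20 normal samples) is applied when the
  cohort set is assembled, with an optional `min_samples` filter in the
  calling function itself.

## Known limitations

* Models are linear per gene; genes whose cross-platform relationship is
  driven by values at or near the detection floor (heavy dropout) are
  fit poorly by the single-gene model — on simulated data, per-entry
  dropout degrades single-gene regression faster than it degrades the
  moment baselines, while the multi-gene model is robust because
  partners carry the signal. This mirrors the practical advice to
  exclude problematic genes from the modeled universe.
* Genes that are unexpressed on the target platform everywhere cannot be
  recovered by any correction method; the simulator represents these as
  problematic genes, and the recovery report marks them unrecoverable
  rather than scoring them.
* The power solver's default noncentrality convention was chosen to
  reproduce the published post hoc result; users comparing against
  textbook tables should pass `ncp = "total"`.
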