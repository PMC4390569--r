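---
title: "Quantifying heritable variation in courtship patterns from scan-sampled ethograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying heritable variation in courtship patterns from scan-sampled ethograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoscan)
library(dplyr)
```

## The measurement model

Male *Drosophila melanogaster* courtship proceeds through a stereotyped
sequence: orienting toward the female, pursuit, wing vibration (courtship
song), genital licking, attempted copulation, copulation. `ethoscan`
analyzes scan-sampled records of this progression: each male is observed
every 30 s for 15 min (30 scans) and assigned an ordinal score 1–8, where
1 is "not moving" and 8 is "copulating". Two summaries are derived per
male:

* the **MMP score** (male mating progression), the sum of the 30 ordinal
  scores, ranging 30–240; and
* a **condensed category sequence** over five states, A–E, obtained by the
  fixed mapping {1,2}→A (no engagement), {3,4}→B (orienting/pursuit),
  {5}→C (wing vibration), {6}→D (licking), {7,8}→E (attempted or actual
  copulation). The paired scores are merged because a 30-s scan cannot
  reliably distinguish them.

A male never scoring above 2 is a **noninitiator**: he may move but never
engages the female.

Scan sampling censors bouts shorter than the 30-s scan interval, so
transition counts are a lower bound on the true number of behavioral
changes. No imputation is attempted; the estimand is the scan-resolution
transition structure.

## Transition phenotypes

From each male's condensed sequence we tally the 5×5 matrix of
first-order transitions between successive scans (self-transitions
included; a 30-scan male contributes 29 transitions) and normalize by the
**total** transition count, so all 25 cells sum to 1. This whole-matrix
(joint) normalization — rather than row-conditioning — is deliberate: each
cell is then the proportion of a male's scan-to-scan transitions that
were x→y, a well-defined per-male phenotype even for rarely visited
states, and the 25 cells are jointly compositional. A row-stochastic view
is available via `joint_to_conditional()` for simulation and inspection,
but the analyzed phenotypes are always the joint probabilities. Cells
never visited get probability 0; no pseudocounts are added, since
panel-mean cell values of order 0.002 would be swamped by any prior mass.

Line-level summaries are unweighted means of the per-male matrices
(`line_mean_transitions()`), optionally after block adjustment; because
each male's matrix sums to 1, line means do too.

## Variance decomposition and broad-sense heritability

Traits are decomposed sequentially: block enters first as a fixed effect
(one-way ANOVA; `%B = 100·SS_block/SS_total`), and line then enters as a
random effect on the block residuals. This two-step residualization —
rather than a joint mixed model — matches the two-column reporting
convention (%B separate from H²) and keeps every quantity a closed-form
mean-square ratio.

Heritability uses method-of-moments variance components from the one-way
random-effects ANOVA with the unbalanced coefficient
n₀ = (N − Σnᵢ²/N)/(a−1):

σ̂²_L = (MS_line − MS_error)/n₀,  H² = σ̂²_L/(σ̂²_L + σ̂²_error).

Estimates are **not truncated at zero**. Under weak line effects MS_line
can fall below MS_error and Ĥ² goes negative; reporting the negative
value preserves the estimator's unbiasedness across traits and makes
sampling noise visible. This is also why REML (which constrains variance
components to be nonnegative) is not used. The line F test and its P
value accompany every estimate, and Bonferroni families are always
explicit — the package never infers a test count: for the 25 transition
phenotypes at α = 0.05 the critical value is 0.05/25 = 0.002, and a
genome scan over ~2.4 million variants uses 0.05/2.4×10⁶ ≈ 2.08×10⁻⁸.

An arcsine-square-root switch is provided for the proportion-scale traits;
raw and transformed analyses are both supported and neither is privileged.

## Noninitiator mixture comparison

The per-line proportion of noninitiating males is fitted with two
candidate distributions and compared by AIC (= 2k − 2 logL):

* an exponential (k = 1), the natural "single decaying tail" null; and
* a two-component Normal mixture (k = 5) fitted by EM, representing two
  line classes — most lines with essentially zero noninitiators, some
  with a modest rate.

EM details that matter on these data: proportions pile up at exactly
zero, so the lower component tends to a point mass. Component variances
are floored (default 1e−6) to keep the likelihood bounded; the floor is a
numerical device, not a model claim. Initialization is a deterministic
quantile split (lower/upper half), so the default fit is seed-free;
k-means initialization is available and takes a seed. Components are
always reported with µ1 ≤ µ2, making labels stable. The log-likelihood
trace is retained and checked non-decreasing every iteration. Both
candidate densities have support outside [0,1]; they are fitted as-is to
match the intended model menu, and truncated alternatives are noted as an
extension rather than implemented.

## Factor analysis of transition structure

Line-mean matrices (25 phenotypes per line) are analyzed by principal
components on the **correlation** matrix — the phenotypes differ in scale
by two orders of magnitude, so covariance PCA would be dominated by the
E→E and A→A cells. Components with eigenvalue > 1 are retained (Kaiser
criterion), loadings are formed as eigenvector × √eigenvalue
(principal-component factoring), and the retained loadings are
varimax-rotated.

The rotation is implemented as cyclic pairwise planar rotations with the
closed-form quartic angle, applied with Kaiser row-normalization
(toggleable). The varimax criterion is verified non-decreasing after
every sweep, communalities are conserved under rotation (checked to
1e−8), and two conventions make output reproducible: each factor's
largest-magnitude loading is made positive, and factors are ordered by
explained variance. Factor scores use the regression (Thurstone) method,
`Z R⁻¹ L`; when fewer lines than variables make R singular, the
Moore–Penrose pseudoinverse is substituted.

## Line-means association scan

The most heritable transition phenotype (by default E→A, copulation to
no engagement) is regressed on each variant's dosage across lines by OLS,
with optional user-supplied per-line covariates (inversion karyotypes,
Wolbachia status, relatedness axes — any numeric columns). Inbred
homozygotes are coded 0/2; residual heterozygous calls are missing by
default (dosage 1 optionally). Internally phenotype and genotypes are
residualized on the covariates once (Frisch–Waugh–Lovell), making the
scan a single vectorized pass that is exactly equal to per-variant
multiple regression (verified against `lm()` to 1e−10 in the tests).
Variants are pre-filtered on minor-genotype line count (default ≥ 4
lines; the threshold is configurable and 0 disables it). Diagnostics
include uniform-reference QQ coordinates and a two-tier hit table
(strict Bonferroni plus a suggestive tier, default P ≤ 10⁻⁵). Mixed-model
relatedness correction is out of scope by design: line-level covariate
regression preserves the scan's structure and the covariates slot accepts
externally computed axes.

## The synthetic-study generator

`simulate_panel()` produces a complete study with known ground truth so
every stage has a recovery test. Defaults encode the emulated design:
166 lines, 10–15 males per line, 5 blocks (each line assayed in one
block, as in the original randomization), 30 scans per male.

* **Between-line variation** enters on the conditional (row-stochastic)
  matrices: each line's rows are Dirichlet draws centered on the base
  rows with common concentration. The analyzed phenotypes are joint
  probabilities, so the dispersion→heritability mapping is not analytic;
  it was calibrated numerically, once. Concentration 22 yields realized
  H² ≈ 0.095 for the E→E phenotype (and ≈ 0.095 for the MMP score) at
  the default design, matching the magnitude of the strongest published
  transition heritabilities.
* **Block effects** mix a per-block Dirichlet tilt matrix into every
  male's rows with weight 0.35 (tilt concentration 80). With only five
  blocks the realized block share of variance is itself highly variable
  across realizations (roughly 0.5–3% for the MMP score), consistent
  with the wide published per-trait range (0.24–5.85%).
* **Noninitiators** follow a two-group structure: 20% of lines have
  within-line noninitiator probability 0.122, the rest 0.
* **Genotypes** are biallelic with allele frequencies uniform on
  [0.05, 0.5] and no linkage disequilibrium. One causal variant moves
  0.05 of conditional probability from E→E to E→A in carrier lines.
* **Copulation durations** are drawn per line with a target correlation
  of −0.35 between line duration means and the line's *true* conditional
  E→A rate, then per-pair noise is added (10 pairs/line, mean 20 min).
  The pipeline's estimated correlation against measured E→A line means
  is attenuated by measurement noise (about −0.15 to −0.2 at the default
  design); tests therefore assert the sign and the true-scale coupling,
  not the attenuated magnitude.
* The chain starts in state A (the pair begins separated by a divider);
  the scan tie rule is emulated by recording the more copulation-like
  ordinal of a category when the chain has just advanced (toggleable).
* The first scan is indexed t = 0; the assay window is [0, 15) min. The
  alternative (first scan at 30 s) also yields 30 scans and is
  observationally equivalent here.

What the generator does **not** emulate: dwell times shorter than the
scan interval (the chain is defined at scan resolution), female behavior
and feedback, linkage disequilibrium, and genuine relatedness structure.
Passing recovery tests therefore demonstrate estimator correctness at
scan resolution under the stated design, not robustness to those
real-data features.

## Numerical choices and degenerate inputs

* Transition counting requires ≥ 2 observations; zero-transition
  normalization is an error, not a silent NaN.
* A constant trait has H² defined as 0; lines that are all singletons are
  an error (no within-line degrees of freedom).
* All-zero proportion data make the exponential rate undefined and raise
  an error pointing at the zero-inflation option.
* Zero rows in joint→conditional conversion become self-loops by default
  (a never-visited state has no observed exits) or an error on request.
* P values of exactly 0 in QQ coordinates are clamped to the machine
  floor with a warning.
* Constant phenotype columns are dropped (with a warning) before PCA.

## Problem sizes used in the test suite

Unit tests run at reduced scale (panels of ~24 lines × 8–10 males);
estimator-recovery checks use the full 166 × 12 design with 500 replicate
traits for the heritability calibration, 200 simulated panels for the
mixture comparison, a 10,000-variant null scan, and 100 seeds for
causal-variant power — sizes chosen so the whole suite completes in a few
minutes while keeping Monte-Carlo error well inside the asserted
tolerances.

## Worked example

```{r example, eval = FALSE}
panel <- simulate_panel(panel_spec(), seed = 1)
run <- run_pipeline(
  panel$observations,
  durations  = panel$durations,
  genotypes  = panel$genotypes,
  covariates = panel$covariates
)
run$mmp_decomposition
run$transition_decomposition |> arrange(desc(h2_pct)) |> head()
run$mixture_comparison
plot_noninitiator_fit(run$noninit_proportions, run$mixture_fits)
plot_qq(run$assoc)
```

## Known limitations

* Sequential (block-then-line) residualization slightly redistributes
  variance relative to a joint mixed model when block and line are
  partially confounded, as they are when each line sits in one block.
  The chosen decomposition is the reporting convention this package
  reproduces; a REML alternative would change numbers at the margin and
  cannot produce the (informative) negative estimates.
* AIC values for the mixture comparison use continuous densities; data
  concentrated on a narrow range can produce positive log-likelihoods
  and hence negative AICs. Only AIC *differences* on the same data are
  meaningful, and `compare_fits()` refuses cross-data comparisons.
* The scan is OLS per variant; population structure beyond what the
  supplied covariates capture will inflate the QQ tail.
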