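---
title: "Methods: Fourier regression of telomere length on season of conception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Fourier regression of telomere length on season of conception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasontl)
```

## The scientific question and the measurement chain

Leukocyte telomere length (LTL) in children may carry a signature of the
periconceptional environment. In a strongly seasonal setting, date of
conception is a natural exposure proxy: it indexes parental nutrition,
energy balance and infection pressure around conception. `seasontl`
implements the whole chain from raw quantitative-PCR plate readings to a
seasonal inference, because each link shapes what the final test can
see:

1. **MMqPCR quantification.** Relative telomere length is the T/S
   ratio: the telomere amplicon quantity divided by a single-copy gene
   quantity, each interpolated from a per-plate standard curve (OLS of
   Cq on log10 relative concentration over a dilution series). Curves
   are fitted per plate and per target, never pooled across plates,
   because run-to-run efficiency differences are exactly what the
   standards are there to absorb.
2. **Quality control.** Per-replicate T/S ratios are averaged within a
   sample; the duplicate coefficient of variation (sample sd / mean over
   replicate ratios) must not exceed 15% — strictly: a CV of exactly
   0.15 is kept. Samples with no complete replicate (a missing Cq on
   either target in every replicate) are amplification failures; a
   single complete replicate leaves the CV undefined and the sample is
   likewise excluded rather than passed unchecked.
3. **Plate normalization.** Raw T/S ratios carry batch effects in both
   level and scale. Within-plate z-scoring removes any plate-wise affine
   distortion exactly (a property the tests verify), at the cost of
   absorbing any true between-plate biology — acceptable when samples
   are assigned to plates without regard to exposure.
4. **Seasonal model.** With θ the conception date's angular position in
   the year, LTL z-scores are modelled as a linear combination of
   sin(jθ), cos(jθ) pairs plus covariates. A pair of Fourier terms
   captures a sinusoid of free phase and amplitude without assuming
   where the peak lies; additional pairs add sharper features. The
   seasonal effect is judged by a likelihood ratio test (LRT) against
   the same model without the Fourier columns, fitted on identical
   rows; one pair gives 2 df.

## Model and likelihood conventions

`fit_gaussian_lm()` uses QR least squares; the log-likelihood is the
Gaussian maximum-likelihood value with σ² = RSS/n, so the LRT statistic
is 2·Δlog-likelihood = n·log(RSS_reduced/RSS_full), referred to χ² with
df equal to the parameter difference. An F-test on the same nested pair
is asymptotically equivalent; the LRT is the default because the model
comparison is explicitly likelihood-based. Coefficient covariances use
the unbiased σ̂² = RSS/(n−p), and per-predictor p-values are two-sided t
tests. Complete-case analysis is applied per model, so n legitimately
varies across the adjustment models; the LRT machinery refuses to
compare fits with different n.

The amplitude is defined as the maximum minus the minimum of the fitted
mean curve evaluated on a 366-point daily grid with covariates at
reference values (means for continuous covariates, reference level for
indicator columns). This definition extends to any number of harmonics;
for k = 1 it equals 2√(a²+b²) and the peak angle is atan2(a, b), used
as closed-form cross-checks. The grid discretization error is bounded by
2√(a²+b²)·(1−cos(π/366)) ≈ 3.7×10⁻⁵ relative — negligible against
sampling error, and the tolerance the tests use.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `cv_threshold` | 0.15 | fraction | the standard 15% duplicate rule |
| `k` (Fourier pairs) | 1 | – | selected by sequential 2-df LRTs (`select_harmonics`, α = 0.05, forward) |
| date convention | calendar | – | θ = 2π(doy−1)/D with D the actual year length (365/366); a fixed-365.25 variant is available, and the two never differ by more than the leap-day offset |
| Box-Cox shift | min → +0.01 | z units | the power family needs positive input; z-scores are shifted so the minimum maps to +0.01, with the shift stored |
| Box-Cox λ grid | −2..2 step 0.001 | – | deterministic profile-likelihood maximization |
| bootstrap `B` | 1000 | – | percentile intervals; 400 is used in the long-running calibration loops, well above the floor where percentile intervals stabilize |

## The synthetic-data generator

Cohort data of this kind are typically controlled-access, so the
generator is a first-class module: it defines the conditions under which
the pipeline's statistical behaviour is demonstrated.

The outcome model is y = (A/2)·cos(θ − θ_peak) + Σβ·x + ε with defaults
A = 0.6 z-scores (so max − min = 0.6), peak day 244 (1 September),
ε ~ N(0, 1), n = 218 — a mid-childhood cohort scale. Conception dates
are uniform over two years (the true conception-rate seasonality of the
population is not modelled; a non-uniform date distribution would change
power but not calibration). Two collection designs reproduce the
structural contrast that matters for confounding: `window_locked` draws
collection dates in a fixed February–May window, making conception and
collection dates essentially uncorrelated, while `age_locked` sets
collection = conception + 280 days gestation + 2 years, making them
correlate near 1 so a conception-season effect cannot be separated from
a collection-season effect. Covariate marginals are realistic for the
setting (55% male; birthweight 3069 ± 417 g; maternal BMI lognormal,
median 20.8; folate lognormal, median 13 nmol/L; two- or four-arm
supplementation factors), with mild sinusoidal seasonality in
birthweight (±50 g) and maternal BMI (±2%) so that "seasonal covariate"
adjustment does something; covariate effects on the outcome default to
zero. Missingness is completely at random, by default 8% in birthweight
and 2% in cell fractions, mirroring how adjusted-model Ns shrink in
practice.

Plates hold 32 samples plus a five-point two-fold dilution series per
target, a duplicated reference (T/S 1) and three duplicated controls
(T/S 1.90, 1.54, 1.09 — young, adult, elderly donors). True T/S maps to
z via ts = 1.1 + 0.28·z (floored at 0.05), matching a mid-childhood T/S
distribution; plate batch effects are an additive shift (sd 0.15) and a
multiplicative scale (log-sd 0.05), large enough that the raw-scale
batch ANOVA is routinely significant. Duplicate noise is lognormal on
the replicate ratio with log-sd √log(1+cv²), so the expected duplicate
CV equals the configured 5%. Deliberate QC failures are injected
deterministically: flagged samples get duplicates at ratio·exp(±δ) with
δ = atanh(0.25/√2), whose duplicate CV is exactly 0.25 whatever the
random stream does — this makes "injected failures are excluded
exactly" a sharp property rather than a probabilistic one (exact when
the baseline duplicate CV is 0; with a 5% baseline a normal sample
exceeds the 15% rule only ~0.3% of the time).

What the generator does **not** emulate: non-uniform conception rates,
infection histories, breastfeeding, attrition-by-age, real methylation
array structure, instrument-level fluorescence artefacts, or any
mechanism linking covariates to the seasonal effect (no confounding of
the exposure by default). Passing tests therefore demonstrate that the
estimator and its calibration are correct *under the stated sampling
model*, not that any particular real cohort satisfies that model.

## Cell-composition estimation

The adjustment for white-cell composition uses reference-based
deconvolution: given a reference matrix R (markers × cell types,
values in [0, 1], full column rank) and a sample profile p, solve
min ‖p − Rw‖² subject to w ≥ 0, Σw = 1. The solver is an active-set
quadratic minimizer: it solves the equality-constrained KKT system on
the free set, walks back along the feasible segment when a weight would
cross zero (constraining the blocker), and frees the active weight with
the most negative Lagrange multiplier until all multipliers are
nonnegative (tolerance 1e−10, iteration cap 10⁴). The sum-to-one
equality (rather than ≤ 1) keeps the output an interpretable
composition; downstream, one fraction is dropped from the design to
avoid simplex collinearity. The module operates on synthetic reference
matrices with six leukocyte types by default; it does not implement
array preprocessing or published reference panels.

## Numerical and degenerate-case choices

- Rank deficiency raises an error naming the collinear columns rather
  than silently dropping them.
- An exactly-fitting model (RSS numerically 0) has an unbounded Gaussian
  likelihood; the fit is flagged `degenerate` and its coefficients
  remain valid, so noiseless fixtures can still be summarized.
- `select_harmonics` never returns k = 0: the significance of
  seasonality itself is a separate comparison against the baseline.
- Bootstrap peak-date intervals are formed on angular deviations
  recentred on the estimate, avoiding wrap-around artefacts at the
  year boundary; amplitude intervals are plain percentile intervals.
- Categorical covariates are reference-coded against the alphabetically
  first level.
- Ties on the daily grid (flat stretches) resolve to the first index,
  i.e. the earliest day.
- The T/S dialect is per-replicate ratios then mean (the duplicate CV
  rule is defined on replicate-level ratios); a ratio-of-means dialect
  is available via `method = "ratio_of_means"`. Box-Cox is applied to
  the z-scores (shifted), not before z-scoring; both orders are
  defensible and the transform parameters are always recorded.

## Problem sizes and calibration results

The package's statistical guarantees are demonstrated by computation in
the test suite and `scripts/acceptance.R`, at these scales: type-I
calibration of the 2-df LRT over 1000 null cohorts of n = 218;
amplitude/peak recovery and bootstrap coverage over 200 cohorts with
A = 0.6 and B = 400 bootstrap replicates; oracle-equivalence checks on
seeded fixtures (OLS and ANOVA to 1e−9, Box-Cox λ within 0.05 of an
independent grid search, deconvolution against a 0.001-resolution
simplex grid in three dimensions). The acceptance script writes the
measured rates — rejection rate, Kolmogorov–Smirnov distance of null
p-values from uniformity, mean amplitude, median peak error, interval
coverage, design-contrast correlations — to JSON; no result is quoted
here that the scripts do not themselves compute.

## Limitations

Per-plate z-scoring discards absolute T/S scale, so effects are in
z-score units, not base pairs. The LRT relies on Gaussian residuals;
the Box-Cox option mitigates skew but the package does not model heavy
tails. Complete-case analysis assumes missingness unrelated to outcome.
The `age_locked` design's confounding of conception and collection
season is structural: no adjustment within this package can separate
the two, and the design-contrast check exists precisely to display
that limitation.
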