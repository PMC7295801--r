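# seasontl

Does the season in which a child was conceived predict their leukocyte
telomere length (LTL) years later? In strongly seasonal environments —
the motivating setting is rural West Africa, with a July–September rainy
("hungry") season and a long dry season — parental diet, energy balance
and infection pressure at conception differ sharply by calendar date, and
season of conception has been linked to offspring epigenetic marks and
survival. `seasontl` implements the full analysis chain needed to test a
season-of-conception effect on LTL measured by monochrome multiplex qPCR
(MMqPCR), for epidemiologists working with cohort phenotype tables and
raw qPCR plate exports.

## What it computes

**T/S ratios.** Each plate carries a dilution series of a reference DNA;
for each amplicon (telomere `T`, single-copy gene `S`) an OLS standard
curve Cq = β₀ + β₁·log₁₀(dilution) is fitted, and a well's relative
quantity is 10^((Cq−β₀)/β₁). A sample's relative telomere length is the
T/S ratio, averaged over duplicate wells; duplicates with a coefficient
of variation above 15% and samples that fail to amplify are excluded.

**Normalization.** Raw T/S ratios carry plate batch effects (diagnosed
with one-way ANOVA); they are converted to per-plate z-scores, optionally
followed by a Box-Cox transform with profile-likelihood λ. Skewed
predictors (maternal BMI, folate) are log-transformed.

**Seasonality.** Conception dates are mapped to angles θ = 2π(doy−1)/D
and LTL z-scores are regressed on Fourier (cosinor) terms

&nbsp;&nbsp;&nbsp;&nbsp;y = β₀ + Σⱼ [ aⱼ sin(jθ) + bⱼ cos(jθ) ] + γᵀx + ε

with covariates x (age, sex, estimated white-cell composition, maternal
BMI, birthweight, supplementation arm). Each model is compared with its
Fourier-free baseline on identical complete cases by a likelihood ratio
test (2 df per pair); the number of pairs is chosen by sequential LRTs.
The seasonal effect size is the amplitude — maximum minus minimum of the
fitted daily curve — with its peak/nadir dates; for k = 1 this equals
2√(a₁²+b₁²), used as a closed-form cross-check. Case-resampling
bootstrap gives percentile intervals for amplitude and peak date.

**Cell composition.** A Houseman-style constrained projection estimates
leukocyte fractions from methylation-like marker profiles: min ‖p − Rw‖²
subject to w ≥ 0, Σw = 1, solved by an active-set quadratic minimizer.

**Synthetic cohorts.** Because the motivating cohort data are not
public, `generate_cohort()`/`generate_plates()` produce cohorts and raw
plate tables with known ground truth: a cosine seasonal effect with
configurable amplitude and peak day, two collection designs
(`window_locked`, all samples drawn in a fixed Feb–May window, versus
`age_locked`, collection at a fixed age so collection date tracks
conception date), plate batch effects, duplicate noise, injected QC
failures, and seasonally varying covariates.

## Worked example

```r
library(seasontl)
cfg <- synthetic_config(n = 218, true_amplitude = 0.6, peak_day = 244, seed = 7)
run <- run_pipeline(pipeline_config(simulate = cfg, out_dir = NULL, seed = 7,
                                    bootstrap_B = 1000, make_plots = FALSE))
run$model_table
```

```
                   model   n chi2 df p_value amplitude peak_day
1           model1_crude 203 5.65  2  0.0592     0.471      274
2         model2_age_sex 203 4.80  2  0.0908     0.456      273
3           model3_cells 197 5.70  2  0.0578     0.494      271
4    model4_maternal_bmi 203 5.18  2  0.0750     0.473      268
5     model5_birthweight 183 6.26  2  0.0437     0.548      288
6 model6_supplementation 203 4.99  2  0.0825     0.463      271
```

```r
run$summaries$model1_crude
#> Seasonal curve: amplitude 0.471 z-scores (max - min)
#>   peak day 274 (~30 Sep), nadir day 91 (~31 Mar)
run$bootstrap$amplitude
#> bootstrap 95% CI for amplitude: 0.47 [0.18, 0.88]
```

The cohort was generated with a true amplitude of 0.6 z-scores peaking
on day 244 (1 September). After the full measurement chain (duplicate
qPCR wells, plate batch effects, QC exclusions: intra-assay CV 3.9%,
batch ANOVA p = 9×10⁻⁵ before z-scoring) the crude model recovers an
amplitude of 0.47 with a September peak and a March nadir; `n` varies
across models because each uses complete cases for its own covariates.
At n ≈ 200 with unit residual sd the amplitude estimate has a standard
error near 0.2, so individual replicates scatter widely around the
truth — the calibration battery below quantifies this.

A shell entry point with `simulate`, `qpcr`, `fit` and `run-all`
subcommands is installed at `system.file("scripts/seasontl", package =
"seasontl")`.

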