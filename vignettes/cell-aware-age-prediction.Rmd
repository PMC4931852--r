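---
title: "Cell composition-aware age prediction from buccal swabs: models, training and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell composition-aware age prediction from buccal swabs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swabage)
```

## The model

A buccal swab is a two-component cell mixture: buccal epithelial cells and
leukocytes. Both cell types acquire DNA methylation changes with age, but
with different baselines and different rates, so a clock trained on one
composition is miscalibrated on another. `swabage` treats this explicitly.

All quantities are β-values (fraction of methylated alleles, in [0,1]) at
five CpGs: three age-associated sites (α = cg02228185/*ASPA*,
β = cg25809905/*ITGA2B*, γ = a pyrosequenced CpG upstream of
cg17861230/*PDE4C*) and two cell-type-specific sites (δ = cg07380416/*CD6*,
ε = cg20837735/*SERPINB5*). Three model layers build on each other:

1. **Linear age clocks.** Affine maps from β-values to years, fitted by
   ordinary least squares of age on β (`fit_age_model()`), or — for the
   single-CpG convenience model — by regressing β on age and inverting the
   line (`fit_one_cpg_model()`), which is the algebraic form of the frozen
   `swab1` model `(γ − 0.0648)/0.0046`.

2. **Cell deconvolution.** The percentage of epithelial cells ϐ is estimated
   from the two marker CpGs. Each marker is independently calibrated by a
   simple regression of cytologically counted percent epithelial cells on
   its β-value (`calibrate_cell_signature()`), and the two calibration lines
   are averaged with equal weights. Two opposing markers (one unmethylated,
   one methylated in leukocytes) give an internal consistency check and
   halve the calibration noise relative to either line alone. The output is
   clamped into [0,100] — ϐ is a physical fraction — while the raw value is
   kept for diagnostics. Predicted ages are never clamped: a negative
   predicted age is a visible symptom of miscalibration and hiding it would
   be worse than reporting it (a warning is emitted).

3. **Mixture clock.** With weight w = ϐ/100, the 5-CpG prediction is
   `(1 − w)·blood(β) + w·epithelial(β)`. The epithelial clock is estimated
   by the two-stage plug-in procedure (`fit_epithelial_age_model()`): the
   blood clock and the signature are held fixed, the known leukocyte
   contribution `(1 − w)·blood(β)` is subtracted from age, and the residual
   is regressed on the scaled design `w·(1, α, β, γ)` with no free
   intercept. Holding the first-stage models fixed reproduces the published
   procedure and keeps the identifiability of the second stage transparent;
   no joint refitting and no regularization anywhere (the models are
   deliberately plain linear forms).

Frozen coefficients are stored at printed precision and never re-derived.
Where the source prints a constant at two precisions the more precise
printing is used (swab intercept 32.69; signature constants
99.8/1.92/−98.12/88.54) and the model's `notes` field records the
discrepancy.

## Marker selection

`screen_markers()` reproduces the screen that selected the two marker CpGs.
For every probe shared by two tissue data sets and an age reference it
computes (i) the absolute difference of mean β between the tissues, (ii) the
sum of the within-tissue variances (denominator n−1), and (iii) the Pearson
correlation with chronological age in the reference. Probes pass if
`|r| < age_corr_max` (default 0.05; an anti-correlation is equally
disqualifying — a marker must be composition-pure, not merely non-aging) and
if their variance sum lies in the lowest `var_sum_quantile` of all screened
probes (default the lowest decile). Survivors are ranked by mean difference,
ties broken by smaller variance sum, then probe ID, so the ranking is fully
deterministic and invariant to sample and probe order.

Two of these choices were genuinely open. The published screen gives no
explicit variance cutoff (the original triage was partly visual), so a
quantile rule was adopted as a deterministic surrogate. And the quantile is
computed over *all* screened probes rather than over the age-passing subset:
computing it over a shrinking subset would let a stricter age veto raise the
variance cutoff and admit new candidates, breaking the natural monotonicity
of the filter. Probes missing in more than 20 % of samples in either tissue
are dropped before any statistics.

## The synthetic cohort generator

The generator exists so that the estimators can be tested against known
truth. It emulates exactly the statistical structure the mixture model
assumes, under the published study conditions as defaults: 55 donors, ages
uniform on 1–85 years, epithelial fractions uniform on 24–91 %, additive
Gaussian measurement noise of 0.02 β-units (pyrosequencing-scale scatter)
clipped to [0,1], with a moment-matched Beta noise option behind a flag for
bounded realism. Seeds are mandatory; there is no wall-clock seeding, and
generation never disturbs the caller's RNG state.

Each cell type is a set of linear β(age) trajectories plus constant marker
baselines (`cell_type_spec()`). The defaults (`paperlike_cell_specs()`) are
*solved*, not tuned: the leukocyte γ curve is chosen so the frozen blood
clock is exact on pure leukocytes, the epithelial ITGA2B and PDE4C curves so
that the frozen epithelial clock is exact on pure epithelium *and* the cross
condition `blood(β_epi(a)) + epithelial(β_leuko(a)) = 2a` holds. That cross
condition is what makes the printed mixture model exact at every
intermediate composition, so at zero noise the full two-stage estimation
recovers the generating epithelial coefficients to machine precision — the
strongest possible correctness check for the estimator.

The remaining free curve parameters are fixed once at realistic values:
β mid-range over the age span, slopes of order 10⁻³ per year (the solved
leukocyte PDE4C slope, 0.0048/y, lands naturally next to the published swab
regression slope 0.0046/y), and leukocyte slopes steep enough that the
cross-tissue prediction divergence *grows* with age — the regime in which
composition adjustment matters most in older donors, which is the pattern
the stratified evaluation checks.

Marker CpGs need one extra care. The printed signature is an affine map that
does not pass through (0 %, 100 %): its largest attainable output on valid
β-values is 95.13 %. A generator in which the signature reads back the
latent fraction exactly therefore cannot place the marker β-values at the
physical mixing coordinate. By default (`marker_mixing =
"signature_consistent"`) marker β-values are set by inverting the frozen
signature at the sample's latent fraction — a linear interpolation between
the pure baselines at a slightly different coordinate — while the age CpGs
mix with weight ϐ/100, so the mixture identity holds exactly. For physically
pure tissues (fractions 0 or 100 %, outside the signature's representable
span) `marker_mixing = "proportional"` mixes every probe with ϐ/100; this is
what the marker-screen fixtures use.

Decoy probes (for screening experiments) are age-independent with means
shared between the two cell types and an inter-individual biological
standard deviation of 0.05 β-units on top of measurement noise. This is the
feature that makes the low-variance criterion meaningful: random CpGs vary
between donors, good cell-type markers are selected precisely for their
stability. The age reference used in the screen tests has 3000 samples,
chosen so that the sampling error of a null correlation (≈ 1/√n ≈ 0.018) sits
well below the 0.05 veto and the planted markers survive it reliably.

`generate_calibration_set()` mirrors the small cytology experiment: paired
β-profiles and counted percent epithelial cells for 11 samples spanning
37–88 % epithelium (leukocyte proportions 12–63 %), with optional counting
noise.

What the generator does *not* emulate: array-scale probe panels, batch and
laboratory effects, non-linear (logarithmic) age trajectories in childhood,
and cohort age structure (ages are uniform, not a donor-recruitment
histogram; a custom age list can be supplied). Passing tests on this
generator therefore demonstrate the correctness of the estimators under the
model's own assumptions, not the field performance of the assays.

## Evaluation statistics

`evaluate_predictions()` reports n, MAD, mean signed error and squared
Pearson correlation. MAD here is the field's usage — the *mean* absolute
deviation between predicted and chronological age in years — not the robust
median statistic; the function is named `mad_prediction()` to avoid the
collision with `stats::mad()`. R² is affine-invariant, so it cannot detect a
calibration offset; the blood-clock-on-swabs case (high R², decade-scale
overestimation) is the canonical example, and both numbers are always
reported together. Model comparisons use the classical paired two-sided
t-test on per-sample absolute errors; identical error vectors return t = 0,
p = 1 (no evidence of a difference), while constant non-zero differences are
a degenerate case and raise an error. Group comparisons default to the
classical equal-variance t-test with Welch behind a flag, since the original
analyses do not specify the variant. `stratify_mad()` splits at a
chronological-age cutpoint (30 or 35 years in the published analyses) and
reports per-stratum n and MAD, flagging empty strata rather than failing.

## Numerical and interface choices

* All fitting goes through a QR decomposition with an explicit rank check
  that names the aliased column; coefficients agree with the normal
  equations to ≤ 10⁻⁸ relative error (property-tested).
* Missing β-values are never imputed. Models return missing predictions with
  a per-sample reason; fitting functions exclude the affected samples and
  list them in the fit report. Forensic use demands no silent imputation.
* The canonical β scale is the fraction [0,1]. Percent-scale files (common
  pyrosequencing exports) are accepted only behind an explicit flag; values
  in (1,100] otherwise produce an error with a percent-scale hint.
* Near-zero mixture weights are retained in the epithelial estimation (they
  contribute ≈ 0 information); filtering them would introduce a threshold
  for no identifiability gain.
* The one-CpG fit declares the line non-invertible when |slope| < 10⁻¹²,
  the scale of pure floating-point residue for an exactly flat fit.
* Model files are flat key–value text with numbers at full double precision
  (round-trip exact). CLI outputs print ages and percentages at 4 decimals
  for byte-reproducible runs; `--raw` switches to full precision.
* The γ CpG is not on Illumina arrays; the registry stores
  `cg17861230_upstream` with the on-array neighbour `cg17861230` available
  behind `array_gamma = TRUE` for array data.

## Known limitations

**Identifiability of the epithelial coefficients under noise.** The
two-stage estimation inverts a mixture in which the same measured β-values
enter both the response (through the subtracted blood prediction) and the
scaled design. With 55 samples and 0.02 β-noise, the noise propagated
through the blood clock's coefficient vector (ℓ₂ norm ≈ 168 years per
β-unit) puts a floor of roughly a year on the standard error of the
epithelial intercept, and the shared errors bias all four coefficients
(errors-in-variables). Small coefficients — the intercept 2.6 and the α/β
slopes — are therefore not recoverable to tight relative tolerances at this
design size, even though the *predictions* of the fitted mixture remain
accurate (the ill-determined directions of the coefficient space are
precisely those that barely move the fit). The test suite documents this
honestly: exact recovery at zero noise passes at 10⁻⁶, while the ±15 %
per-coefficient recovery claim at 0.02 noise fails and is left failing. For
reliable coefficient-level inference one needs either purified cell
populations or a much larger n.

**Scope.** No IDAT/array preprocessing, no GEO download clients, no
multi-CpG array clocks, no confidence intervals for single predictions (the
linear models ship no error model), no ANOVA across more than two groups,
and no non-linear age modelling for children. The package estimates
chronological age under the published linear forms; biological-age
interpretation is outside its remit.
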