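---
title: "Methods: marker modelling and risk simulation for Down syndrome screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker modelling and risk simulation for Down syndrome screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmark)
```

## Scope and model

`screenmark` implements the statistical core of multi-marker antenatal
Down syndrome screening with placental growth factor (PlGF) as an
additional marker. The chain of models is:

1. **MoM normalization.** In unaffected pregnancies the median
   concentration of a serum marker changes rapidly with gestational age
   (for PlGF, about +31% per week in the late first trimester and +19%
   per week in the early second). Concentrations are therefore expressed
   as multiples of the median (MoM): the observed concentration divided
   by the regressed median for the same gestational age. The regression
   is of log10 category medians on category median age in days (2-day
   categories in the first trimester, weekly in the second), weighted by
   category counts; medians rather than means keep outliers from
   influencing the curve.
2. **Covariate adjustment.** MoM values are divided by the regressed
   value for the woman's weight (log-linear fit on 5 kg binned medians;
   PlGF falls by about 1.3%/5 kg in the first trimester and 3.1%/5 kg in
   the second), then by fixed divisors in smokers (1.32 first trimester,
   1.36 second) and Afro-Caribbean women (1.18 and 1.30). The factors are
   multiplicative, so their order is immaterial.
3. **Log-Gaussian distribution parameters.** Within each outcome group,
   log10 MoM vectors are modelled as multivariate Gaussian. Affected
   medians follow a log-linear gestational trend (for PlGF, regressed
   medians of 0.85, 0.72 and 0.61 MoM at 11, 12 and 13 completed weeks —
   a 15%/week fall — and 0.69, 0.77, 0.85 at 14–16 weeks, an 11%/week
   rise), each evaluated at the completed week + 3 days. SDs come from
   the probability plot (below), correlations from Pearson's r after a
   single 3.5-SD exclusion, and each marker is truncated to the MoM range
   over which the Gaussian model is acceptable.
4. **Risk.** Posterior odds = maternal-age prior odds × likelihood ratio
   of the truncated profile, where the prior is the age-specific
   livebirth odds divided by 0.77 (the survival fraction of affected
   pregnancies from mid-trimester to term) and the likelihood ratio is
   the quotient of the two multivariate Gaussian densities. A pregnancy
   is screen positive when the risk is **at or above** the cutoff — the
   boundary case counts as positive.
5. **Performance.** Detection rate (DR), false-positive rate (FPR) and
   the odds of being affected given a positive result (OAPR) are
   estimated from simulated cohorts of 250,000 affected and 250,000
   unaffected pregnancies.

## Estimators and numerical choices

**Probability-plot SD.** The SD of log10 MoM is the unweighted
least-squares slope of the order statistics against Gaussian quantiles,
restricted to points whose empirical centile lies in [10%, 90%]. We use
the plotting position (i − 0.5)/n; the choice among standard conventions
moves the estimate by well under 0.002 on samples of a few hundred, which
is negligible against sampling error. On a noise-free quantile grid the
estimator returns the generating SD exactly, and because it ignores the
tails it resists the occasional gross outlier that inflates the raw
sample SD (both properties are exercised in the test suite).

**Category medians.** For even-sized categories the median is the mean of
the central pair. Gestational-age categories are anchored at day 0
(2-day) and at whole weeks; weeks 19–22 are pooled into one category in
second-trimester affected-median work because affected pregnancies are
sparse beyond 18 weeks.

**Correlation exclusion.** A pair is excluded when either coordinate lies
more than 3.5 group-specific probability-plot SDs from its group mean;
the rule is applied once, not iterated.

**Confidence intervals.** Intervals for regressed medians use the
delta method on the log10 scale (±1.96 prediction SEs, exponentiated);
intervals for group multipliers (smoking, ethnicity) use a seeded
percentile bootstrap over records (2,000 resamples) and are flagged
unreliable when either group has fewer than 10 records.

**Truncation and risk reversal.** With unequal group SDs the univariate
density ratio is stationary at
x\* = (μ<sub>a</sub>σ<sub>u</sub>² − μ<sub>u</sub>σ<sub>a</sub>²)/(σ<sub>u</sub>² − σ<sub>a</sub>²).
Default PlGF limits are [0.4, 2.5] MoM. When x\* falls inside a marker's
limits — as it does for PlGF at 11 and at 14–16 weeks, where the
affected-to-unaffected median gap is small relative to the SD gap — the
limit on the reversal side is tightened to x\*, keeping risk monotone in
the marker. At 12–13 weeks the reversal sits far outside (≈ 11.7 MoM at
13 weeks) and the fixed limits govern.

**Likelihood ratio.** Covariances are built as D·R·D from the SD vectors
and correlation matrices; densities are evaluated via the Cholesky
factor. A non-positive-definite input is refused with the offending group
named: silent "nearest-PSD" repair would mask transcription errors in
parameter files, which are exactly the errors worth catching.

**Maternal age.** The livebirth risk curve is the classical
three-parameter form risk = α + exp(β + γ·age) with defaults
α = 0.000627, β = −16.2395, γ = 0.286; any published curve of this form
can be substituted. Mid-trimester odds divide the livebirth odds by 0.77
(the adjustment is applied to odds, not probabilities; at these
magnitudes the difference is negligible but the contract is fixed).
Simulated unaffected pregnancies draw ages from a packaged single-year
histogram approximating the England and Wales 2006–2008 maternity
distribution; affected pregnancies draw from the same histogram
re-weighted by the age-specific mid-trimester odds, the standard
construction for a risk-gradient population. The packaged histogram is a
smooth interpolation of published five-year group shares (hence
"synthetic" in its filename) and implies a mid-trimester prevalence of
about 1 in 362, consistent with the 1 in 250–500 range such populations
produce; both files are swappable.

**Empirical rate conventions.** DR-for-FPR uses the (1 − fpr) empirical
quantile of unaffected risks with the higher-interpolation convention, so
the realised FPR never exceeds the target, and ties at the cutoff count
as positive (matching the inclusive cutoff rule). FPR-for-DR mirrors
this. Binomial Monte Carlo standard errors accompany every rate. Weekly
summaries are averaged cell-wise (equal numbers screened per week) to
give overall first-trimester performance.

## The synthetic cohort generator

`generate_cohort()` emulates the nested case-control design the analysis
assumes: log-Gaussian MoM distributions around gestational-age-dependent
medians; configurable affected median trends anchored at a completed
week; multiplicative maternal-weight, smoking and ethnicity effects; and
matched-control selection on exact gestational day, 5-year maternal age
band (anchored at multiples of five) and 6-month storage band (anchored
at zero), with ties broken in first-come order after a seeded shuffle.
Defaults mirror the study conditions the package's tests assume: 289
first-trimester cases with 2 controls each, maternal age from the
packaged histogram (median ≈ 29), weight log-normal with median 66 kg and
log10 SD 0.07 (a realistic interquartile spread for a screening
population, since only the median is published), smoking prevalence 7.7%,
and ethnicity proportions of 10% Afro-Caribbean, 73% white, 5.7% South
Asian, 3.3% Oriental and 8.3% other. Gestational days are sampled
uniformly over the configured range because the day-level mix of a
screening population is not otherwise specified.

What the generator does **not** emulate: assay drift with storage time,
missing markers, twin pregnancies, digit preference, or any
non-log-Gaussian tail behaviour beyond what truncation would remove.
Passing tests therefore demonstrate that the estimators recover the
parameters of data that follow the model, not that real cohorts do.

One behaviour worth knowing about: dividing smokers' and Afro-Caribbean
women's MoM values by fixed group divisors, after a median regression
fitted to the covariate-inflated mixture, re-centres the whole cohort a
couple of percent below 1.0 MoM (the weight regression's intercept
absorbs most, not all, of this). The effect is identical for affected and
unaffected pregnancies, so likelihood ratios are essentially untouched;
parameter-recovery tests use covariate-free generators to keep the check
sharp.

## Packaged parameters and their provenance

Two parameter files ship with the package:

* `plgf_parameters.json` — PlGF regressed affected medians by week, the
  probability-plot SDs (0.1705/0.1556 first trimester affected/unaffected,
  0.2243/0.1786 second trimester), truncation limits [0.4, 2.5] MoM,
  gestational trends and covariate divisors, all as published.
* `standard_marker_parameters_synthetic.json` — means, SDs, truncation
  limits and the full correlation matrix for NT, PAPP-A, free β-hCG,
  AFP, uE3 and inhibin-A, plus their correlations with PlGF. **This file
  is a synthetic stand-in**: the reference parameter sets for the
  standard markers live in report appendices that are not distributed
  with this package, so representative values were assembled from the
  published screening literature (single-marker detection rates,
  truncated-scale SDs, standard correlation tables) and are not a
  transcription of any single source. Full-test performance computed from
  it reproduces the published pattern — the Combined, serum Integrated
  and Integrated tests improve markedly when first-trimester PlGF is
  added at 13 weeks, second-trimester PlGF adds little — and most
  absolute false-positive rates to within about a point, but the
  Quadruple test comes out 2–3 percentage points weaker than published
  figures. Users with access to a validated parameter set should supply
  it via `standard_test_parameters(standard_path = ...)` or
  `read_test_parameters()`.

## Problem sizes and determinism

Performance simulations default to 250,000 pregnancies per group, giving
binomial standard errors of about 0.06 percentage points on a 10% rate;
the test suite uses 40,000–250,000 depending on the tolerance being
checked, and the parameter-recovery property runs 100 seeded replicates
of a 289-case/578-control cohort. Every stochastic function takes an
explicit integer seed and is bit-reproducible from it; the pipeline
driver derives per-stage seeds from one root seed so a rerun is
byte-identical.

## Known limitations

* Absolute full-test performance depends on the synthetic standard-marker
  file (above); treat those numbers as indicative.
* Second-trimester marker means are modelled as constant across 14–22
  weeks (except PlGF); gestation-specific second-trimester parameters
  would need a richer parameter file.
* NT is consumed as a MoM-equivalent input; fitting NT gestational
  curves from raw measurements is out of scope.
* The weight regression interprets the published method as binned
  medians (5 kg bins). Sensitivity to bin width on synthetic data is
  below 0.2 percentage points in the recovered per-5 kg slope.
* Risks are expressed at the early second trimester; first-trimester
  expressed risks, twin corrections and ultrasound anomaly adjustments
  are not implemented.
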