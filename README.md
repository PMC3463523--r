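# screenmark

Statistical engine for multi-marker antenatal Down syndrome (trisomy 21)
screening, with placental growth factor (PlGF) as an additional serum
marker. The package is aimed at screening-programme statisticians and
methodologists who need to (i) normalize marker concentrations to
multiples of the median (MoM), (ii) estimate the log-Gaussian distribution
parameters that risk algorithms consume, and (iii) estimate the screening
performance of marker combinations — the Combined, Quadruple, serum
Integrated and Integrated tests, with or without PlGF — by Monte Carlo
simulation. A synthetic nested case-control cohort generator makes every
stage testable without access to patient data.

## The model

Marker concentrations are expressed as MoM values: the concentration
divided by the expected (regressed) median concentration in unaffected
pregnancies at the same gestational age, where the expectation comes from
a weighted regression of log10 category medians (2-day categories in the
first trimester, weekly in the second) on gestational age. MoM values are
then adjusted for maternal weight (log-linear regression of binned
medians), smoking and ethnicity (fixed divisors, e.g. 1.32 for
first-trimester smokers).

Within each group (Down syndrome affected, unaffected) the vector of
log10 MoM values **x** is modelled as multivariate Gaussian with mean
**μ**<sub>g</sub>, SD vector **σ**<sub>g</sub> and correlation matrix
**R**<sub>g</sub> (covariance **Σ**<sub>g</sub> = D<sub>g</sub>
R<sub>g</sub> D<sub>g</sub>). SDs are estimated from the central part of
the probability plot (least-squares slope between the 10th and 90th
centiles), correlations after a single exclusion of points more than 3.5
SD from the mean, and marker values are truncated to limits within which
the distributions are acceptably log-Gaussian — tightened where needed to
the point of risk reversal

x\* = (μ<sub>a</sub>σ<sub>u</sub>² − μ<sub>u</sub>σ<sub>a</sub>²) /
(σ<sub>u</sub>² − σ<sub>a</sub>²),

so that risk is a monotone function of each marker.

A woman's posterior risk multiplies her maternal-age-specific prior odds
of an affected pregnancy — livebirth odds divided by 0.77 to move them to
the early second trimester — by the likelihood ratio
LR(**x**) = φ(**x**; **μ**<sub>a</sub>, **Σ**<sub>a</sub>) /
φ(**x**; **μ**<sub>u</sub>, **Σ**<sub>u</sub>). She is screen positive
when the posterior risk is at or above a cutoff such as 1 in 150.
Screening performance (detection rate DR, false-positive rate FPR, and
the odds of being affected given a positive result, OAPR) is estimated by
simulating 250,000 affected and 250,000 unaffected pregnancies.

## Worked example

```r
library(screenmark)

## PlGF alone at 13 completed weeks: affected median 0.61 MoM,
## SDs 0.1705 / 0.1556 (log10)
d <- plgf_marker_distribution(13)
dr_for_fpr_univariate(d$affected$mean, d$affected$sd, d$unaffected$sd, 0.05)
#> 40.4   # % of affected pregnancies detected at a 5% false-positive rate

## Combined test + first-trimester PlGF at 13 weeks for one pregnancy
tp <- standard_test_parameters("combined", week_first = 13, plgf = "first")
x  <- log10(c(NT = 1.0, PAPP_A = 0.9, free_bhCG_1 = 1.1, PlGF_1 = 0.5))
posterior_risk(35, x, tp)
#>    prior_odds likelihood_ratio posterior_risk one_in_n
#> 1  0.00338        0.466          0.00157        635
```

Although the PlGF value is low (0.5 MoM, which on its own raises risk),
the unremarkable NT, PAPP-A and free β-hCG values dominate: the joint
likelihood ratio of 0.47 turns this 35-year-old's prior odds of about
1:296 into a posterior risk of 1 in 635, below all routine cutoffs.

Population performance of the same test:

```r
sim <- simulate_risks(tp, 250000, 250000, seed = 1)
screening_performance(sim)
#> Screening performance: combined+PlGF(T1) (n = 250,000 + 250,000, seed 1)
#>   first-trimester markers at 13 completed weeks
#>   DR (%) for FPR of:   1%: 75.0   3%: 84.5   5%: 88.4
#>   FPR (%) for DR of:   85%: 3.2   90%: 6.3   95%: 14.4
#>   At risk cutoffs:     1/100: DR 81 FPR 2.0 OAPR 1:9 ...
```

i.e. adding PlGF at 13 weeks lets the Combined test reach a 90% detection
rate at roughly half the false-positive rate it needs without PlGF
(compare `plgf = "none"`).

Note: the PlGF distribution parameters are packaged from published
results, but the standard-marker block
(`inst/extdata/standard_marker_parameters_synthetic.json`) is a synthetic
literature-based stand-in, so absolute full-test figures are indicative;
see the methods vignette (`vignettes/screening-methods.Rmd`).

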