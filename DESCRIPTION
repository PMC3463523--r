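Package: screenmark
Title: Multiple-of-the-Median Marker Modelling and Risk Simulation for Antenatal Down Syndrome Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling maternal serum screening markers for Down
    syndrome (trisomy 21). Converts marker concentrations to gestational-age
    specific multiples of the median (MoM) with maternal weight, smoking and
    ethnicity adjustment; estimates log-Gaussian distribution parameters
    (median trends by regression, standard deviations from probability plots,
    outlier-excluded correlations, truncation limits with risk-reversal
    checks); computes posterior Down syndrome risk from multivariate Gaussian
    likelihood ratios combined with maternal age-specific prior odds; and
    estimates screening performance (detection rate, false-positive rate and
    the odds of being affected given a positive result) for the Combined,
    Quadruple, serum Integrated and Integrated tests, with or without
    placental growth factor (PlGF), by Monte Carlo simulation. Includes a
    synthetic nested case-control cohort generator so that the whole pipeline
    is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
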