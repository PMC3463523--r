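#' Packaged PlGF distribution parameters
#'
#' Loads the packaged placental growth factor parameter file: regressed
#' affected median MoM by completed week (first trimester 11--13, second
#' trimester 14--16, each evaluated at week + 3 days), probability-plot SDs
#' of log10 MoM (0.1705/0.1556 first trimester affected/unaffected,
#' 0.2243/0.1786 second trimester), MoM truncation limits [0.4, 2.5], the
#' gestational-age median trends, and the smoking/ethnicity adjustment
#' divisors.
#'
#' @param path Optional path to an alternative JSON file of the same shape.
#' @return A list (see the packaged `plgf_parameters.json` for the schema).
#' @export
plgf_parameters <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "plgf_parameters.json",
                        package = "screenmark", mustWork = TRUE)
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' PlGF marker distributions at a gestational week
#'
#' Builds the affected and unaffected univariate [marker_distribution()]s
#' for PlGF measured at a given completed week (11--13 first trimester,
#' 14--16 second trimester). Unaffected log10 MoM has mean 0 by
#' construction of the MoM scale.
#'
#' @param week Completed week of measurement.
#' @param params PlGF parameter list, from [plgf_parameters()].
#' @return A list with elements `affected` and `unaffected`.
#' @export
plgf_marker_distribution <- function(week, params = plgf_parameters()) {
  tri <- if (week <= 13) "first_trimester" else "second_trimester"
  block <- params[[tri]]
  med <- block$affected_median_mom[[as.character(week)]]
  assert_that(!is.null(med),
              sprintf("no PlGF affected median for week %s", week))
  trunc <- cap_truncation_at_reversal(
    as.numeric(block$truncation_mom),
    list(mean = log10(med), sd = block$sd_log10$affected),
    list(mean = 0, sd = block$sd_log10$unaffected))
  list(affected = marker_distribution("PlGF", "affected",
                                      mean = log10(med),
                                      sd = block$sd_log10$affected,
                                      truncation = trunc),
       unaffected = marker_distribution("PlGF", "unaffected",
                                        mean = 0,
                                        sd = block$sd_log10$unaffected,
                                        truncation = trunc))
}

# Marker panels of the four screening tests, in the order used throughout.
test_marker_panels <- list(
  combined = c("NT", "PAPP_A", "free_bhCG_1"),
  quadruple = c("AFP", "uE3", "free_bhCG_2", "inhibin_A"),
  serum_integrated = c("PAPP_A", "AFP", "uE3", "free_bhCG_2", "inhibin_A"),
  integrated = c("NT", "PAPP_A", "AFP", "uE3", "free_bhCG_2", "inhibin_A")
)

#' Assemble parameters for a standard screening test
#'
#' Builds a [test_parameters()] object for the Combined, Quadruple, serum
#' Integrated or Integrated test, optionally extended with a first- or
#' second-trimester PlGF measurement. PlGF means, SDs and truncation limits
#' come from the packaged PlGF file; the standard markers and all
#' correlations come from the packaged standard-marker file, which is a
#' synthetic literature-based stand-in (see
#' `standard_marker_parameters_synthetic.json`), so absolute performance
#' estimates computed from it are indicative rather than a reproduction of
#' any particular study.
#'
#' @param test One of `"combined"`, `"quadruple"`, `"serum_integrated"`,
#'   `"integrated"`.
#' @param week_first Completed week (11, 12 or 13) at which first-trimester
#'   markers are measured; ignored for the Quadruple test.
#' @param plgf `"none"`, `"first"` (first-trimester PlGF, measured at
#'   `week_first`) or `"second"` (second-trimester PlGF, measured at
#'   `week_plgf_second`).
#' @param week_plgf_second Completed week of a second-trimester PlGF
#'   measurement (14--16).
#' @param standard_path,plgf_path Optional alternative parameter files.
#' @return A [test_parameters()] object.
#' @export
standard_test_parameters <- function(test = c("combined", "quadruple",
                                              "serum_integrated", "integrated"),
                                     week_first = 11,
                                     plgf = c("none", "first", "second"),
                                     week_plgf_second = 15,
                                     standard_path = NULL, plgf_path = NULL) {
  test <- match.arg(test)
  plgf <- match.arg(plgf)
  if (is.null(standard_path)) {
    standard_path <- system.file("extdata",
                                 "standard_marker_parameters_synthetic.json",
                                 package = "screenmark", mustWork = TRUE)
  }
  std <- jsonlite::read_json(standard_path, simplifyVector = TRUE)
  pl <- plgf_parameters(plgf_path)

  panel <- test_marker_panels[[test]]
  if (plgf == "first") {
    assert_that(test != "quadruple",
                "first-trimester PlGF cannot be added to the Quadruple test")
    panel <- c(panel, "PlGF_1")
  } else if (plgf == "second") {
    assert_that(test != "combined",
                "second-trimester PlGF cannot be added to the Combined test")
    panel <- c(panel, "PlGF_2")
  }

  week_of <- function(name) {
    if (name %in% c("PlGF_1")) return(week_first)
    if (name %in% c("PlGF_2")) return(week_plgf_second)
    if (std$markers[[name]]$trimester == "first") week_first else NA
  }
  affected_mean <- function(name) {
    if (name == "PlGF_1") {
      return(log10(pl$first_trimester$affected_median_mom[[as.character(week_first)]]))
    }
    if (name == "PlGF_2") {
      return(log10(pl$second_trimester$affected_median_mom[[as.character(week_plgf_second)]]))
    }
    meds <- std$markers[[name]]$affected_median_mom
    key <- if (std$markers[[name]]$trimester == "first") as.character(week_first) else "all"
    assert_that(!is.null(meds[[key]]),
                sprintf("no affected median for %s at week %s", name, key))
    log10(meds[[key]])
  }
  sd_of <- function(name, group) {
    if (name == "PlGF_1") return(pl$first_trimester$sd_log10[[group]])
    if (name == "PlGF_2") return(pl$second_trimester$sd_log10[[group]])
    std$markers[[name]]$sd_log10[[group]]
  }
  trunc_of <- function(name) {
    if (name == "PlGF_1") return(as.numeric(pl$first_trimester$truncation_mom))
    if (name == "PlGF_2") return(as.numeric(pl$second_trimester$truncation_mom))
    as.numeric(std$markers[[name]]$truncation_mom)
  }

  means <- list(affected = vapply(panel, affected_mean, numeric(1)),
                unaffected = stats::setNames(rep(0, length(panel)), panel))
  sds <- list(affected = vapply(panel, sd_of, numeric(1), group = "affected"),
              unaffected = vapply(panel, sd_of, numeric(1), group = "unaffected"))
  ord <- std$correlation_order
  idx <- match(panel, ord)
  assert_that(!anyNA(idx), "panel markers missing from correlation_order")
  correlations <- lapply(std$correlations[c("affected", "unaffected")],
                         function(M) M[idx, idx, drop = FALSE])
  truncation <- vapply(panel, function(nm) {
    cap_truncation_at_reversal(
      trunc_of(nm),
      list(mean = affected_mean(nm), sd = sd_of(nm, "affected")),
      list(mean = 0, sd = sd_of(nm, "unaffected")))
  }, numeric(2))

  has_first <- any(vapply(panel, function(p) isTRUE(!is.na(week_of(p)) && week_of(p) <= 13), logical(1)))
  has_second <- any(panel %in% c("AFP", "uE3", "free_bhCG_2", "inhibin_A", "PlGF_2"))
  label <- paste0(test,
                  switch(plgf, none = "", first = "+PlGF(T1)", second = "+PlGF(T2)"))
  test_parameters(test = label, markers = panel, means = means, sds = sds,
                  correlations = correlations, truncation = truncation,
                  week_first = if (has_first) week_first else NA,
                  week_second = if (has_second) std$week_second_default else NA)
}
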