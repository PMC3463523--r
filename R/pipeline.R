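#' Run the full screening analysis pipeline
#'
#' Executes the analysis stages in order — `simulate` (synthetic cohort),
#' `normalize` (MoM computation and covariate adjustment), `estimate`
#' (distribution parameters), `risk` (per-pregnancy posterior risks) and
#' `performance` (Monte Carlo screening performance) — writing each stage's
#' artifact to `out_dir` and a run manifest recording the configuration
#' snapshot, derived seeds, file checksums and stage timings. Stages can be
#' omitted; `risk`/`performance` fall back to `config$parameters_file`
#' (a [write_test_parameters()] JSON) when `estimate` is not run.
#'
#' All randomness is derived from the single root `seed` by a documented
#' per-stage split, so a rerun with the same configuration and seed
#' produces byte-identical numeric outputs.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `stages` (character subset of the five stage names, in any order —
#'   execution order is fixed), `cohort` (arguments for [cohort_config()]
#'   except `seed`), `marker` (marker column to normalize), `trimester`,
#'   `parameters_file` (optional), `test`, `week_first`, `plgf`,
#'   `n_affected`, `n_unaffected`.
#' @param out_dir Output directory (created if needed).
#' @param seed Root integer seed.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stages <- config$stages %||% c("simulate", "normalize", "estimate",
                                 "risk", "performance")
  order <- c("simulate", "normalize", "estimate", "risk", "performance")
  bad <- setdiff(stages, order)
  assert_that(length(bad) == 0,
              sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  stages <- order[order %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(config = config, root_seed = seed,
                   package_version = as.character(utils::packageVersion("screenmark")),
                   stages = list(), outputs = list())
  cohort <- NULL; moms <- NULL; params <- NULL; marker <- config$marker %||% "PlGF"
  trimester <- config$trimester %||% "first"

  record <- function(stage, files, t0) {
    manifest$stages[[stage]] <<- list(
      seed = derive_seed(seed, stage),
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      files = files)
    for (f in files) manifest$outputs[[basename(f)]] <<- unname(tools::md5sum(f))
  }

  if ("simulate" %in% stages) {
    t0 <- as.numeric(Sys.time())
    cc <- do.call(cohort_config,
                  c(config$cohort, list(seed = derive_seed(seed, "simulate"))))
    cohort <- generate_cohort(cc)
    f <- file.path(out_dir, "cohort.csv")
    utils::write.csv(cohort, f, row.names = FALSE)
    record("simulate", f, t0)
  } else if (!is.null(config$cohort_file)) {
    cohort <- utils::read.csv(config$cohort_file)
  }

  if ("normalize" %in% stages) {
    assert_that(!is.null(cohort), "normalize requires a cohort (run simulate or set cohort_file)")
    t0 <- as.numeric(Sys.time())
    mr <- fit_median_regression(cohort, marker, trimester)
    mom_raw <- compute_mom(cohort[[marker]], cohort$ga_days, mr)
    un <- cohort$outcome == "unaffected"
    wfit <- fit_weight_adjustment(mom_raw[un], cohort$weight_kg[un])
    cov_cfg <- config$covariates %||% list()
    adj <- covariate_adjustment(
      weight = wfit,
      smoking_divisor = cov_cfg$smoking_divisor %||% 1,
      ethnicity_divisors = unlist(cov_cfg$ethnicity_divisors) %||% numeric(0))
    mom_col <- paste0(marker, "_mom")
    cohort[[mom_col]] <- adjust_mom(mom_raw, cohort$weight_kg, cohort$smoker,
                                    cohort$ethnicity, adj)
    moms <- cohort[[mom_col]]
    f <- file.path(out_dir, "cohort_mom.csv")
    utils::write.csv(cohort, f, row.names = FALSE)
    record("normalize", f, t0)
  }

  if ("estimate" %in% stages) {
    assert_that(!is.null(moms), "estimate requires normalized MoM values")
    t0 <- as.numeric(Sys.time())
    aff <- cohort$outcome == "affected"
    med <- regress_affected_medians(moms[aff], cohort$ga_days[aff], trimester)
    sd_a <- estimate_sd_probability_plot(log10(moms[aff]))
    sd_u <- estimate_sd_probability_plot(log10(moms[!aff]))
    week <- config$week_first %||% 12
    trunc <- config$truncation %||% c(0.4, 2.5)
    params <- test_parameters(
      test = paste0(marker, "_univariate"), markers = marker,
      means = list(
        affected = log10(med$regressed_median[med$week == week]),
        unaffected = 0),
      sds = list(affected = sd_a, unaffected = sd_u),
      correlations = list(affected = diag(1), unaffected = diag(1)),
      truncation = matrix(as.numeric(trunc), ncol = 1))
    f1 <- file.path(out_dir, "affected_medians.csv")
    utils::write.csv(med, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "parameters.json")
    write_test_parameters(params, f2)
    record("estimate", c(f1, f2), t0)
  } else if (!is.null(config$parameters_file)) {
    params <- read_test_parameters(config$parameters_file)
  }

  age_model <- age_risk_model()
  age_dist <- maternal_age_distribution()

  if ("risk" %in% stages) {
    assert_that(!is.null(params),
                "risk requires parameters (run estimate or set parameters_file)")
    assert_that(!is.null(cohort), "risk requires a cohort")
    t0 <- as.numeric(Sys.time())
    prof <- log10(as.matrix(cohort[, paste0(params$markers, "_mom"), drop = FALSE]))
    rr <- posterior_risk(cohort$maternal_age_edd, prof, params, age_model)
    rr <- cbind(cohort["id"], rr)
    f <- file.path(out_dir, "risks.csv")
    utils::write.csv(rr, f, row.names = FALSE)
    record("risk", f, t0)
  }

  if ("performance" %in% stages) {
    assert_that(!is.null(params),
                "performance requires parameters (run estimate or set parameters_file)")
    t0 <- as.numeric(Sys.time())
    sim <- simulate_risks(params,
                          n_affected = config$n_affected %||% 250000,
                          n_unaffected = config$n_unaffected %||% 250000,
                          age_dist = age_dist, age_model = age_model,
                          seed = derive_seed(seed, "performance"))
    perf <- screening_performance(sim)
    f <- file.path(out_dir, "performance.json")
    jsonlite::write_json(list(test = perf$test, n = perf$n, seed = perf$seed,
                              prevalence = perf$prevalence,
                              dr_for_fpr = perf$dr_for_fpr,
                              fpr_for_dr = perf$fpr_for_dr,
                              at_cutoff = perf$at_cutoff),
                         f, digits = NA, auto_unbox = TRUE, dataframe = "rows")
    record("performance", f, t0)
  }

  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(manifest)
}
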