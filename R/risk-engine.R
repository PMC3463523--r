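#' Truncate a marker profile to its limits
#'
#' Clamps each coordinate of a log10 MoM profile into the marker's
#' truncation limits (converted to the log10 scale). Values outside the
#' limits carry the likelihood ratio of the nearest limit, which keeps the
#' estimated risk a monotone function of each marker value.
#'
#' @param log10_moms Numeric vector (one profile) or matrix with one row
#'   per profile, columns in `params$markers` order.
#' @param params A [test_parameters()] object.
#' @return Truncated vector or matrix of the same shape.
#' @export
truncate_profile <- function(log10_moms, params) {
  stopifnot(inherits(params, "test_parameters"))
  vec <- is.null(dim(log10_moms))
  x <- if (vec) matrix(log10_moms, nrow = 1) else as.matrix(log10_moms)
  assert_that(ncol(x) == length(params$markers),
              "profile length must match the marker panel")
  lo <- log10(params$truncation["low", ])
  hi <- log10(params$truncation["high", ])
  for (j in seq_len(ncol(x))) x[, j] <- clamp(x[, j], lo[j], hi[j])
  if (vec) drop(x) else x
}

#' Multivariate Gaussian likelihood ratio for a marker profile
#'
#' Evaluates the ratio of the affected to the unaffected multivariate
#' Gaussian density of log10 MoM values at the (truncated) profile. The
#' covariance of each group is built as \eqn{D R D} from its SD vector and
#' correlation matrix.
#'
#' @inheritParams truncate_profile
#' @param truncate Apply [truncate_profile()] first (default `TRUE`).
#' @return Likelihood ratio(s), finite and positive.
#' @export
likelihood_ratio <- function(log10_moms, params, truncate = TRUE) {
  stopifnot(inherits(params, "test_parameters"))
  vec <- is.null(dim(log10_moms))
  x <- if (vec) matrix(log10_moms, nrow = 1) else as.matrix(log10_moms)
  if (truncate) x <- truncate_profile(x, params)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  sig_a <- make_covariance(params$sds$affected, params$correlations$affected)
  sig_u <- make_covariance(params$sds$unaffected, params$correlations$unaffected)
  lr <- exp(ldmvnorm(x, params$means$affected, sig_a, "affected") -
              ldmvnorm(x, params$means$unaffected, sig_u, "unaffected"))
  if (vec) unname(lr[1]) else unname(lr)
}

#' Posterior Down syndrome risk for a marker profile
#'
#' Multiplies the maternal-age-specific mid-trimester prior odds by the
#' multivariate Gaussian likelihood ratio of the marker profile, and
#' classifies the pregnancy as screen positive at each risk cutoff when the
#' posterior risk is greater than or equal to the cutoff.
#'
#' @param age Maternal age (years at expected date of delivery).
#' @param log10_moms Marker profile(s): vector or matrix, columns in
#'   `params$markers` order.
#' @param params A [test_parameters()] object.
#' @param model An [age_risk_model()].
#' @param cutoffs Risk cutoffs as probabilities (default 1/100, 1/150,
#'   1/200, the early-second-trimester cutoffs in routine use).
#' @return A data frame with columns `prior_odds`, `likelihood_ratio`,
#'   `posterior_odds`, `posterior_risk`, `one_in_n` (risk expressed as 1 in
#'   N), and one logical `positive_1_in_<N>` column per cutoff.
#' @export
posterior_risk <- function(age, log10_moms, params, model = age_risk_model(),
                           cutoffs = c(1 / 100, 1 / 150, 1 / 200)) {
  lr <- likelihood_ratio(log10_moms, params)
  prior <- midtrimester_prior_odds(age, model)
  post_odds <- prior * lr
  risk <- post_odds / (1 + post_odds)
  out <- data.frame(prior_odds = prior,
                    likelihood_ratio = lr,
                    posterior_odds = post_odds,
                    posterior_risk = risk,
                    one_in_n = round(1 / risk))
  for (ct in cutoffs) {
    out[[sprintf("positive_1_in_%d", round(1 / ct))]] <- risk >= ct
  }
  out
}
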