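#' Parameters for the population-scale transformation
#'
#' The MR estimate is expressed per 1-log-unit increase in the odds of the
#' (binary) exposure; contrasting ever-users with never-users requires an
#' exposure-scale contrast. The parameter triple is validated for internal
#' consistency: the population risk `K` must lie between the never-user risk
#' `K0` and the implied ever-user risk
#' \eqn{K_1 = (K - (1-P)K_0)/P}, which must itself lie in (0, 1).
#'
#' The contrast can be supplied directly (`contrast`, in log-odds units of
#' exposure — e.g. the value derived in the source analysis' supplementary
#' methods). When omitted, it is derived from the exposure prevalence alone
#' as the difference in mean liability between the top `P` and bottom
#' `1 - P` fractions of a standard logistic liability distribution — a
#' documented fallback, not an attempt to reproduce any specific published
#' recipe.
#'
#' @param disease_risk_population Baseline outcome risk K in the general
#'   population, in (0, 1).
#' @param disease_risk_never_users Outcome risk K0 among never-users.
#' @param exposure_prevalence Fraction P of ever-users, in (0, 1).
#' @param contrast Optional exposure-scale contrast (log-odds units).
#' @return A validated `transform_params` list, with `implied_user_risk`
#'   and the resolved `contrast`.
#' @export
transform_params <- function(disease_risk_population,
                             disease_risk_never_users,
                             exposure_prevalence,
                             contrast = NULL) {
  K <- disease_risk_population
  K0 <- disease_risk_never_users
  P <- exposure_prevalence
  for (v in c(K, K0, P)) {
    if (!is_scalar_number(v) || v <= 0 || v >= 1) {
      stop_input("transformation parameters must all lie in (0, 1)")
    }
  }
  K1 <- (K - (1 - P) * K0) / P
  if (K1 <= 0 || K1 >= 1) {
    stop_input("inconsistent parameters: implied risk among ever-users is ",
               signif(K1, 4), ", outside (0, 1)")
  }
  if ((K - K0) * (K - K1) > 0) {
    stop_input("inconsistent parameters: population risk K must lie between ",
               "the never-user and implied ever-user risks")
  }
  if (is.null(contrast)) contrast <- logistic_liability_contrast(P)
  if (!is_scalar_number(contrast) || contrast <= 0) {
    stop_input("contrast must be a positive number")
  }
  structure(list(disease_risk_population = K,
                 disease_risk_never_users = K0,
                 exposure_prevalence = P,
                 implied_user_risk = K1,
                 contrast = contrast),
            class = "transform_params")
}

# Difference in mean standard-logistic liability between the top P and
# bottom 1-P fractions of the distribution. Closed form: with q the
# (1-P)-quantile, E[X | X > q] = (qP + log(1 + exp(-q)))/P and, since the
# mean is 0, the contrast is E[X | X > q]/(1-P).
logistic_liability_contrast <- function(P) {
  q <- stats::qlogis(1 - P)
  e_top <- (q * P + log1p(exp(-q))) / P
  e_top / (1 - P)
}

#' Transform a per-log-unit MR estimate to an ever- vs never-user odds ratio
#'
#' Applies a strictly increasing linear map on the log-OR scale: the causal
#' log odds ratio, its standard error and both CI bounds are multiplied by
#' the exposure-scale contrast resolved by [transform_params()]. The null is
#' preserved (OR 1 maps to OR 1), direction is preserved, and the CI width
#' on the log scale scales by the same factor as the point estimate.
#'
#' @param estimate An `mr_estimate` on the per-1-log-unit log-OR scale.
#' @param params A [transform_params()] object.
#' @return An `mr_estimate` with `"_population"` appended to the method
#'   label.
#' @export
per_log_unit_to_ever_never <- function(estimate, params) {
  stopifnot(inherits(params, "transform_params"))
  if (!is_scalar_number(estimate$theta) || !is_scalar_number(estimate$se)) {
    stop_input("estimate must carry a finite theta and se on the log scale")
  }
  s <- params$contrast
  out <- new_mr_estimate(paste0(estimate$method, "_population"),
                         estimate$theta * s, estimate$se * s,
                         estimate$n_snps,
                         q_stat = estimate$q_stat, tau2 = estimate$tau2)
  out
}
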