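#' Construct an MR estimate record
#'
#' Internal constructor shared by every pooling method. Confidence intervals
#' and p-values use the normal reference distribution, the standard in
#' two-sample MR.
#'
#' @keywords internal
new_mr_estimate <- function(method, theta, se, n_snps,
                            q_stat = NA_real_, tau2 = NA_real_,
                            intercept = NA_real_, intercept_se = NA_real_,
                            extra = list()) {
  z <- theta / se
  i2 <- if (is.na(q_stat) || q_stat <= 0) {
    if (is.na(q_stat)) NA_real_ else 0
  } else {
    max(0, (q_stat - (n_snps - 1)) / q_stat) * 100
  }
  est <- c(list(
    method = method,
    theta = theta,
    se = se,
    ci_low = theta - stats::qnorm(0.975) * se,
    ci_high = theta + stats::qnorm(0.975) * se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    n_snps = n_snps,
    q_stat = q_stat,
    i2 = i2,
    tau2 = tau2,
    intercept = intercept,
    intercept_se = intercept_se,
    intercept_p = if (is.na(intercept)) NA_real_ else
      2 * stats::pnorm(-abs(intercept / intercept_se))
  ), extra)
  class(est) <- "mr_estimate"
  est
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], %d SNPs\n", x$method, x$n_snps))
  cat(sprintf("  log-OR %.4f (se %.4f), OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$theta, x$se, exp(x$theta), exp(x$ci_low), exp(x$ci_high),
              x$pvalue))
  if (!is.na(x$q_stat)) {
    cat(sprintf("  Q = %.2f, I2 = %.1f%%%s\n", x$q_stat, x$i2,
                if (!is.na(x$tau2)) sprintf(", tau2 = %.4g", x$tau2) else ""))
  }
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, theta = x$theta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             or = exp(x$theta), or_low = exp(x$ci_low), or_high = exp(x$ci_high),
             n_snps = x$n_snps, q_stat = x$q_stat, i2 = x$i2, tau2 = x$tau2,
             intercept = x$intercept, intercept_se = x$intercept_se,
             intercept_p = x$intercept_p, stringsAsFactors = FALSE)
}

#' Bind a list of MR estimates into a one-row-per-method data frame
#'
#' @param estimates List of `mr_estimate` objects.
#' @return A `data.frame`.
#' @export
mr_estimates_table <- function(estimates) {
  do.call(rbind, lapply(estimates, as.data.frame))
}

#' Per-SNP Wald ratio estimates
#'
#' The per-SNP causal estimate divides the SNP-outcome association by the
#' SNP-exposure association, \eqn{\hat\theta_j = \hat\Gamma_j/\hat\gamma_j}.
#' Its standard error is the first-order delta approximation
#' \deqn{se_j = \sqrt{se_\Gamma^2/\hat\gamma^2 +
#'   \hat\Gamma^2 se_\gamma^2 / \hat\gamma^4}.}
#' With `second_order = TRUE` the second-order term
#' \eqn{se_\gamma^2 se_\Gamma^2/\hat\gamma^4} is added inside the root.
#'
#' @param instruments Harmonized instrument data frame.
#' @param second_order Include the second-order delta term (default FALSE).
#' @return A `data.frame` of class `wald_estimates` with columns `rsid`,
#'   `ratio`, `se`.
#' @export
wald_ratio <- function(instruments, second_order = FALSE) {
  bx <- instruments$beta_exposure
  if (any(bx == 0)) {
    stop_input("zero exposure effect for SNP(s) ",
               paste(instruments$rsid[bx == 0], collapse = ", "),
               "; Wald ratio undefined")
  }
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  var_ratio <- sy^2 / bx^2 + by^2 * sx^2 / bx^4
  if (second_order) var_ratio <- var_ratio + sx^2 * sy^2 / bx^4
  out <- data.frame(rsid = instruments$rsid, ratio = by / bx,
                    se = sqrt(var_ratio), se_nome = sy / abs(bx),
                    stringsAsFactors = FALSE)
  class(out) <- c("wald_estimates", "data.frame")
  out
}

# Pooling weights: under "nome" (the default, matching the regression form
# and standard two-sample MR tooling) the exposure-side uncertainty is
# ignored in the weights, w_j = gamma_j^2/se_Gamma_j^2; "delta" uses the
# full delta-method variance of the ratio instead.
pooling_se <- function(estimates, weights) {
  if (weights == "nome" && "se_nome" %in% names(estimates)) {
    estimates$se_nome
  } else {
    estimates$se
  }
}

#' Fixed-effects inverse-variance-weighted pooling of Wald ratios
#'
#' Pools per-SNP causal estimates with weights \eqn{w_j = 1/se_j^2}:
#' \eqn{\hat\theta = \sum w_j\hat\theta_j/\sum w_j},
#' \eqn{se = 1/\sqrt{\sum w_j}}, with Cochran's
#' \eqn{Q = \sum w_j(\hat\theta_j - \hat\theta)^2} and
#' \eqn{I^2 = \max(0, (Q - (k-1))/Q) \times 100}.
#'
#' @param estimates `wald_estimates` data frame from [wald_ratio()], or any
#'   data frame with `ratio` and `se` columns.
#' @param weights `"nome"` (default): weight by the outcome-side variance
#'   only, \eqn{w_j = \hat\gamma_j^2/se_{\Gamma j}^2} — identical to the
#'   weighted regression of outcome on exposure effects through the origin
#'   and to standard two-sample MR practice; `"delta"`: weight by the full
#'   delta-method ratio variance. When the `se_nome` column is absent
#'   (hand-built ratio tables) the `se` column is used for both choices.
#' @return An `mr_estimate` with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(estimates, weights = c("nome", "delta")) {
  weights <- match.arg(weights)
  k <- nrow(estimates)
  if (is.null(k) || k < 2) stop_input("IVW needs at least 2 SNPs")
  se <- pooling_se(estimates, weights)
  w <- 1 / se^2
  theta <- sum(w * estimates$ratio) / sum(w)
  q <- sum(w * (estimates$ratio - theta)^2)
  new_mr_estimate("ivw_fixed", theta, 1 / sqrt(sum(w)), k, q_stat = q)
}

# DerSimonian-Laird moment estimator of between-unit variance and the
# re-weighted pooled estimate. Shared by ivw_random() and dl_meta().
dl_pool <- function(est, se, method_label) {
  k <- length(est)
  if (k < 2) stop_input("random-effects pooling needs at least 2 estimates")
  w <- 1 / se^2
  theta_fe <- sum(w * est) / sum(w)
  q <- sum(w * (est - theta_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (se^2 + tau2)
  theta <- sum(w_star * est) / sum(w_star)
  new_mr_estimate(method_label, theta, 1 / sqrt(sum(w_star)), k,
                  q_stat = q, tau2 = tau2)
}

#' Random-effects (DerSimonian-Laird) pooling of Wald ratios
#'
#' Estimates the between-SNP variance by the moment estimator
#' \eqn{\hat\tau^2 = \max(0, (Q - (k-1))/(\sum w - \sum w^2/\sum w))},
#' re-weights with \eqn{w_j^* = 1/(se_j^2 + \hat\tau^2)} and pools as in
#' [ivw_fixed()]. When \eqn{Q \le k-1} the result equals the fixed-effects
#' pooling.
#'
#' @inheritParams ivw_fixed
#' @return An `mr_estimate` with method `"ivw_random"`.
#' @export
ivw_random <- function(estimates, weights = c("nome", "delta")) {
  weights <- match.arg(weights)
  dl_pool(estimates$ratio, pooling_se(estimates, weights), "ivw_random")
}

#' Regression-form IVW estimate
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations through the origin with weights \eqn{1/se_\Gamma^2} — the
#' regression counterpart of ratio-based IVW, and the model MR-Egger relaxes
#' by freeing the intercept. Agrees with [ivw_fixed()] in the strong-
#' instrument limit.
#'
#' @param instruments Harmonized instrument data frame.
#' @return An `mr_estimate` with method `"ivw_regression"`.
#' @export
ivw_regression <- function(instruments) {
  k <- nrow(instruments)
  if (k < 2) stop_input("IVW needs at least 2 SNPs")
  w <- 1 / instruments$se_outcome^2
  fit <- wls_line(instruments$beta_exposure, instruments$beta_outcome, w,
                  intercept = FALSE)
  se <- 1 / sqrt(sum(w * instruments$beta_exposure^2))
  resid <- instruments$beta_outcome - fit[2] * instruments$beta_exposure
  new_mr_estimate("ivw_regression", fit[2], se, k,
                  q_stat = sum(w * resid^2))
}

#' Serialize MR estimates to TSV and JSON
#'
#' @param estimates List of `mr_estimate` objects.
#' @param tsv_path,json_path Output paths; `NULL` skips that format.
#' @return The estimates table, invisibly.
#' @export
write_mr_estimates <- function(estimates, tsv_path = NULL, json_path = NULL) {
  tab <- mr_estimates_table(estimates)
  if (!is.null(tsv_path)) {
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(tab, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(tab)
}
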