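# Orient instruments so every exposure effect is non-negative, flipping the
# outcome (and covariate) effect signs accordingly. Egger-type regressions
# are defined on this orientation and are invariant to the input signs.
orient_positive <- function(instruments) {
  flip <- instruments$beta_exposure < 0
  instruments$beta_exposure <- abs(instruments$beta_exposure)
  instruments$beta_outcome[flip] <- -instruments$beta_outcome[flip]
  if ("beta_covariate" %in% names(instruments)) {
    instruments$beta_covariate[flip] <- -instruments$beta_covariate[flip]
  }
  instruments
}

egger_fit <- function(bx, by, w) {
  wls_line(bx, by, w, intercept = TRUE)  # c(intercept, slope)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome associations on the
#' SNP-exposure associations (weights \eqn{1/se_\Gamma^2}) with an
#' unconstrained intercept. The slope estimates the causal effect allowing
#' directional pleiotropy; the intercept estimates the average directional
#' pleiotropic effect, and a low intercept p-value suggests pleiotropy.
#' Exposure effects are re-oriented to be non-negative before fitting.
#'
#' Standard errors are obtained by bootstrap, resampling SNPs with
#' replacement (`n_boot` resamples, default 10,000); `n_boot = 0` falls back
#' to the analytic weighted-least-squares errors.
#'
#' @param instruments Harmonized instrument data frame (>= 3 SNPs).
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` with method `"egger"`, slope in `theta` and the
#'   pleiotropy intercept in `intercept`/`intercept_se`/`intercept_p`.
#' @export
mr_egger <- function(instruments, n_boot = 10000, seed = 1) {
  k <- nrow(instruments)
  if (k < 3) stop_input("MR-Egger needs at least 3 SNPs")
  d <- orient_positive(instruments)
  w <- 1 / d$se_outcome^2
  fit <- egger_fit(d$beta_exposure, d$beta_outcome, w)

  if (n_boot > 0) {
    ses <- with_seed(seed, {
      boot <- boot_egger(d$beta_exposure, d$beta_outcome, w, n_boot)
      c(stats::sd(boot[1, ]), stats::sd(boot[2, ]))
    })
    int_se <- ses[1]; slope_se <- ses[2]
  } else {
    sw <- sum(w); sx <- sum(w * d$beta_exposure)
    sxx <- sum(w * d$beta_exposure^2)
    resid <- d$beta_outcome - fit[1] - fit[2] * d$beta_exposure
    s2 <- sum(w * resid^2) / (k - 2)
    den <- sw * sxx - sx^2
    slope_se <- sqrt(s2 * sw / den)
    int_se <- sqrt(s2 * sxx / den)
  }
  new_mr_estimate("egger", fit[2], slope_se, k,
                  intercept = fit[1], intercept_se = int_se)
}

# Vectorized SNP-resampling bootstrap of the Egger fit; returns a 2 x B
# matrix (intercept; slope).
boot_egger <- function(bx, by, w, n_boot) {
  k <- length(bx)
  idx <- matrix(sample.int(k, k * n_boot, replace = TRUE), nrow = k)
  WX <- matrix(w[idx] * bx[idx], nrow = k)
  WY <- matrix(w[idx] * by[idx], nrow = k)
  W <- matrix(w[idx], nrow = k)
  BX <- matrix(bx[idx], nrow = k)
  sw <- colSums(W)
  sx <- colSums(WX)
  sy <- colSums(WY)
  sxx <- colSums(WX * BX)
  sxy <- colSums(WY * BX)
  den <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / den
  rbind((sy - slope * sx) / sw, slope)
}

#' I-squared_GX: adequacy of the NO-Measurement-Error assumption
#'
#' Quantifies the dilution of the MR-Egger slope due to noise in the
#' SNP-exposure associations. With \eqn{\bar\gamma_w} the
#' \eqn{1/se_\gamma^2}-weighted mean of the \eqn{|\hat\gamma_j|},
#' \deqn{Q_{GX} = \sum_j (|\hat\gamma_j| - \bar\gamma_w)^2/se_{\gamma j}^2,
#'  \quad I^2_{GX} = \max(0, (Q_{GX} - (k-1))/Q_{GX}) \times 100.}
#' Values near 100% indicate negligible regression dilution; low values flag
#' weak-instrument bias in the Egger slope.
#'
#' @param instruments Harmonized instrument data frame (>= 2 SNPs).
#' @return Percentage in \[0, 100\].
#' @export
i2_gx <- function(instruments) {
  if (nrow(instruments) < 2) stop_input("I2_GX needs at least 2 SNPs")
  g <- abs(instruments$beta_exposure)
  w <- 1 / instruments$se_exposure^2
  gbar <- sum(w * g) / sum(w)
  q <- sum((g - gbar)^2 * w)
  if (q <= 0) return(0)
  max(0, (q - (nrow(instruments) - 1)) / q) * 100
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation-extrapolation correction for the measurement-error attenuation
#' of the Egger slope when the NO-Measurement-Error assumption is violated.
#' For each inflation factor \eqn{\lambda} in the grid, the SNP-exposure
#' estimates are perturbed `n_sim` times with
#' \eqn{N(0, \lambda \cdot se_{\gamma j}^2)} noise, the Egger regression is
#' refit, and the slopes averaged; a quadratic in \eqn{\lambda} is then fit
#' to the mean slopes and extrapolated to \eqn{\lambda = -1} (the
#' error-free limit). The standard error is a SNP-resampling bootstrap over
#' the entire procedure.
#'
#' @param instruments Harmonized instrument data frame (>= 3 SNPs).
#' @param lambdas Inflation grid; must contain 0 (default `seq(0, 2, 0.5)`).
#' @param n_sim Simulations per grid point (default 1000).
#' @param seed Seed; the procedure is deterministic given it.
#' @param n_boot Bootstrap resamples for the standard error (default 100).
#' @return An `mr_estimate` with method `"egger_simex"`; `intercept` holds
#'   the SIMEX-extrapolated Egger intercept.
#' @export
egger_simex <- function(instruments, lambdas = seq(0, 2, 0.5), n_sim = 1000,
                        seed = 1, n_boot = 100) {
  if (nrow(instruments) < 3) stop_input("SIMEX needs at least 3 SNPs")
  if (!any(lambdas == 0)) stop_config("SIMEX grid must contain lambda = 0")
  d <- orient_positive(instruments)
  with_seed(seed, {
    point <- simex_once(d$beta_exposure, d$beta_outcome,
                        d$se_exposure, d$se_outcome, lambdas, n_sim)
    if (n_boot > 0) {
      k <- nrow(d)
      boots <- vapply(seq_len(n_boot), function(b) {
        i <- sample.int(k, k, replace = TRUE)
        simex_once(d$beta_exposure[i], d$beta_outcome[i],
                   d$se_exposure[i], d$se_outcome[i], lambdas, n_sim)
      }, numeric(2))
      slope_se <- stats::sd(boots[1, ])
      int_se <- stats::sd(boots[2, ])
    } else {
      slope_se <- NA_real_
      int_se <- NA_real_
    }
    new_mr_estimate("egger_simex", point[1], slope_se, nrow(d),
                    intercept = point[2], intercept_se = int_se)
  })
}

# One SIMEX pass: mean Egger coefficients along the lambda grid, quadratic
# extrapolation to lambda = -1. Returns c(slope, intercept).
simex_once <- function(bx, by, sx, sy, lambdas, n_sim) {
  w <- 1 / sy^2
  sw <- sum(w)
  sy_w <- sum(w * by)
  coefs <- vapply(lambdas, function(lam) {
    if (lam == 0) {
      fit <- egger_fit(bx, by, w)
      return(c(fit[2], fit[1]))
    }
    noise <- matrix(stats::rnorm(length(bx) * n_sim, 0, sqrt(lam) * sx),
                    nrow = length(bx))
    BX <- bx + noise
    sx_w <- colSums(w * BX)
    sxx_w <- colSums(w * BX^2)
    sxy_w <- colSums(w * by * BX)
    den <- sw * sxx_w - sx_w^2
    slopes <- (sw * sxy_w - sx_w * sy_w) / den
    ints <- (sy_w - slopes * sx_w) / sw
    c(mean(slopes), mean(ints))
  }, numeric(2))
  extrapolate <- function(y) {
    fit <- stats::lm.fit(cbind(1, lambdas, lambdas^2), y)
    sum(fit$coefficients * c(1, -1, 1))
  }
  c(extrapolate(coefs[1, ]), extrapolate(coefs[2, ]))
}

# Exact weighted median by the cumulative-midpoint percentile construction.
weighted_median_est <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- w[ord] / sum(w)
  p <- cumsum(wn) - wn / 2
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  stats::approx(p, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' Consistent even when up to 50% of the weight comes from invalid
#' instruments. Ratios are sorted ascending; with normalized weights
#' \eqn{w'_j} the cumulative midpoint percentiles are
#' \eqn{p_j = \sum_{i \le j} w'_i - w'_j/2} and the estimate is the linear
#' interpolation of the ordered ratios at \eqn{p = 0.5}. The standard error
#' is a parametric bootstrap drawing
#' \eqn{\hat\theta_j^* \sim N(\hat\theta_j, se_j^2)}.
#'
#' @param estimates `wald_estimates` data frame (>= 3 SNPs).
#' @param n_boot Parametric bootstrap draws (default 10,000).
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(estimates, n_boot = 10000, seed = 1) {
  k <- nrow(estimates)
  if (is.null(k) || k < 3) stop_input("weighted median needs at least 3 SNPs")
  w <- 1 / estimates$se^2
  est <- weighted_median_est(estimates$ratio, w)
  se <- with_seed(seed, {
    draws <- matrix(stats::rnorm(k * n_boot, estimates$ratio, estimates$se),
                    nrow = k)
    stats::sd(apply(draws, 2, weighted_median_est, w = w))
  })
  new_mr_estimate("weighted_median", est, se, k)
}

#' Steiger directionality filtering
#'
#' For each SNP, the variance explained on each trait is recovered from the
#' Wald z-statistic and sample size as \eqn{r^2 = z^2/(z^2 + n - 2)}; a
#' valid instrument should explain more variance in the exposure than in the
#' outcome. The per-SNP test compares the Fisher-transformed implied
#' correlations with a two-sided z-test; the overall test pools the per-SNP
#' \eqn{r^2} across (approximately independent) instruments and applies the
#' same comparison.
#'
#' @param instruments Harmonized instrument data frame.
#' @param n_exposure,n_outcome Sample sizes; default to the per-SNP `n`
#'   columns carried through harmonization.
#' @return A `data.frame` with columns `rsid`, `r2_exposure`, `r2_outcome`,
#'   `correct_direction`, `z_p`; attributes `overall_z`, `overall_p`,
#'   `overall_direction`.
#' @export
steiger_filter <- function(instruments, n_exposure = NULL, n_outcome = NULL) {
  n_exp <- n_exposure %||% instruments$n_exposure
  n_out <- n_outcome %||% instruments$n_outcome
  if (any(!is.finite(n_exp)) || any(!is.finite(n_out)) ||
      any(n_exp <= 3) || any(n_out <= 3)) {
    stop_input("positive sample sizes (> 3) are required for Steiger filtering")
  }
  z_exp <- instruments$beta_exposure / instruments$se_exposure
  z_out <- instruments$beta_outcome / instruments$se_outcome
  r2_exp <- z_exp^2 / (z_exp^2 + n_exp - 2)
  r2_out <- z_out^2 / (z_out^2 + n_out - 2)

  steiger_z <- function(r2x, r2y, nx, ny) {
    (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) / sqrt(1 / (nx - 3) + 1 / (ny - 3))
  }
  z <- steiger_z(r2_exp, r2_out, n_exp, n_out)
  out <- data.frame(rsid = instruments$rsid,
                    r2_exposure = r2_exp, r2_outcome = r2_out,
                    correct_direction = r2_exp > r2_out,
                    z_p = 2 * stats::pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  tot_z <- steiger_z(min(sum(r2_exp), 1 - 1e-12), min(sum(r2_out), 1 - 1e-12),
                     mean(n_exp), mean(n_out))
  attr(out, "overall_z") <- tot_z
  attr(out, "overall_p") <- 2 * stats::pnorm(-abs(tot_z))
  attr(out, "overall_direction") <- sum(r2_exp) > sum(r2_out)
  out
}

#' Write per-SNP Steiger results as TSV
#'
#' @param steiger Data frame from [steiger_filter()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_steiger <- function(steiger, path) {
  utils::write.table(steiger, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Multivariable MR adjusting for a secondary exposure
#'
#' Weighted least squares of the SNP-outcome associations on the primary-
#' and secondary-exposure associations jointly (weights
#' \eqn{1/se_\Gamma^2}, no intercept); the primary-exposure coefficient is
#' the adjusted causal estimate. SNPs with missing covariate effects are
#' dropped and counted (attribute `n_dropped_covariate`). Standard errors
#' are a SNP-resampling bootstrap (default 10,000 resamples). If every
#' covariate effect is zero the fit reduces to the regression-form IVW
#' estimate and the covariate coefficient is `NA`.
#'
#' @param instruments Harmonized instrument data frame with
#'   `beta_covariate`/`se_covariate` (>= 3 complete SNPs).
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap.
#' @return An `mr_estimate` with method `"mvmr"`; extra fields
#'   `covariate_theta` and `covariate_se` hold the secondary-exposure
#'   coefficient.
#' @export
mr_mvmr <- function(instruments, n_boot = 10000, seed = 1) {
  complete <- !is.na(instruments$beta_covariate)
  n_dropped <- sum(!complete)
  d <- orient_positive(instruments[complete, , drop = FALSE])
  if (nrow(d) < 3) stop_input("multivariable MR needs at least 3 complete SNPs")

  if (all(d$beta_covariate == 0)) {
    est <- ivw_regression(d)
    est$method <- "mvmr"
    est$covariate_theta <- NA_real_
    est$covariate_se <- NA_real_
    attr(est, "n_dropped_covariate") <- n_dropped
    return(est)
  }

  w <- 1 / d$se_outcome^2
  X <- cbind(exposure = d$beta_exposure, covariate = d$beta_covariate)
  Xw <- X * sqrt(w)
  if (qr(Xw)$rank < ncol(X)) {
    stop_input("rank-deficient multivariable design: exposure and covariate ",
               "effects are collinear")
  }
  fit_coef <- function(X, y, w) {
    Xw <- X * sqrt(w)
    yw <- y * sqrt(w)
    qr.coef(qr(Xw), yw)
  }
  coefs <- fit_coef(X, d$beta_outcome, w)

  ses <- with_seed(seed, {
    k <- nrow(d)
    boots <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(k, k, replace = TRUE)
      cf <- tryCatch(fit_coef(X[i, , drop = FALSE], d$beta_outcome[i], w[i]),
                     error = function(e) c(NA_real_, NA_real_))
      cf
    }, numeric(2))
    apply(boots, 1, stats::sd, na.rm = TRUE)
  })

  est <- new_mr_estimate("mvmr", unname(coefs[1]), ses[1], nrow(d),
                         extra = list(covariate_theta = unname(coefs[2]),
                                      covariate_se = ses[2]))
  attr(est, "n_dropped_covariate") <- n_dropped
  est
}
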