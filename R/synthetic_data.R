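#' Configuration for the two-sample summary-statistics generator
#'
#' Collects every knob of the synthetic generator. Defaults emulate the
#' structure of the cannabis-use instrument set applied to a CAD-scale
#' case-control outcome GWAS: 64 approximately independent SNPs jointly
#' explaining 1% of exposure variance in an exposure GWAS of 184,765
#' participants, with a binary outcome of 60,801 cases and 123,504 controls.
#'
#' @param n_snps Number of instruments (>= 2).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome GWAS case/control counts.
#' @param total_r2 Variance in the exposure jointly explained by the
#'   instruments, in (0, 1); per-SNP effects are rescaled to hit it exactly.
#' @param theta True causal effect of the exposure on the outcome log-odds.
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of per-SNP direct
#'   (pleiotropic) effects on the outcome; a non-zero mean makes the
#'   pleiotropy directional.
#' @param inside_violation Correlation in (-1, 1) between pleiotropic and
#'   instrument effect sizes; non-zero violates the InSIDE assumption.
#' @param prop_invalid Fraction of SNPs given an additional large direct
#'   effect `invalid_alpha` (invalid instruments for breakdown experiments).
#' @param invalid_alpha Direct outcome effect added to each invalid SNP.
#' @param maf_range Interval within (0, 0.5] for simulated minor-allele
#'   frequencies.
#' @param gamma_trunc Lower truncation point (in half-normal SD units) for
#'   the instrument-effect magnitudes before rescaling (default 1).
#'   Published instrument lists have passed a significance threshold, so a
#'   generator emulating them should not produce near-null instruments.
#' @param covariate_theta True causal effect of a secondary exposure
#'   (e.g. tobacco) on the outcome; `NULL` disables the covariate arm.
#' @param covariate_r2 Variance of the secondary exposure explained by the
#'   same SNPs.
#' @param covariate_cor Correlation between primary- and secondary-exposure
#'   instrument effects.
#' @param n_covariate Covariate GWAS sample size.
#' @param seed Mandatory random seed; all randomness is local to the
#'   generator.
#' @return A `simulation_config` list, validated.
#' @export
simulation_config <- function(n_snps = 64,
                              n_exposure = 184765,
                              n_cases = 60801,
                              n_controls = 123504,
                              total_r2 = 0.01,
                              theta = 0,
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0,
                              inside_violation = 0,
                              prop_invalid = 0,
                              invalid_alpha = 0,
                              maf_range = c(0.05, 0.5),
                              gamma_trunc = 1,
                              covariate_theta = NULL,
                              covariate_r2 = NULL,
                              covariate_cor = 0.3,
                              n_covariate = 1232091,
                              seed) {
  if (missing(seed) || is.null(seed)) stop_config("seed is mandatory")
  if (!is_scalar_number(n_snps) || n_snps < 2) stop_config("n_snps must be >= 2")
  if (!is_scalar_number(total_r2) || total_r2 <= 0 || total_r2 >= 1) {
    stop_config("total_r2 must be in (0, 1)")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop_config("maf_range must be an increasing interval within (0, 0.5]")
  }
  # the rescaled per-SNP effects must stay small enough to be meaningful
  # log-odds effects; a joint r2 this large over so few SNPs has no
  # counterpart in the data structure being emulated
  if (total_r2 / n_snps > 0.1) {
    stop_config("infeasible total_r2 ", total_r2, " for ", n_snps, " SNPs")
  }
  if (!is_scalar_number(inside_violation) || abs(inside_violation) >= 1) {
    stop_config("inside_violation must be in (-1, 1)")
  }
  if (prop_invalid < 0 || prop_invalid > 1) stop_config("prop_invalid must be in [0, 1]")
  cfg <- list(n_snps = as.integer(n_snps), n_exposure = n_exposure,
              n_cases = n_cases, n_controls = n_controls,
              total_r2 = total_r2, theta = theta,
              pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
              inside_violation = inside_violation,
              prop_invalid = prop_invalid, invalid_alpha = invalid_alpha,
              maf_range = maf_range, gamma_trunc = gamma_trunc,
              covariate_theta = covariate_theta, covariate_r2 = covariate_r2,
              covariate_cor = covariate_cor, n_covariate = n_covariate,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a two-sample GWAS summary-statistics pair
#'
#' Generates exposure, outcome and (optionally) covariate summary statistics
#' directly on the log-odds scale with analytic standard-error
#' approximations, emulating a two-sample design with non-overlapping
#' samples:
#' \itemize{
#'   \item MAFs \eqn{p_j} uniform on `maf_range`;
#'   \item exposure effects \eqn{\gamma_j}: half-normal magnitudes, random
#'     signs, rescaled so \eqn{\sum_j 2\gamma_j^2 p_j(1-p_j)} equals
#'     `total_r2` exactly;
#'   \item true outcome effects
#'     \eqn{\Gamma_j = \theta\gamma_j + \theta_c\delta_j +
#'     sign(\gamma_j)\alpha_j} with \eqn{\alpha_j} normal (optionally
#'     correlated with \eqn{|\gamma_j|} to violate InSIDE) plus
#'     `invalid_alpha` on the invalid subset; direct effects are expressed
#'     in the orientation of the exposure-increasing allele, the frame in
#'     which directional pleiotropy (the Egger intercept) is defined;
#'   \item observed estimates are the true values plus normal noise with
#'     \eqn{se(\hat\gamma_j) = 1/\sqrt{2 N p_j(1-p_j)}} and
#'     \eqn{se(\hat\Gamma_j) = \sqrt{(1/n_{cases}+1/n_{controls})/(2
#'     p_j(1-p_j))}}; p-values from the Wald z.
#' }
#'
#' @param config A [simulation_config()].
#' @return A `sim_study_pair` list: `exposure_stats`, `outcome_stats`,
#'   `covariate_stats` (or `NULL`), and `truth` (the config plus per-SNP
#'   true `gamma`, `alpha`, `delta`, `Gamma`, and `invalid` flags).
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    k <- config$n_snps
    rsid <- sprintf("rs%07d", seq_len(k))
    p <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    v <- 2 * p * (1 - p)

    # Half-normal magnitudes truncated away from zero: published instrument
    # lists have passed a significance threshold, so the generator must not
    # produce essentially null instruments whose estimated orientation is
    # random (they would destroy the directional-pleiotropy structure the
    # oriented frame carries).
    mag <- stats::qnorm(stats::runif(k, stats::pnorm(config$gamma_trunc), 1))
    scale <- sqrt(config$total_r2 / sum(mag^2 * v))
    gamma <- sample(c(-1, 1), k, replace = TRUE) * scale * mag

    gz <- as.numeric(scale(abs(gamma)))
    rho <- config$inside_violation
    alpha <- config$pleiotropy_mean + config$pleiotropy_sd *
      (rho * gz + sqrt(1 - rho^2) * stats::rnorm(k))
    invalid <- rep(FALSE, k)
    n_invalid <- round(config$prop_invalid * k)
    if (n_invalid > 0) {
      invalid[sample.int(k, n_invalid)] <- TRUE
      alpha[invalid] <- alpha[invalid] + config$invalid_alpha
    }

    delta <- NULL
    has_cov <- !is.null(config$covariate_theta) && !is.null(config$covariate_r2)
    if (has_cov) {
      dmag <- abs(config$covariate_cor * gz +
                    sqrt(1 - config$covariate_cor^2) * stats::rnorm(k))
      dmag <- pmax(dmag, 1e-3)
      dscale <- sqrt(config$covariate_r2 / sum(dmag^2 * v))
      delta <- sign(gamma) * dscale * dmag
    }

    # Direct effects are defined in the orientation of the exposure-
    # increasing allele (the frame in which the Egger intercept lives);
    # with random allele signs they enter as sign(gamma) * alpha.
    Gamma <- config$theta * gamma + sign(gamma) * alpha
    if (has_cov) Gamma <- Gamma + config$covariate_theta * delta

    se_gamma <- 1 / sqrt(v * config$n_exposure)
    se_Gamma <- sqrt((1 / config$n_cases + 1 / config$n_controls) / v)

    make_stats <- function(true_beta, se, n) {
      est <- stats::rnorm(k, true_beta, se)
      data.frame(rsid = rsid,
                 effect_allele = "A", other_allele = "G",
                 eaf = p, beta = est, se = se,
                 pvalue = 2 * stats::pnorm(-abs(est / se)),
                 n = n, stringsAsFactors = FALSE)
    }
    exposure_stats <- make_stats(gamma, se_gamma, config$n_exposure)
    outcome_stats <- make_stats(Gamma, se_Gamma, config$n_cases + config$n_controls)
    covariate_stats <- NULL
    if (has_cov) {
      se_delta <- 1 / sqrt(v * config$n_covariate)
      covariate_stats <- make_stats(delta, se_delta, config$n_covariate)
    }

    truth <- c(unclass(config),
               list(gamma = gamma, alpha = alpha, delta = delta,
                    Gamma = Gamma, maf = p, invalid = invalid))
    structure(list(exposure_stats = exposure_stats,
                   outcome_stats = outcome_stats,
                   covariate_stats = covariate_stats,
                   truth = truth),
              class = "sim_study_pair")
  })
}

#' Write a simulated study pair to disk
#'
#' Emits the same TSV dialect [read_summary_stats()] reads, plus a YAML
#' side-car with the scalar truth parameters for downstream assertions.
#'
#' @param pair A `sim_study_pair`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulated_pair <- function(pair, dir, prefix = "sim") {
  stopifnot(inherits(pair, "sim_study_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, paste0(prefix, "_exposure.tsv")),
             outcome = file.path(dir, paste0(prefix, "_outcome.tsv")))
  write_summary_stats(pair$exposure_stats, paths[["exposure"]])
  write_summary_stats(pair$outcome_stats, paths[["outcome"]])
  if (!is.null(pair$covariate_stats)) {
    paths[["covariate"]] <- file.path(dir, paste0(prefix, "_covariate.tsv"))
    write_summary_stats(pair$covariate_stats, paths[["covariate"]])
  }
  scalars <- pair$truth[vapply(pair$truth, function(x)
    is.null(x) || (is.atomic(x) && length(x) <= 2), logical(1))]
  paths[["truth"]] <- file.path(dir, paste0(prefix, "_truth.yaml"))
  yaml::write_yaml(scalars, paths[["truth"]])
  invisible(paths)
}

#' Simulate a table of observational study estimates
#'
#' Study log-effects are drawn from
#' \eqn{N(\mu, \tau^2 + se_i^2)} with per-study standard errors uniform on
#' `se_range` — the random-effects model the DerSimonian-Laird pooling
#' assumes.
#'
#' @param k_studies Number of studies (>= 2).
#' @param true_log_or Common true log odds ratio \eqn{\mu}.
#' @param tau2 Between-study variance (>= 0).
#' @param se_range Interval for per-study standard errors.
#' @param seed Random seed.
#' @param outcome_group Label recycled across studies (e.g. `"CAD"`).
#' @param design Study design flag recycled across studies.
#' @return A `data.frame` of study estimates: `label`, `outcome_group`,
#'   `effect` (log scale), `se`, `design`.
#' @export
simulate_observational_studies <- function(k_studies, true_log_or, tau2,
                                           se_range = c(0.1, 0.4), seed,
                                           outcome_group = "CAD",
                                           design = "prospective") {
  if (k_studies < 2) stop_config("k_studies must be >= 2")
  if (!is_scalar_number(tau2) || tau2 < 0) stop_config("tau2 must be >= 0")
  with_seed(seed, {
    se <- stats::runif(k_studies, se_range[1], se_range[2])
    effect <- stats::rnorm(k_studies, true_log_or, sqrt(tau2 + se^2))
    data.frame(label = sprintf("study_%02d", seq_len(k_studies)),
               outcome_group = outcome_group,
               effect = effect, se = se, design = design,
               stringsAsFactors = FALSE)
  })
}
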