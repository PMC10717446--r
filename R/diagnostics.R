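#' Per-SNP variance explained in the exposure
#'
#' Under an additive model, a SNP with effect-allele frequency \eqn{p} and
#' per-allele effect \eqn{\beta} explains
#' \eqn{r^2 = 2\beta^2 p(1-p)/\sigma^2} of the trait variance, with
#' \eqn{\sigma^2} the trait variance on the analysis scale (default 1,
#' the standardized scale; pass `trait_var = K * (1 - K)` for the observed
#' scale of a binary trait with prevalence K).
#'
#' @param beta Per-allele effect(s).
#' @param eaf Effect-allele frequency(ies); SNPs with missing `eaf` get `NA`
#'   with a warning.
#' @param trait_var Trait variance on the analysis scale.
#' @return Numeric vector of variance fractions.
#' @export
snp_r2 <- function(beta, eaf, trait_var = 1) {
  if (any(is.na(eaf))) {
    warning(sum(is.na(eaf)), " SNP(s) with missing eaf: r2 not computed")
  }
  2 * beta^2 * eaf * (1 - eaf) / trait_var
}

#' Instrument-strength F-statistics
#'
#' Cumulative F for `k` instruments jointly explaining `r2_total` of the
#' exposure variance in a sample of size `n`:
#' \deqn{F = \frac{r^2 (n - k - 1)}{k (1 - r^2)}.}
#' When per-SNP `r2` values are supplied, per-SNP statistics
#' \eqn{F_j = r_j^2 (n - 2)/(1 - r_j^2)} are returned alongside. F > 20 is
#' the conventional bar for acceptably strong instruments.
#'
#' @param r2_total Joint variance fraction in (0, 1).
#' @param n Exposure sample size (> k + 1).
#' @param k Instrument count.
#' @param r2_snp Optional vector of per-SNP variance fractions.
#' @return List with `f_cumulative` and (if `r2_snp` given) `f_snp`.
#' @export
f_statistics <- function(r2_total, n, k, r2_snp = NULL) {
  if (!is_scalar_number(r2_total) || r2_total <= 0 || r2_total >= 1) {
    stop_input("r2_total must be in (0, 1)")
  }
  if (n <= k + 1) stop_input("sample size must exceed k + 1")
  out <- list(f_cumulative = r2_total * (n - k - 1) / (k * (1 - r2_total)))
  if (!is.null(r2_snp)) out$f_snp <- r2_snp * (n - 2) / (1 - r2_snp)
  out
}

#' Statistical power of a two-sample MR design with a binary outcome
#'
#' Non-centrality approximation: with case fraction
#' \eqn{K = n_{cases}/N}, instrument strength \eqn{r^2} and detectable odds
#' ratio \eqn{OR},
#' \deqn{power = \Phi\left(|\ln OR| \sqrt{N r^2 K(1-K)} -
#'   z_{1-\alpha/2}\right).}
#' Symmetric in cases/controls; `or_expected = 1` returns `alpha` with a
#' warning (the null boundary).
#'
#' @param n_cases,n_controls Outcome-study counts.
#' @param r2 Variance of the exposure explained by the instruments.
#' @param or_expected Odds ratio to detect (typically from the observational
#'   literature).
#' @param alpha Two-sided significance level (default 0.05).
#' @param n_total_override Optional total outcome sample size replacing
#'   `n_cases + n_controls` (the case fraction is kept).
#' @return Power in \[0, 1\].
#' @export
mr_power_binary <- function(n_cases, n_controls, r2, or_expected,
                            alpha = 0.05, n_total_override = NULL) {
  if (any(c(n_cases, n_controls, r2, or_expected, alpha) <= 0) ||
      r2 >= 1 || alpha >= 1) {
    stop_input("power parameters must be positive with r2 and alpha in (0, 1)")
  }
  if (or_expected == 1) {
    warning("or_expected = 1: power equals the significance level")
    return(alpha)
  }
  n_total <- n_total_override %||% (n_cases + n_controls)
  K <- n_cases / (n_cases + n_controls)
  ncp <- abs(log(or_expected)) * sqrt(n_total * r2 * K * (1 - K))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Instrument diagnostics table
#'
#' Per-SNP variance explained and F alongside the cumulative F and the
#' design's power, assembled as one tidy table.
#'
#' @param instruments Harmonized instrument data frame (exposure side used).
#' @param n_exposure Exposure GWAS sample size.
#' @param power_params Optional list with `n_cases`, `n_controls`,
#'   `or_expected` and optionally `alpha`, forwarded to [mr_power_binary()].
#' @return List with `per_snp` (data frame `rsid`, `r2`, `f`), `r2_total`,
#'   `f_cumulative`, and `power` (or `NA`).
#' @export
instrument_diagnostics <- function(instruments, n_exposure,
                                   power_params = NULL) {
  r2 <- snp_r2(instruments$beta_exposure, instruments$eaf)
  fs <- f_statistics(min(sum(r2, na.rm = TRUE), 1 - 1e-9), n_exposure,
                     nrow(instruments), r2_snp = r2)
  power <- NA_real_
  if (!is.null(power_params)) {
    power <- mr_power_binary(power_params$n_cases, power_params$n_controls,
                             sum(r2, na.rm = TRUE), power_params$or_expected,
                             power_params$alpha %||% 0.05)
  }
  list(per_snp = data.frame(rsid = instruments$rsid, r2 = r2, f = fs$f_snp,
                            stringsAsFactors = FALSE),
       r2_total = sum(r2, na.rm = TRUE),
       f_cumulative = fs$f_cumulative,
       power = power)
}
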