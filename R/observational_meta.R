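#' Read a table of observational study estimates
#'
#' Expects a TSV/CSV with columns `label`, `outcome_group`, `estimate`
#' (reported OR/HR/RR), `ci_low`, `ci_high`, and optionally `design`.
#' Effects are taken to the log scale and the standard error recovered from
#' the 95% interval as \eqn{(\ln u - \ln l)/(2 \times 1.96)}. Ratio
#' intervals are symmetric on the log scale up to rounding; inputs whose log
#' midpoint deviates from the log estimate by more than `sym_tol` times the
#' half-width are rejected with a clear message.
#'
#' @param path Path to the study table.
#' @param sym_tol Relative asymmetry tolerance (default 0.1).
#' @return A `data.frame` with `label`, `outcome_group`, `effect` (log
#'   scale), `se`, `design`.
#' @export
read_study_table <- function(path, sym_tol = 0.1) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  needed <- c("label", "outcome_group", "estimate", "ci_low", "ci_high")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L) {
    stop_config("study table is missing column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  if (any(raw$ci_high <= raw$ci_low) || any(raw$estimate <= 0) ||
      any(raw$ci_low <= 0)) {
    stop_input("study estimates and CI bounds must be positive with upper > lower")
  }
  effect <- log(raw$estimate)
  half <- (log(raw$ci_high) - log(raw$ci_low)) / 2
  mid <- (log(raw$ci_high) + log(raw$ci_low)) / 2
  bad <- abs(mid - effect) > sym_tol * half
  if (any(bad)) {
    stop_input("asymmetric confidence interval(s) on the log scale for: ",
               paste(raw$label[bad], collapse = ", "),
               "; check the reported estimate and bounds")
  }
  data.frame(label = raw$label, outcome_group = raw$outcome_group,
             effect = effect, se = half / stats::qnorm(0.975),
             design = raw$design %||% NA_character_,
             stringsAsFactors = FALSE)
}

#' DerSimonian-Laird random-effects meta-analysis of study estimates
#'
#' Pools study log-effects with the moment-based between-study variance
#' estimator (see [ivw_random()] for the algebra) and reports the pooled
#' effect with Q, I-squared and tau-squared.
#'
#' @param studies Data frame with `effect` and `se` columns (>= 2 rows),
#'   e.g. from [read_study_table()].
#' @return An `mr_estimate` with method `"dl_random"`.
#' @export
dl_meta <- function(studies) {
  if (nrow(studies) < 2) stop_input("meta-analysis needs at least 2 studies")
  dl_pool(studies$effect, studies$se, "dl_random")
}

#' Fixed-effect meta-analysis of study estimates
#'
#' Inverse-variance pooling with the between-study variance forced to zero;
#' the degenerate limit of [dl_meta()].
#'
#' @inheritParams dl_meta
#' @return An `mr_estimate` with method `"fixed"`.
#' @export
fe_meta <- function(studies) {
  if (nrow(studies) < 2) stop_input("meta-analysis needs at least 2 studies")
  w <- 1 / studies$se^2
  theta <- sum(w * studies$effect) / sum(w)
  q <- sum(w * (studies$effect - theta)^2)
  new_mr_estimate("fixed", theta, 1 / sqrt(sum(w)), nrow(studies), q_stat = q)
}

#' Funnel-plot asymmetry (Egger) test
#'
#' Weighted linear regression of the study effects on their standard errors
#' with inverse-variance weights; a coefficient away from zero indicates
#' small-study effects consistent with publication bias. The algebraically
#' equivalent precision-regression form (effect/se on 1/se) is available via
#' `form = "precision"`.
#'
#' @param studies Data frame with `effect` and `se` (>= 3 rows).
#' @param form `"direct"` (default) or `"precision"`.
#' @return List with `coef`, `se`, `ci_low`, `ci_high`, `pvalue`.
#' @export
egger_funnel_test <- function(studies, form = c("direct", "precision")) {
  form <- match.arg(form)
  if (nrow(studies) < 3) stop_input("funnel test needs at least 3 studies")
  if (form == "direct") {
    fit <- stats::lm(effect ~ se, data = studies, weights = 1 / studies$se^2)
    coef_name <- "se"
  } else {
    prec <- 1 / studies$se
    snd <- studies$effect / studies$se
    fit <- stats::lm(snd ~ prec)
    coef_name <- "(Intercept)"
  }
  sm <- summary(fit)$coefficients
  est <- sm[coef_name, "Estimate"]
  se <- sm[coef_name, "Std. Error"]
  list(coef = unname(est), se = unname(se),
       ci_low = unname(est - stats::qnorm(0.975) * se),
       ci_high = unname(est + stats::qnorm(0.975) * se),
       pvalue = unname(2 * stats::pnorm(-abs(est / se))))
}

#' Between-group heterogeneity test for two pooled estimates
#'
#' Cochran's Q comparing two estimates on the log scale (e.g. the pooled
#' observational estimate versus the population-scale causal estimate):
#' inverse-variance weighted mean, \eqn{Q = \sum_i w_i(\theta_i -
#' \bar\theta)^2}, referred to chi-square with 1 degree of freedom.
#'
#' @param estimate_a,estimate_b `mr_estimate` objects or lists with `theta`
#'   and `se`.
#' @return List with `q`, `pvalue`.
#' @export
between_group_q <- function(estimate_a, estimate_b) {
  th <- c(estimate_a$theta, estimate_b$theta)
  se <- c(estimate_a$se, estimate_b$se)
  w <- 1 / se^2
  mu <- sum(w * th) / sum(w)
  q <- sum(w * (th - mu)^2)
  list(q = q, pvalue = stats::pchisq(q, df = 1, lower.tail = FALSE))
}

#' Leave-one-out re-pooling of a meta-analysis
#'
#' Re-runs [dl_meta()] omitting each study in turn, to check whether any
#' single (e.g. largest-weight) study drives the pooled effect.
#'
#' @inheritParams dl_meta
#' @return Data frame with one row per omitted study: `omitted`, `theta`,
#'   `se`, `ci_low`, `ci_high`.
#' @export
leave_one_out_meta <- function(studies) {
  if (nrow(studies) < 3) stop_input("leave-one-out needs at least 3 studies")
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    est <- dl_meta(studies[-i, , drop = FALSE])
    data.frame(omitted = studies$label[i], theta = est$theta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tidy forest/funnel plot data for external plotting
#'
#' @param studies Data frame from [read_study_table()].
#' @param pooled Optional `mr_estimate` appended as a summary row.
#' @return Data frame with `label`, `outcome_group`, `effect`, `se`,
#'   `or`, `or_low`, `or_high`, `is_pooled`.
#' @export
forest_data <- function(studies, pooled = NULL) {
  z <- stats::qnorm(0.975)
  out <- data.frame(label = studies$label,
                    outcome_group = studies$outcome_group,
                    effect = studies$effect, se = studies$se,
                    or = exp(studies$effect),
                    or_low = exp(studies$effect - z * studies$se),
                    or_high = exp(studies$effect + z * studies$se),
                    is_pooled = FALSE, stringsAsFactors = FALSE)
  if (!is.null(pooled)) {
    out <- rbind(out, data.frame(
      label = paste0("pooled (", pooled$method, ")"),
      outcome_group = studies$outcome_group[1],
      effect = pooled$theta, se = pooled$se, or = exp(pooled$theta),
      or_low = exp(pooled$ci_low), or_high = exp(pooled$ci_high),
      is_pooled = TRUE, stringsAsFactors = FALSE))
  }
  out
}
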