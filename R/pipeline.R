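#' Build a validated pipeline configuration
#'
#' One configuration drives one exposure-outcome analysis: harmonization,
#' instrument selection, the MR estimator suite, diagnostics, the
#' population-scale transformation, and (optionally) the observational
#' meta-analysis arm for the same outcome.
#'
#' @param exposure_path,outcome_path Paths to summary-statistic tables.
#' @param covariate_path Optional path to secondary-exposure (e.g. tobacco)
#'   summary statistics; enables multivariable MR.
#' @param studies_path Optional path to an observational study table;
#'   enables the meta-analysis arm and the causal-vs-observational
#'   comparison.
#' @param outcome_label Label used in outputs (e.g. `"CAD"`); also selects
#'   the matching `outcome_group` rows of the study table.
#' @param pvalue_threshold Instrument significance cutoff.
#' @param discordant_rsids rsIDs excluded before thresholding.
#' @param remove_palindromic Apply [filter_palindromic()]?
#' @param maf_window Palindrome ambiguity window.
#' @param n_boot Bootstrap resamples for Egger / weighted median / MVMR.
#' @param seed Seed governing every stochastic step.
#' @param simex List with `lambdas`, `n_sim`, `n_boot` for [egger_simex()];
#'   `NULL` skips SIMEX.
#' @param transform Optional [transform_params()] (or plain list of its
#'   arguments) for the population-scale conversion.
#' @param column_map Column mapping for the summary-statistic files.
#' @param out_dir Optional output directory for the report bundle.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(exposure_path, outcome_path,
                            covariate_path = NULL, studies_path = NULL,
                            outcome_label = "outcome",
                            pvalue_threshold = 5e-5,
                            discordant_rsids = character(),
                            remove_palindromic = FALSE, maf_window = 0.08,
                            n_boot = 10000, seed = 1,
                            simex = list(lambdas = seq(0, 2, 0.5),
                                         n_sim = 1000, n_boot = 100),
                            transform = NULL,
                            column_map = default_column_map(),
                            out_dir = NULL) {
  for (p in c(exposure_path, outcome_path, covariate_path, studies_path)) {
    if (!is.null(p) && !file.exists(p)) stop_config("file not found: ", p)
  }
  if (is.null(seed)) stop_config("seed must be set")
  if (!is.null(transform) && !inherits(transform, "transform_params")) {
    transform <- do.call(transform_params, transform)
  }
  structure(list(exposure_path = exposure_path, outcome_path = outcome_path,
                 covariate_path = covariate_path, studies_path = studies_path,
                 outcome_label = outcome_label,
                 pvalue_threshold = pvalue_threshold,
                 discordant_rsids = discordant_rsids,
                 remove_palindromic = remove_palindromic,
                 maf_window = maf_window,
                 n_boot = n_boot, seed = as.integer(seed), simex = simex,
                 transform = transform, column_map = column_map,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$transform)) cfg$transform <- do.call(transform_params, cfg$transform)
  if (!is.null(cfg$column_map)) cfg$column_map <- unlist(cfg$column_map)
  do.call(pipeline_config, cfg)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: read and validate summary statistics; instrument
#' selection (exclusion list + significance threshold); harmonization of
#' exposure, outcome and optional covariate; optional palindrome filtering;
#' Wald ratios; fixed- and random-effects IVW; MR-Egger (+ optional SIMEX);
#' weighted median; Steiger directionality; multivariable MR when a
#' covariate is present; instrument diagnostics; the population-scale
#' transformation when configured; and, when a study table is configured,
#' the observational meta-analysis arm with funnel test, leave-one-out and
#' the causal-vs-observational comparison. SNP counts are logged after every
#' filtering step. Two runs with an identical configuration produce
#' identical reports.
#'
#' @param config A [pipeline_config()].
#' @return An `mr_report` list: `counts`, `exclusions`, `instruments`,
#'   `wald`, `estimates` (named list of `mr_estimate`), `steiger`,
#'   `diagnostics`, `meta`, `comparison`, `log`, `config`. Written to
#'   `config$out_dir` when set (see [write_report()]).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  exposure <- stage("read_exposure",
                    read_summary_stats(config$exposure_path, config$column_map))
  outcome <- stage("read_outcome",
                   read_summary_stats(config$outcome_path, config$column_map))
  covariate <- NULL
  if (!is.null(config$covariate_path)) {
    covariate <- stage("read_covariate",
                       read_summary_stats(config$covariate_path, config$column_map))
  }
  counts <- list(exposure_snps = nrow(exposure))
  note("exposure SNPs read: ", nrow(exposure))

  selected <- stage("select_instruments",
                    select_instruments(exposure, config$pvalue_threshold,
                                       config$discordant_rsids))
  counts$after_exclusion_list <- nrow(exposure) - attr(selected, "n_excluded")
  counts$after_threshold <- nrow(selected)
  note("after exclusion list: ", counts$after_exclusion_list,
       "; after p < ", format(config$pvalue_threshold), ": ", nrow(selected))

  harm <- stage("harmonize", harmonize_pair(selected, outcome, covariate))
  excl <- attr(harm, "exclusions")
  counts$harmonized <- nrow(harm)
  note("harmonized instruments: ", nrow(harm),
       if (nrow(excl) > 0) paste0(" (excluded: ",
                                  paste(excl$rsid, collapse = ", "), ")") else "")

  if (isTRUE(config$remove_palindromic)) {
    harm <- stage("filter_palindromic",
                  filter_palindromic(harm, config$maf_window))
    counts$after_palindrome_filter <- nrow(harm)
    note("after palindrome filter: ", nrow(harm))
  }

  wald <- stage("wald_ratio", wald_ratio(harm))
  estimates <- list()
  estimates$ivw_fixed <- stage("ivw_fixed", ivw_fixed(wald))
  estimates$ivw_random <- stage("ivw_random", ivw_random(wald))
  estimates$egger <- stage("egger",
                           mr_egger(harm, n_boot = config$n_boot,
                                    seed = config$seed))
  if (!is.null(config$simex)) {
    estimates$egger_simex <- stage("egger_simex", egger_simex(
      harm, lambdas = config$simex$lambdas %||% seq(0, 2, 0.5),
      n_sim = config$simex$n_sim %||% 1000,
      seed = config$seed, n_boot = config$simex$n_boot %||% 100))
  }
  estimates$weighted_median <- stage("weighted_median",
                                     weighted_median(wald,
                                                     n_boot = config$n_boot,
                                                     seed = config$seed))
  if (!is.null(covariate)) {
    estimates$mvmr <- stage("mvmr",
                            mr_mvmr(harm, n_boot = config$n_boot,
                                    seed = config$seed))
    note("MVMR SNPs without covariate effect, dropped: ",
         attr(estimates$mvmr, "n_dropped_covariate"))
  }

  steiger <- stage("steiger", steiger_filter(harm))
  note(sprintf("Steiger: %d/%d SNPs with correct direction, overall p = %.3g",
               sum(steiger$correct_direction), nrow(steiger),
               attr(steiger, "overall_p")))

  diagnostics <- stage("diagnostics", instrument_diagnostics(
    harm, n_exposure = stats::median(harm$n_exposure)))

  if (!is.null(config$transform)) {
    for (m in c("ivw_fixed", "ivw_random", "mvmr")) {
      if (!is.null(estimates[[m]])) {
        estimates[[paste0(m, "_population")]] <-
          stage("transform", per_log_unit_to_ever_never(estimates[[m]],
                                                        config$transform))
      }
    }
  }

  meta <- NULL
  if (!is.null(config$studies_path)) {
    studies <- stage("read_studies", read_study_table(config$studies_path))
    grp <- studies[studies$outcome_group == config$outcome_label, , drop = FALSE]
    if (nrow(grp) >= 2) {
      meta <- list(studies = grp,
                   pooled = stage("dl_meta", dl_meta(grp)),
                   funnel = if (nrow(studies) >= 3)
                     stage("funnel", egger_funnel_test(studies)) else NULL,
                   leave_one_out = if (nrow(grp) >= 3)
                     stage("leave_one_out", leave_one_out_meta(grp)) else NULL,
                   pooled_all = if (nrow(studies) >= 2)
                     stage("dl_meta_all", dl_meta(studies)) else NULL)
      note(sprintf("observational pooled OR (%s): %.3f (%.3f-%.3f), I2 = %.1f%%",
                   config$outcome_label, exp(meta$pooled$theta),
                   exp(meta$pooled$ci_low), exp(meta$pooled$ci_high),
                   meta$pooled$i2))
    } else {
      note("fewer than 2 studies for outcome group ", config$outcome_label,
           "; meta-analysis arm skipped")
    }
  }

  report <- structure(list(outcome_label = config$outcome_label,
                           counts = counts, exclusions = excl,
                           instruments = harm, wald = wald,
                           estimates = estimates, steiger = steiger,
                           diagnostics = diagnostics, meta = meta,
                           comparison = NULL, log = log_lines,
                           config = config),
                      class = "mr_report")
  if (!is.null(meta)) report$comparison <- compare_estimates(report)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Compare the observational and causal arms of a report
#'
#' Builds a side-by-side table of the pooled observational estimate and each
#' population-scale MR estimate for the same outcome, with the between-group
#' heterogeneity Q test.
#'
#' @param report An `mr_report` containing both arms.
#' @return Data frame with one row per causal method: the two ORs with CIs
#'   and the between-group `q` and `pvalue`.
#' @export
compare_estimates <- function(report) {
  if (is.null(report$meta) || is.null(report$meta$pooled)) {
    stop_input("report lacks the observational meta-analysis arm")
  }
  pop <- report$estimates[grepl("_population$", names(report$estimates))]
  if (length(pop) == 0) {
    stop_input("report lacks population-scale causal estimates ",
               "(no transform configured)")
  }
  obs <- report$meta$pooled
  rows <- lapply(names(pop), function(m) {
    est <- pop[[m]]
    bg <- between_group_q(obs, est)
    data.frame(outcome = report$outcome_label, causal_method = m,
               causal_or = exp(est$theta),
               causal_or_low = exp(est$ci_low),
               causal_or_high = exp(est$ci_high),
               observational_or = exp(obs$theta),
               observational_or_low = exp(obs$ci_low),
               observational_or_high = exp(obs$ci_high),
               q = bg$q, pvalue = bg$pvalue, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a report bundle to disk
#'
#' Emits per-stage TSVs (harmonized instruments, Wald ratios, Steiger,
#' per-method estimates, per-SNP diagnostics, comparison), a consolidated
#' JSON report and a plain-text log under `dir`.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, report$outcome_label)
  write_harmonized(report$instruments, paste0(pre, "_instruments.tsv"))
  utils::write.table(report$wald, paste0(pre, "_wald.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_steiger(report$steiger, paste0(pre, "_steiger.tsv"))
  write_mr_estimates(report$estimates, tsv_path = paste0(pre, "_estimates.tsv"))
  utils::write.table(report$diagnostics$per_snp,
                     paste0(pre, "_diagnostics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$comparison)) {
    utils::write.table(report$comparison, paste0(pre, "_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeLines(report$log, paste0(pre, "_log.txt"))

  json <- list(
    outcome = report$outcome_label,
    counts = report$counts,
    estimates = mr_estimates_table(report$estimates),
    steiger_overall = list(z = attr(report$steiger, "overall_z"),
                           p = attr(report$steiger, "overall_p"),
                           correct_direction = attr(report$steiger,
                                                    "overall_direction")),
    diagnostics = list(r2_total = report$diagnostics$r2_total,
                       f_cumulative = report$diagnostics$f_cumulative,
                       power = report$diagnostics$power),
    meta = if (!is.null(report$meta)) list(
      pooled = as.data.frame(report$meta$pooled),
      pooled_all = if (!is.null(report$meta$pooled_all))
        as.data.frame(report$meta$pooled_all) else NULL,
      funnel = report$meta$funnel) else NULL,
    comparison = report$comparison
  )
  jsonlite::write_json(json, paste0(pre, "_report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(dir)
}
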