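#' Default column mapping for GWAS summary-statistic tables
#'
#' Maps the canonical field names used throughout the package to the column
#' names found in an input file. Override individual entries to read files
#' with different headers.
#'
#' @return Named character vector: canonical name -> column name in the file.
#' @export
default_column_map <- function() {
  c(rsid = "rsid", effect_allele = "effect_allele",
    other_allele = "other_allele", eaf = "eaf",
    beta = "beta", se = "se", pvalue = "pvalue", n = "n")
}

VALID_ALLELES <- c("A", "C", "G", "T")
ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Read and validate a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated table with one row per SNP and returns a
#' standardized data frame of per-SNP association records (rsid, alleles,
#' effect-allele frequency, beta on the log-odds scale, its standard error,
#' p-value, and sample size). Alleles are upper-cased. Rows violating the
#' record invariants (non-ACGT or identical alleles, `se <= 0`, p-value
#' outside (0, 1], `eaf` outside (0, 1), non-positive `n`) are dropped; the
#' number dropped is reported via a message and attached as attribute
#' `n_dropped`.
#'
#' @param path Path to the file. The delimiter is sniffed from the header
#'   line (tab preferred, else comma) unless `sep` is given.
#' @param column_map Named character vector as from [default_column_map()].
#'   `eaf` and `n` may be absent from the file; all other columns are
#'   required.
#' @param sep Optional field separator override.
#' @return A `data.frame` with columns `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, attribute
#'   `n_dropped`.
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               sep = NULL) {
  if (!file.exists(path)) stop_input("summary-statistics file not found: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stop_input("empty summary-statistics file: ", path)
  }
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (nrow(raw) == 0L) stop_input("summary-statistics file has no data rows: ", path)

  map <- default_column_map()
  map[names(column_map)] <- column_map
  required <- setdiff(names(map), c("eaf", "n"))
  missing_cols <- required[!(map[required] %in% names(raw))]
  if (length(missing_cols) > 0L) {
    stop_config("required column(s) not found in ", path, ": ",
                paste0(map[missing_cols], " (", missing_cols, ")", collapse = ", "))
  }

  get_col <- function(field, default = NA_real_) {
    if (map[[field]] %in% names(raw)) raw[[map[[field]]]] else rep(default, nrow(raw))
  }
  out <- data.frame(
    rsid = as.character(get_col("rsid")),
    effect_allele = toupper(trimws(as.character(get_col("effect_allele")))),
    other_allele = toupper(trimws(as.character(get_col("other_allele")))),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE
  )
  # carry chromosome/position through if present, never used for matching
  for (extra in c("chr", "pos")) {
    if (extra %in% names(raw)) out[[extra]] <- raw[[extra]]
  }

  keep <- out$effect_allele %in% VALID_ALLELES &
    out$other_allele %in% VALID_ALLELES &
    out$effect_allele != out$other_allele &
    is.finite(out$beta) &
    is.finite(out$se) & out$se > 0 &
    is.finite(out$pvalue) & out$pvalue > 0 & out$pvalue <= 1 &
    (is.na(out$eaf) | (out$eaf > 0 & out$eaf < 1)) &
    (is.na(out$n) | out$n > 0)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " row(s) dropped while reading ", basename(path),
            " (invalid alleles, se, p-value, eaf or n)")
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a summary-statistics table as TSV
#'
#' @param stats Data frame as returned by [read_summary_stats()] or
#'   [simulate_two_sample()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome (and optional covariate) summary statistics
#'
#' Intersects the datasets on rsID and aligns every association to the
#' exposure's effect allele. When the outcome reports the same allele pair in
#' the opposite orientation (directly or after strand complement), the
#' outcome beta sign is flipped and its effect-allele frequency complemented.
#' SNPs whose allele pairs cannot be reconciled even after strand complement
#' are excluded with reason `"allele mismatch"`; SNPs absent from the outcome
#' dataset are excluded with reason `"absent from outcome"`. Exclusions are
#' reported in the `exclusions` attribute, never silently.
#'
#' A SNP missing from the covariate dataset keeps `NA` covariate effects (it
#' is dropped, with a count, only inside [mr_mvmr()]).
#'
#' @param exposure,outcome,covariate Data frames of per-SNP association
#'   records ([read_summary_stats()] format); `covariate` optional.
#' @return A `data.frame` of harmonized instruments with columns `rsid`,
#'   `effect_allele`, `other_allele`, `eaf` (exposure-side frequency of the
#'   harmonized effect allele), `beta_exposure`, `se_exposure`,
#'   `pvalue_exposure`, `n_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `n_outcome`, `beta_covariate`, `se_covariate`,
#'   `is_palindromic`, `gw_significant` (exposure p < 5e-8). Attribute
#'   `exclusions`: data frame of excluded rsids and reasons.
#' @export
harmonize_pair <- function(exposure, outcome, covariate = NULL) {
  exp_idx <- match(exposure$rsid, outcome$rsid)
  exclusions <- data.frame(rsid = character(), reason = character(),
                           stringsAsFactors = FALSE)

  absent <- is.na(exp_idx)
  if (any(absent)) {
    exclusions <- rbind(exclusions, data.frame(
      rsid = exposure$rsid[absent], reason = "absent from outcome",
      stringsAsFactors = FALSE))
  }

  ex <- exposure[!absent, , drop = FALSE]
  ou <- outcome[exp_idx[!absent], , drop = FALSE]

  align <- align_alleles(ex$effect_allele, ex$other_allele,
                         ou$effect_allele, ou$other_allele)
  mismatch <- is.na(align)
  if (any(mismatch)) {
    exclusions <- rbind(exclusions, data.frame(
      rsid = ex$rsid[mismatch], reason = "allele mismatch",
      stringsAsFactors = FALSE))
    ex <- ex[!mismatch, , drop = FALSE]
    ou <- ou[!mismatch, , drop = FALSE]
    align <- align[!mismatch]
  }

  flip <- align == -1
  beta_outcome <- ifelse(flip, -ou$beta, ou$beta)
  eaf_outcome <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  h <- data.frame(
    rsid = ex$rsid,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    eaf = ex$eaf,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    pvalue_exposure = ex$pvalue,
    n_exposure = ex$n,
    beta_outcome = beta_outcome,
    se_outcome = ou$se,
    eaf_outcome = eaf_outcome,
    n_outcome = ou$n,
    beta_covariate = NA_real_,
    se_covariate = NA_real_,
    is_palindromic = is_palindromic_pair(ex$effect_allele, ex$other_allele),
    gw_significant = ex$pvalue < 5e-8,
    stringsAsFactors = FALSE
  )

  if (!is.null(covariate)) {
    cov_idx <- match(h$rsid, covariate$rsid)
    present <- !is.na(cov_idx)
    cv <- covariate[cov_idx[present], , drop = FALSE]
    calign <- align_alleles(h$effect_allele[present], h$other_allele[present],
                            cv$effect_allele, cv$other_allele)
    ok <- !is.na(calign)
    rows <- which(present)[ok]
    h$beta_covariate[rows] <- ifelse(calign[ok] == -1, -cv$beta[ok], cv$beta[ok])
    h$se_covariate[rows] <- cv$se[ok]
  }

  rownames(h) <- NULL
  attr(h, "exclusions") <- exclusions
  h
}

# Orientation of allele pair (b1, b2) relative to (a1, a2):
# +1 same orientation (possibly after strand complement), -1 flipped,
# NA irreconcilable. Vectorized.
align_alleles <- function(a1, a2, b1, b2) {
  c1 <- unname(ALLELE_COMPLEMENT[b1])
  c2 <- unname(ALLELE_COMPLEMENT[b2])
  out <- rep(NA_real_, length(a1))
  out[b1 == a1 & b2 == a2] <- 1
  out[is.na(out) & b1 == a2 & b2 == a1] <- -1
  out[is.na(out) & c1 == a1 & c2 == a2] <- 1
  out[is.na(out) & c1 == a2 & c2 == a1] <- -1
  out
}

#' Remove strand-ambiguous palindromic SNPs with intermediate allele frequency
#'
#' Palindromic (A/T or C/G) SNPs cannot be strand-resolved from the allele
#' labels alone; when their effect-allele frequency is close to 50% the
#' frequency cannot resolve them either, so they are removed. A palindromic
#' SNP with missing `eaf` is treated as ambiguous and removed.
#'
#' @param instruments Harmonized instrument data frame.
#' @param maf_window Half-width of the ambiguity window around 0.5
#'   (default 0.08: removed when `|eaf - 0.5| < 0.08`).
#' @return Filtered data frame; attribute `removed` holds the removed subset.
#' @export
filter_palindromic <- function(instruments, maf_window = 0.08) {
  ambiguous <- instruments$is_palindromic &
    (is.na(instruments$eaf) | abs(instruments$eaf - 0.5) < maf_window)
  out <- instruments[!ambiguous, , drop = FALSE]
  if (nrow(out) == 0L) warning("all instruments removed as ambiguous palindromes")
  rownames(out) <- NULL
  attr(out, "removed") <- instruments$rsid[ambiguous]
  out
}

#' Select instruments by exclusion list and exposure significance threshold
#'
#' First removes explicitly excluded rsIDs (e.g. variants with discordant
#' direction of effect across the contributing exposure GWAS sources), then
#' keeps SNPs whose exposure p-value is below the threshold. The
#' `gw_significant` flag marks the subset below the conventional genome-wide
#' threshold 5e-8.
#'
#' @param instruments Harmonized instrument data frame (or a raw exposure
#'   table with a `pvalue` column).
#' @param pvalue_threshold Significance cutoff in (0, 1].
#' @param discordant_rsids Character vector of rsIDs to exclude.
#' @return Filtered data frame; attributes `n_excluded` (by list) and
#'   `n_below_threshold` record the step counts.
#' @export
select_instruments <- function(instruments, pvalue_threshold = 5e-5,
                               discordant_rsids = character()) {
  if (!is_scalar_number(pvalue_threshold) ||
      pvalue_threshold <= 0 || pvalue_threshold > 1) {
    stop_config("pvalue_threshold must be in (0, 1], got ", pvalue_threshold)
  }
  pcol <- if ("pvalue_exposure" %in% names(instruments)) "pvalue_exposure" else "pvalue"
  keep_list <- !(instruments$rsid %in% discordant_rsids)
  out <- instruments[keep_list, , drop = FALSE]
  keep_p <- out[[pcol]] < pvalue_threshold
  res <- out[keep_p, , drop = FALSE]
  res$gw_significant <- res[[pcol]] < 5e-8
  rownames(res) <- NULL
  attr(res, "n_excluded") <- sum(!keep_list)
  attr(res, "n_below_threshold") <- nrow(res)
  res
}

#' Write harmonized instruments as TSV
#'
#' Columns are written in the fixed order of the harmonized schema.
#'
#' @param instruments Harmonized instrument data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(instruments, path) {
  cols <- c("rsid", "effect_allele", "other_allele", "eaf",
            "beta_exposure", "se_exposure", "pvalue_exposure", "n_exposure",
            "beta_outcome", "se_outcome", "eaf_outcome", "n_outcome",
            "beta_covariate", "se_covariate", "is_palindromic", "gw_significant")
  cols <- intersect(cols, names(instruments))
  utils::write.table(instruments[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
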