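test_that("reading validates rows, normalizes alleles, and round-trips", {
  pair <- simulate_two_sample(simulation_config(seed = 7))
  tab <- pair$exposure_stats
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(tab, f)
  got <- read_summary_stats(f)
  expect_equal(nrow(got), 64)
  expect_equal(attr(got, "n_dropped"), 0)
  expect_equal(got$beta, tab$beta)

  # lower-case alleles are accepted and upper-cased on read
  tab2 <- tab
  tab2$effect_allele <- tolower(tab2$effect_allele)
  write_summary_stats(tab2, f)
  got2 <- read_summary_stats(f)
  expect_equal(got2$effect_allele, tab$effect_allele)

  # invariant-violating rows are dropped and counted
  tab3 <- tab
  tab3$se[5] <- 0
  tab3$pvalue[9] <- 0
  write_summary_stats(tab3, f)
  expect_message(got3 <- read_summary_stats(f), "dropped")
  expect_equal(nrow(got3), 62)
  expect_equal(attr(got3, "n_dropped"), 2)
})

test_that("missing columns and empty files raise clear errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rsid\tbeta\nrs1\t0.1", f)
  expect_error(read_summary_stats(f), "required column")
  writeLines("", f)
  expect_error(read_summary_stats(f), "empty")
  # custom column mapping resolves renamed headers
  writeLines(c("SNP\tA1\tA2\tfreq\tb\tstderr\tp\tN",
               "rs1\tA\tG\t0.2\t0.1\t0.02\t1e-6\t10000"), f)
  got <- read_summary_stats(f, column_map = c(
    rsid = "SNP", effect_allele = "A1", other_allele = "A2", eaf = "freq",
    beta = "b", se = "stderr", pvalue = "p", n = "N"))
  expect_equal(got$beta, 0.1)
})

test_that("harmonization flips alleles, complements strand, reports exclusions", {
  ex <- mini_assoc(c("rs1", "rs2", "rs3", "rs4", "rs5"),
                   c("A", "A", "A", "A", "A"), c("G", "G", "T", "G", "G"),
                   beta = c(0.10, 0.10, 0.10, 0.10, 0.10), se = 0.02)
  ou <- mini_assoc(c("rs1", "rs2", "rs3", "rs5"),
                   c("G", "T", "A", "C"), c("A", "C", "T", "A"),
                   beta = c(0.05, 0.04, 0.03, 0.02), se = 0.01)
  h <- harmonize_pair(ex, ou)
  expect_equal(h$rsid, c("rs1", "rs2", "rs3"))
  # rs1: outcome G/A vs exposure A/G -> sign flip
  expect_equal(h$beta_outcome[h$rsid == "rs1"], -0.05)
  # rs2: outcome T/C is strand complement of A/G, same orientation
  expect_equal(h$beta_outcome[h$rsid == "rs2"], 0.04)
  # rs3: A/T palindrome
  expect_true(h$is_palindromic[h$rsid == "rs3"])
  expect_false(any(h$is_palindromic[h$rsid != "rs3"]))
  excl <- attr(h, "exclusions")
  expect_setequal(excl$reason[excl$rsid == "rs4"], "absent from outcome")
  expect_setequal(excl$reason[excl$rsid == "rs5"], "allele mismatch")
})

test_that("harmonization is involutive and conserves effect magnitude", {
  pair <- make_cannabis_like_pair(seed = 99)
  self <- harmonize_pair(pair$exposure, pair$exposure)
  expect_equal(self$beta_outcome, self$beta_exposure)
  expect_equal(nrow(self), nrow(pair$exposure))

  h <- harmonize_pair(pair$exposure, pair$outcome)
  m <- match(h$rsid, pair$outcome$rsid)
  expect_equal(abs(h$beta_outcome), abs(pair$outcome$beta[m]))
  expect_setequal(c(h$rsid, attr(h, "exclusions")$rsid), pair$exposure$rsid)
  expect_setequal(intersect(pair$exposure$rsid, pair$outcome$rsid), h$rsid)
})

test_that("palindrome filtering removes only ambiguous palindromic SNPs", {
  h <- data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
                  effect_allele = c("A", "A", "C", "A"),
                  other_allele = c("T", "T", "A", "T"),
                  eaf = c(0.50, 0.10, 0.50, NA),
                  is_palindromic = c(TRUE, TRUE, FALSE, TRUE),
                  stringsAsFactors = FALSE)
  out <- filter_palindromic(h, maf_window = 0.08)
  expect_setequal(out$rsid, c("rs2", "rs3"))       # A/T at 0.5 and NA removed
  expect_setequal(attr(out, "removed"), c("rs1", "rs4"))
})

test_that("instrument selection reproduces the filtering-step accounting", {
  pair <- make_cannabis_like_pair()
  # 69 -> 65 after discordant exclusion -> 64 below 5e-5, of which 5 gw-sig
  sel <- select_instruments(pair$exposure, 5e-5, pair$discordant)
  expect_equal(attr(sel, "n_excluded"), 4)
  expect_equal(nrow(sel), 64)
  expect_equal(sum(sel$gw_significant), 5)
  # strict threshold keeps only the genome-wide significant subset
  strict <- select_instruments(pair$exposure, 5e-8, pair$discordant)
  expect_equal(nrow(strict), 5)
  # identity case
  ident <- select_instruments(pair$exposure, 1.0)
  expect_equal(nrow(ident), nrow(pair$exposure))
  expect_error(select_instruments(pair$exposure, 0), "threshold")
  # harmonizing the 64 against an outcome lacking one SNP leaves 63
  h <- harmonize_pair(sel, pair$outcome)
  expect_equal(nrow(h), 63)
  expect_equal(attr(h, "exclusions")$rsid, "rs80144387")
})
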