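make_study_file <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("study tables recover log effects and SEs from reported CIs", {
  df <- data.frame(label = c("s1", "s2"), outcome_group = "CAD",
                   estimate = c(1.5, 0.8),
                   ci_low = c(1.5 * exp(-1.96 * 0.2), 0.8 * exp(-1.96 * 0.1)),
                   ci_high = c(1.5 * exp(1.96 * 0.2), 0.8 * exp(1.96 * 0.1)),
                   design = "prospective")
  st <- read_study_table(make_study_file(df))
  expect_equal(st$effect, log(c(1.5, 0.8)))
  expect_equal(st$se, c(0.2, 0.1), tolerance = 1e-4)

  # asymmetric interval on the log scale is rejected with the study named
  bad <- df
  bad$ci_high[1] <- 4.0
  expect_error(read_study_table(make_study_file(bad)), "asymmetric.*s1")
  # missing columns are a configuration error
  expect_error(read_study_table(make_study_file(df[, -3])), "missing column")
})

test_that("DL meta-analysis matches metafor on random study tables", {
  skip_if_not_installed("metafor")
  for (s in 1:5) {
    st <- simulate_observational_studies(4 + 2 * s, 0.2, 0.04,
                                         se_range = c(0.08, 0.4), seed = s)
    ours <- dl_meta(st)
    ref <- metafor::rma(yi = st$effect, sei = st$se, method = "DL")
    expect_equal(ours$theta, unname(ref$beta[1]), tolerance = 1e-10)
    expect_equal(ours$se, ref$se, tolerance = 1e-10)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$i2, ref$I2, tolerance = 1e-6)
    expect_equal(ours$q_stat, ref$QE, tolerance = 1e-10)
  }
})

test_that("meta-analysis limits: homogeneity, convex hull, fixed-effect nesting", {
  two <- data.frame(label = c("a", "b"), effect = c(0.3, 0.3), se = c(0.1, 0.1))
  pool <- dl_meta(two)
  expect_equal(pool$theta, 0.3)
  expect_equal(pool$i2, 0)
  expect_error(dl_meta(two[1, , drop = FALSE]), "at least 2")

  st <- simulate_observational_studies(9, 0.1, 0.05, seed = 4)
  pooled <- dl_meta(st)
  expect_gte(pooled$theta, min(st$effect))
  expect_lte(pooled$theta, max(st$effect))
  # with no between-study variance the random pooling equals fixed pooling
  expect_equal(fe_meta(two)$theta, pool$theta)
  expect_equal(fe_meta(two)$se, pool$se)
})

test_that("leave-one-out re-pools without each study in turn", {
  st <- simulate_observational_studies(6, 0.2, 0.02, seed = 9)
  loo <- leave_one_out_meta(st)
  expect_equal(nrow(loo), 6)
  expect_equal(loo$theta[1], dl_meta(st[-1, ])$theta)
})

test_that("funnel regression detects planted asymmetry and not its absence", {
  # effects constructed as c * se (tiny jitter): coefficient recovers c
  set.seed(14)
  st <- data.frame(effect = 0.8 * seq(0.1, 0.5, length.out = 8) +
                     rnorm(8, 0, 1e-3),
                   se = seq(0.1, 0.5, length.out = 8))
  ft <- egger_funnel_test(st)
  expect_equal(ft$coef, 0.8, tolerance = 0.05)

  # symmetric funnel: coefficient within 3 SE of zero
  st2 <- simulate_observational_studies(40, 0.1, 0, se_range = c(0.05, 0.5),
                                        seed = 12)
  ft2 <- egger_funnel_test(st2)
  expect_lt(abs(ft2$coef), 3 * ft2$se)
  # precision form agrees with the direct form
  ft3 <- egger_funnel_test(st2, form = "precision")
  expect_equal(ft3$coef, ft2$coef, tolerance = 1e-10)
  expect_error(egger_funnel_test(st[1:2, ]), "at least 3")
})

test_that("between-group Q compares two pooled estimates", {
  a <- list(theta = 0.5, se = 0.2)
  expect_equal(between_group_q(a, a)$q, 0)
  expect_equal(between_group_q(a, a)$pvalue, 1)
  bg <- between_group_q(list(theta = 0, se = 1), list(theta = 2, se = 1))
  expect_equal(bg$q, 2)
  expect_equal(bg$pvalue, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("forest data carries study and pooled rows on the OR scale", {
  st <- simulate_observational_studies(5, 0.2, 0.01, seed = 3)
  fd <- forest_data(st, pooled = dl_meta(st))
  expect_equal(nrow(fd), 6)
  expect_true(fd$is_pooled[6])
  expect_equal(fd$or, exp(fd$effect))
})
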