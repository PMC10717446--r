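test_that("Egger recovers slope and directional intercept on strong instruments", {
  # no directional pleiotropy: intercept within 3 bootstrap SE of zero
  h0 <- sim_harmonized(theta = 0.2, n_exposure = 2e6, seed = 61)
  e0 <- mr_egger(h0, n_boot = 2000, seed = 1)
  expect_lt(abs(e0$intercept), 3 * e0$intercept_se)

  # directional pleiotropy under InSIDE: intercept ~ mu_alpha, slope ~ theta
  h1 <- sim_harmonized(theta = 0.2, n_exposure = 2e6,
                       pleiotropy_mean = 0.01, pleiotropy_sd = 0.003, seed = 62)
  e1 <- mr_egger(h1, n_boot = 2000, seed = 1)
  expect_lt(abs(e1$intercept - 0.01), 3 * e1$intercept_se)
  expect_lt(abs(e1$theta - 0.2), 3 * e1$se)

  expect_error(mr_egger(h1[1:2, ]), "at least 3")
})

test_that("Egger is invariant to input sign orientation", {
  h <- sim_harmonized(theta = 0.2, seed = 63)
  e <- mr_egger(h, n_boot = 0)
  flipped <- h
  i <- seq(1, nrow(h), by = 2)
  flipped$beta_exposure[i] <- -flipped$beta_exposure[i]
  flipped$beta_outcome[i] <- -flipped$beta_outcome[i]
  ef <- mr_egger(flipped, n_boot = 0)
  expect_equal(ef$theta, e$theta)
  expect_equal(ef$intercept, e$intercept)
})

test_that("Egger with the intercept constrained to zero is regression IVW", {
  h <- sim_harmonized(theta = 0.2, seed = 64)
  d <- cannabismr:::orient_positive(h)
  w <- 1 / d$se_outcome^2
  constrained <- cannabismr:::wls_line(d$beta_exposure, d$beta_outcome, w,
                                       intercept = FALSE)
  expect_equal(constrained[2], ivw_regression(h)$theta, tolerance = 1e-12)
})

test_that("I2_GX measures dispersion relative to exposure noise", {
  h <- data.frame(beta_exposure = rep(0.1, 5), se_exposure = rep(0.02, 5))
  expect_equal(i2_gx(h), 0)
  # dispersed effects with tiny SEs: approaches 100
  h2 <- data.frame(beta_exposure = seq(0.05, 0.2, length.out = 10),
                   se_exposure = rep(1e-5, 10))
  expect_gt(i2_gx(h2), 99.9)
  expect_error(i2_gx(h[1, , drop = FALSE]), "at least 2")
})

test_that("SIMEX equals Egger without measurement error and tracks it when near-NOME", {
  h <- sim_harmonized(theta = 0.2, seed = 65)
  h0 <- h; h0$se_exposure <- rep(0, nrow(h0))
  e <- mr_egger(h0, n_boot = 0)
  s <- egger_simex(h0, n_sim = 50, n_boot = 0, seed = 1)
  expect_equal(s$theta, e$theta, tolerance = 1e-10)

  # strong instruments (I2_GX > 95): SIMEX within 10% of the Egger slope
  hs <- sim_harmonized(theta = 0.2, n_exposure = 2e6, seed = 66)
  expect_gt(i2_gx(hs), 95)
  es <- mr_egger(hs, n_boot = 0)
  ss <- egger_simex(hs, n_sim = 300, n_boot = 0, seed = 2)
  expect_lt(abs(ss$theta - es$theta), 0.1 * abs(es$theta))

  expect_error(egger_simex(hs, lambdas = c(0.5, 1)), "lambda = 0")
})

test_that("SIMEX corrects the weak-instrument attenuation of the Egger slope", {
  # dilution regime: per-SNP F ~ 10; the corrected slope should land closer
  # to the truth than the naive slope in a clear majority of replicates
  wins <- vapply(1:100, function(i) {
    h <- sim_harmonized(n_snps = 60, total_r2 = 0.02, n_exposure = 30000,
                        theta = 0.5, seed = 50000 + i)
    e <- mr_egger(h, n_boot = 0)
    s <- egger_simex(h, n_sim = 300, n_boot = 0, seed = i)
    abs(s$theta - 0.5) < abs(e$theta - 0.5)
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("weighted median follows the percentile construction", {
  # equal weights: plain median
  expect_equal(cannabismr:::weighted_median_est(c(0.1, 0.2, 0.3), rep(1, 3)),
               0.2)
  # hand case: ratios 1,2,10 with normalized weights .25,.5,.25 -> p = .125,.5,.875
  expect_equal(cannabismr:::weighted_median_est(c(1, 2, 10), c(0.25, 0.5, 0.25)),
               2)
  # estimator interface with bootstrap SE
  est <- data.frame(ratio = c(0.1, 0.2, 0.3), se = c(0.1, 0.1, 0.1))
  wm <- weighted_median(est, n_boot = 500, seed = 1)
  expect_equal(wm$theta, 0.2)
  expect_gt(wm$se, 0)
  expect_error(weighted_median(est[1:2, ]), "at least 3")
})

test_that("weighted median is bounded by the ratios and robust to 30% invalid", {
  h <- sim_harmonized(theta = 0.2, prop_invalid = 0.3, invalid_alpha = 0.05,
                      seed = 67)
  w <- wald_ratio(h)
  wm <- weighted_median(w, n_boot = 2000, seed = 1)
  expect_gte(wm$theta, min(w$ratio))
  expect_lte(wm$theta, max(w$ratio))
  expect_lt(abs(wm$theta - 0.2), 3 * wm$se)
})

test_that("Steiger filtering identifies the causal direction", {
  h <- data.frame(rsid = c("rs1", "rs2"),
                  beta_exposure = c(0.1, 0.05), se_exposure = c(0.01, 0.01),
                  beta_outcome = c(0.01, 0.05), se_outcome = c(0.01, 0.01),
                  n_exposure = 1e5, n_outcome = 1e5, stringsAsFactors = FALSE)
  st <- steiger_filter(h)
  expect_true(st$correct_direction[1])
  # identical z and n on both sides: indeterminate, p ~ 1
  expect_false(st$correct_direction[2])
  expect_equal(st$z_p[2], 1)
  expect_true(all(st$r2_exposure >= 0 & st$r2_exposure < 1))

  # monotone in |z|
  z <- c(1, 2, 5, 10)
  r2 <- z^2 / (z^2 + 1e4 - 2)
  expect_true(all(diff(r2) > 0))

  # synthetic exposure->outcome data at study scale: overall p < 0.001
  hs <- sim_harmonized(theta = 0.2, seed = 68)
  sts <- steiger_filter(hs)
  expect_true(attr(sts, "overall_direction"))
  expect_lt(attr(sts, "overall_p"), 0.001)
})

test_that("multivariable MR adjusts for a correlated secondary exposure", {
  # outcome driven only by the covariate path: primary coefficient near 0
  h0 <- sim_harmonized(theta = 0, covariate_theta = 0.3, covariate_r2 = 0.02,
                       seed = 71)
  mv0 <- mr_mvmr(h0, n_boot = 1000, seed = 1)
  expect_lt(abs(mv0$theta), 3 * mv0$se)
  expect_lt(abs(mv0$covariate_theta - 0.3), 3 * mv0$covariate_se)

  # dual effects recovered
  h1 <- sim_harmonized(theta = 0.2, covariate_theta = 0.3, covariate_r2 = 0.02,
                       seed = 72)
  mv1 <- mr_mvmr(h1, n_boot = 1000, seed = 1)
  expect_lt(abs(mv1$theta - 0.2), 3 * mv1$se)
  expect_lt(abs(mv1$covariate_theta - 0.3), 3 * mv1$covariate_se)

  # zero covariate effects reduce to regression-form IVW
  h2 <- sim_harmonized(theta = 0.2, seed = 73)
  h2$beta_covariate <- 0
  h2$se_covariate <- 0.01
  mv2 <- mr_mvmr(h2, n_boot = 200, seed = 1)
  expect_equal(mv2$theta, ivw_regression(h2)$theta, tolerance = 1e-12)
  expect_true(is.na(mv2$covariate_theta))

  # collinear exposures are an explicit estimation error
  h3 <- h2
  h3$beta_covariate <- 2 * h3$beta_exposure
  expect_error(mr_mvmr(h3, n_boot = 10), "collinear")

  # SNPs missing covariate effects are dropped and counted
  h4 <- h1
  h4$beta_covariate[1:8] <- NA
  mv4 <- mr_mvmr(h4, n_boot = 200, seed = 1)
  expect_equal(attr(mv4, "n_dropped_covariate"), 8)
  expect_equal(mv4$n_snps, nrow(h4) - 8)
})
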