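test_that("generator is deterministic, consistent, and hits total_r2 exactly", {
  cfg <- simulation_config(theta = 0.1, seed = 11)
  a <- simulate_two_sample(cfg)
  b <- simulate_two_sample(cfg)
  expect_identical(a, b)
  expect_identical(a$exposure_stats$rsid, a$outcome_stats$rsid)

  tr <- a$truth
  v <- 2 * tr$maf * (1 - tr$maf)
  expect_equal(sum(tr$gamma^2 * v), 0.01, tolerance = 1e-12)
  # analytic SE forms
  expect_equal(a$exposure_stats$se, 1 / sqrt(v * 184765))
  expect_equal(a$outcome_stats$se, sqrt((1 / 60801 + 1 / 123504) / v))
  # p-values follow from the Wald z
  expect_equal(a$exposure_stats$pvalue,
               2 * pnorm(-abs(a$exposure_stats$beta / a$exposure_stats$se)))
})

test_that("generator rejects infeasible configurations", {
  expect_error(simulation_config(seed = 1, total_r2 = 1.2), "total_r2")
  expect_error(simulation_config(seed = 1, n_snps = 1), "n_snps")
  expect_error(simulation_config(seed = 1, n_snps = 2, total_r2 = 0.5),
               "infeasible")
  expect_error(simulation_config(seed = 1, maf_range = c(0.2, 0.9)), "maf_range")
  expect_error(simulation_config(theta = 0), "seed")
})

test_that("null model and no-pleiotropy construction behave as designed", {
  # theta 0, no pleiotropy: IVW lands within 3 SE of zero
  pair <- simulate_two_sample(simulation_config(theta = 0, seed = 5))
  h <- harmonize_pair(pair$exposure_stats, pair$outcome_stats)
  est <- ivw_fixed(wald_ratio(h))
  expect_lt(abs(est$theta), 3 * est$se)
  # without pleiotropy every true ratio Gamma_j/gamma_j equals theta
  pair2 <- simulate_two_sample(simulation_config(theta = 0.3, seed = 6))
  expect_equal(pair2$truth$Gamma / pair2$truth$gamma, rep(0.3, 64))
})

test_that("study-pair files round-trip through the reader with truth side-car", {
  dir <- withr::local_tempdir()
  pair <- simulate_two_sample(simulation_config(
    theta = 0.2, covariate_theta = 0.1, covariate_r2 = 0.02, seed = 3))
  paths <- write_simulated_pair(pair, dir)
  expect_true(all(file.exists(paths)))
  back <- read_summary_stats(paths[["exposure"]])
  expect_equal(back$beta, pair$exposure_stats$beta, tolerance = 1e-12)
  truth <- yaml::read_yaml(paths[["truth"]])
  expect_equal(truth$theta, 0.2)
  expect_equal(truth$seed, 3L)
})

test_that("observational-study generator respects its limits", {
  # homogeneous limit: tau2 = 0, tiny SEs -> pooled estimate near truth, I2 ~ 0
  st <- simulate_observational_studies(8, 0.25, 0, se_range = c(0.005, 0.01),
                                       seed = 2)
  pool <- dl_meta(st)
  expect_equal(pool$theta, 0.25, tolerance = 0.02)
  expect_lt(pool$i2, 50)
  expect_equal(pool$tau2, 0, tolerance = 1e-4)
  # heterogeneity limit: large tau2, tiny SEs -> I2 near 100
  st2 <- simulate_observational_studies(12, 0, 0.5, se_range = c(0.01, 0.02),
                                        seed = 2)
  expect_gt(dl_meta(st2)$i2, 99)
  # determinism
  expect_identical(st, simulate_observational_studies(
    8, 0.25, 0, se_range = c(0.005, 0.01), seed = 2))
  expect_error(simulate_observational_studies(1, 0, 0, seed = 1), "k_studies")
  expect_error(simulate_observational_studies(4, 0, -1, seed = 1), "tau2")
})

test_that("parameter recovery: IVW is calibrated at the study conditions", {
  # 200 replicates at theta 0.2; mean attenuation is bounded by the
  # weak-instrument factor theta/F (~0.007 at cumulative F ~ 29)
  res <- vapply(1:200, function(i) {
    pair <- simulate_two_sample(simulation_config(theta = 0.2, seed = 40000 + i))
    h <- harmonize_pair(pair$exposure_stats, pair$outcome_stats)
    est <- ivw_fixed(wald_ratio(h))
    c(est$theta, est$ci_low <= 0.2 && est$ci_high >= 0.2)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.2), 0.015)
  expect_gt(mean(res[2, ]), 0.9)
})
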