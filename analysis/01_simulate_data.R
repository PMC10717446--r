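#!/usr/bin/env Rscript

# Generate the synthetic two-sample datasets used by the downstream drivers:
# a CAD-scale and an IS-scale study pair (64 instruments, 1% exposure
# variance, null causal effect — the conditions of the real design), plus a
# tobacco covariate arm for multivariable MR. Everything is written under
# results/data/ and is reproducible from the seeds below.

library(cannabismr)

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

cad_pair <- simulate_two_sample(simulation_config(
  n_snps = 64, n_exposure = 184765, n_cases = 60801, n_controls = 123504,
  total_r2 = 0.01, theta = 0, covariate_theta = 0.1, covariate_r2 = 0.02,
  seed = 101))
write_simulated_pair(cad_pair, "results/data", prefix = "cad")

is_pair <- simulate_two_sample(simulation_config(
  n_snps = 64, n_exposure = 184765, n_cases = 34217, n_controls = 406111,
  total_r2 = 0.01, theta = 0, seed = 102))
write_simulated_pair(is_pair, "results/data", prefix = "is")

studies <- rbind(
  simulate_observational_studies(6, log(1.23), 0.20, se_range = c(0.10, 0.35),
                                 seed = 103, outcome_group = "CAD"),
  simulate_observational_studies(6, log(1.22), 0.08, se_range = c(0.08, 0.30),
                                 seed = 104, outcome_group = "IS"))
write.table(studies, "results/data/observational_studies_log_scale.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated two study pairs (CAD-scale and IS-scale outcomes) with a",
    "null causal effect,\n64 instruments jointly explaining",
    sprintf("%.2f%%", 100 * sum(cad_pair$truth$gamma^2 *
                                  2 * cad_pair$truth$maf *
                                  (1 - cad_pair$truth$maf))),
    "of exposure variance, and 12 observational studies.\n")
cat("Files under results/data/:",
    paste(list.files("results/data"), collapse = ", "), "\n")
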