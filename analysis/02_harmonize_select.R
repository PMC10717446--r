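#!/usr/bin/env Rscript

# Instrument accounting on the packaged synthetic stand-in tables (shaped
# like the public consortium data): 69 candidate SNPs -> remove 4 with
# discordant direction across the exposure GWAS sources -> keep those below
# the lenient threshold 5e-5 -> harmonize against each outcome, losing the
# one SNP absent from the CAD table. Harmonized tables go to results/tables/.

library(cannabismr)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
fx <- function(f) system.file("extdata", f, package = "cannabismr")

exposure <- read_summary_stats(fx("synthetic_cannabis_exposure.tsv"))
cad <- read_summary_stats(fx("synthetic_cad_outcome.tsv"))
is_out <- read_summary_stats(fx("synthetic_is_outcome.tsv"))
tobacco <- read_summary_stats(fx("synthetic_tobacco_covariate.tsv"))

discordant <- c("rs11749751", "rs2335349", "rs3740390", "rs61942416")
sel <- select_instruments(exposure, 5e-5, discordant)
cat(sprintf("candidate SNPs: %d; after discordant-direction exclusion: %d;\n",
            nrow(exposure), nrow(exposure) - attr(sel, "n_excluded")))
cat(sprintf("below p < 5e-5: %d (of which genome-wide significant: %d)\n",
            nrow(sel), sum(sel$gw_significant)))

h_cad <- harmonize_pair(sel, cad, tobacco)
h_is <- harmonize_pair(sel, is_out, tobacco)
cat(sprintf("harmonized for CAD: %d (excluded: %s)\n", nrow(h_cad),
            paste(attr(h_cad, "exclusions")$rsid, collapse = ", ")))
cat(sprintf("harmonized for IS: %d\n", nrow(h_is)))
cat(sprintf("instruments lacking a tobacco effect (dropped only in MVMR): %d\n",
            sum(is.na(h_cad$beta_covariate))))
cat(sprintf("palindromic instruments: %d; ambiguous near eaf 0.5: %d\n",
            sum(h_cad$is_palindromic),
            nrow(h_cad) - nrow(filter_palindromic(h_cad))))

write_harmonized(h_cad, "results/tables/harmonized_cad.tsv")
write_harmonized(h_is, "results/tables/harmonized_is.tsv")
cat("wrote results/tables/harmonized_{cad,is}.tsv\n")
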