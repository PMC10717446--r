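# Fixtures are built in code. make_cannabis_like_pair() emulates the shape of
# the published cannabis instrument list: 69 exposure SNPs of which 4 are
# discordant across sources, 5 pass genome-wide significance (5e-8), 59 pass
# the lenient threshold (5e-5), 1 passes neither; the outcome table lacks
# rs80144387. Effect sizes are internally consistent (p-values follow from
# the Wald z of beta/se).
make_cannabis_like_pair <- function(seed = 421, n_exposure = 184765) {
  set.seed(seed)
  k <- 69
  discordant <- c("rs11749751", "rs2335349", "rs3740390", "rs61942416")
  rsid <- sprintf("rs%06d", seq_len(k))
  rsid[66:69] <- discordant
  rsid[10] <- "rs80144387"

  z <- c(rep(6, 5),              # genome-wide significant
         rep(4.5, 59),           # lenient threshold only
         3.5,                    # passes neither threshold (position 65)
         rep(4.5, 4))            # discordant set
  eaf <- runif(k, 0.1, 0.5)
  se <- 1 / sqrt(2 * n_exposure * eaf * (1 - eaf))
  beta <- sample(c(-1, 1), k, TRUE) * z * se
  alleles <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"),
                   c("A", "T"), c("C", "G"))
  pick <- sample(nrow(alleles), k, TRUE)
  exposure <- data.frame(
    rsid = rsid, effect_allele = alleles[pick, 1],
    other_allele = alleles[pick, 2], eaf = eaf, beta = beta, se = se,
    pvalue = 2 * pnorm(-z), n = n_exposure, stringsAsFactors = FALSE)

  # outcome table: everything except rs80144387, half reported in flipped
  # orientation, a few on the opposite strand
  outcome <- exposure[exposure$rsid != "rs80144387", ]
  outcome$n <- 184305
  outcome$se <- runif(nrow(outcome), 0.006, 0.012)
  outcome$beta <- rnorm(nrow(outcome), 0, outcome$se)
  outcome$pvalue <- 2 * pnorm(-abs(outcome$beta / outcome$se))
  flip <- seq_len(nrow(outcome)) %% 2 == 0
  tmp <- outcome$effect_allele[flip]
  outcome$effect_allele[flip] <- outcome$other_allele[flip]
  outcome$other_allele[flip] <- tmp
  outcome$beta[flip] <- -outcome$beta[flip]
  outcome$eaf[flip] <- 1 - outcome$eaf[flip]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  strand <- !flip & !cannabismr:::is_palindromic_pair(outcome$effect_allele,
                                                      outcome$other_allele)
  strand[seq_len(nrow(outcome)) %% 3 != 0] <- FALSE
  outcome$effect_allele[strand] <- comp[outcome$effect_allele[strand]]
  outcome$other_allele[strand] <- comp[outcome$other_allele[strand]]

  list(exposure = exposure, outcome = outcome, discordant = discordant)
}

# small hand-made association table
mini_assoc <- function(rsid, ea, oa, beta, se, eaf = 0.3, pvalue = 1e-6,
                       n = 1e5) {
  data.frame(rsid = rsid, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}

sim_harmonized <- function(..., seed) {
  pair <- simulate_two_sample(simulation_config(..., seed = seed))
  harmonize_pair(pair$exposure_stats, pair$outcome_stats,
                 pair$covariate_stats)
}
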