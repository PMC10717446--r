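# cannabismr

Two-sample Mendelian randomization (MR) of cannabis use and atherosclerotic
cardiovascular disease, packaged as a tested, reusable workflow. It is
written for epidemiologists and statistical geneticists who want to run —
or audit — the full chain from GWAS summary statistics to a causal odds
ratio that can be set against the observational literature:

* read, validate and **harmonize** exposure/outcome/covariate summary
  statistics (allele flips, strand complements, palindromic ambiguity,
  discordant-variant exclusion, significance thresholds);
* estimate the causal effect by **per-SNP Wald ratios** pooled with fixed-
  and random-effects **IVW**, and probe the exclusion-restriction assumption
  with **MR-Egger** (bootstrap SEs, I²_GX, **SIMEX** dilution correction),
  the **weighted median**, **Steiger** directionality filtering, and
  **multivariable MR** adjusting for tobacco;
* quantify design strength (**per-SNP and cumulative F**, binary-outcome
  **power**);
* pool observational studies with **DerSimonian–Laird** random-effects
  meta-analysis, test funnel asymmetry, and compare the arms with a
  between-group Q test after converting the MR estimate to a
  **population-scale ever- vs never-user OR**;
* generate **synthetic two-sample summary statistics** with the statistical
  structure the analysis assumes, so everything above is testable offline.

## The model in brief

For SNP $j$ with exposure association $\hat\gamma_j$ and outcome
association $\hat\Gamma_j$ (log-odds scale, harmonized to the same effect
allele), the per-SNP causal estimate is the Wald ratio
$\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with delta-method standard
error. Instruments are pooled by inverse-variance weighting,

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},\qquad
w_j = \hat\gamma_j^2 / se_{\Gamma j}^2,$$

equivalent to the weighted regression of $\hat\Gamma_j$ on $\hat\gamma_j$
through the origin. MR-Egger frees the intercept of that regression: the
intercept estimates directional pleiotropy, the slope the causal effect.
Heterogeneity is summarized by Cochran's Q and I²; the random-effects
variants use the DerSimonian–Laird $\tau^2$. See the methods vignette
(`vignettes/two-sample-mr-workflow.Rmd`) for every estimator, its
assumptions, and the package's numerical choices.

## Worked example

Simulate a study pair at the real design's scale (64 instruments explaining
1% of exposure variance; 60,801 cases / 123,504 controls) with a true
causal log-OR of 0.1, then run the estimator suite:

```r
library(cannabismr)

pair <- simulate_two_sample(simulation_config(theta = 0.1, seed = 42))
h <- harmonize_pair(pair$exposure_stats, pair$outcome_stats)
w <- wald_ratio(h)

ivw_fixed(w)
#> MR estimate [ivw_fixed], 64 SNPs
#>   log-OR 0.0791 (se 0.0496), OR 1.082 (95% CI 0.982-1.193), p = 0.111
#>   Q = 60.68, I2 = 0.0%

mr_egger(h, n_boot = 2000, seed = 1)
#> MR estimate [egger], 64 SNPs
#>   log-OR -0.1003 (se 0.1611), OR 0.905 (95% CI 0.660-1.240), p = 0.534
#>   intercept 0.0037 (se 0.0032), p = 0.237

weighted_median(w, n_boot = 2000, seed = 1)
#> MR estimate [weighted_median], 64 SNPs
#>   log-OR 0.0465 (se 0.0739), OR 1.048 (95% CI 0.906-1.211), p = 0.529
```

The IVW interval covers the simulated truth (OR $e^{0.1} \approx 1.105$);
the Egger intercept is compatible with zero, as it should be — no
pleiotropy was simulated. (The Egger slope is noisy and diluted at this
instrument strength; that is what the I²_GX diagnostic and SIMEX correction
are for.) Directionality and the population-scale conversion:

```r
st <- steiger_filter(h)
attr(st, "overall_p")
#> 8.28e-136                      # exposure -> outcome direction confirmed

tp <- transform_params(disease_risk_population = 0.06,
                       disease_risk_never_users = 0.055,
                       exposure_prevalence = 0.29)
per_log_unit_to_ever_never(ivw_fixed(w), tp)
#> MR estimate [ivw_fixed_population], 64 SNPs
#>   log-OR 0.2313 (se 0.1451), OR 1.260 (95% CI 0.948-1.675), p = 0.111
```

Design diagnostics from the published constants:

```r
f_statistics(0.01, 184765, 64)$f_cumulative   # cumulative F = 29.2
mr_power_binary(60801, 123504, 0.01, 1.23)    # power = 0.987
```

## The analysis workflow

The numbered drivers under `analysis/` run the whole study shape on the
packaged synthetic stand-in tables (`inst/extdata/synthetic_*`, generated
by the package's own generator) and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate_data.R` | generate CAD- and IS-scale study pairs + observational studies |
| `02_harmonize_select.R` | instrument accounting (69 → 65 → 64 → 63) and harmonization |
| `03_mr_analysis.R` | full estimator suite per outcome + strict-threshold and palindrome-filter reruns |
| `04_observational_meta.R` | DL meta-analysis per outcome group, funnel test, leave-one-out |
| `05_diagnostics_power.R` | F-statistics and power, per-SNP diagnostics table |

Each is a thin driver over the exported functions — `run_pipeline()`
orchestrates a complete arm from one (YAML-able) configuration and emits
per-stage TSVs, a consolidated JSON report and a log; reruns with the same
configuration are byte-identical.

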