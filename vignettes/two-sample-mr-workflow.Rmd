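---
title: "Two-sample Mendelian randomization of cannabis use and cardiovascular disease: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR workflow: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannabismr)
```

## The question and the design

Whether cannabis use causally affects coronary artery disease (CAD) or
ischemic stroke (IS) is hard to settle observationally: recall bias,
confounding by tobacco and lifestyle, and reverse causation all plague the
reported associations, and a randomized exposure trial is not ethical.
Two-sample Mendelian randomization (MR) approximates the trial with
genetics: variants associated with ever-use of cannabis are used as
instruments, their effects on the exposure ($\hat\gamma_j$, from a cannabis
GWAS of $N \approx 185{,}000$) and on the outcome ($\hat\Gamma_j$, from
CAD/IS case-control GWAS consortia) are estimated in non-overlapping
samples, and the causal effect is inferred from the ratio of the two.

Instruments must satisfy three assumptions: association with the exposure
(relevance), no association with confounders (independence), and no effect
on the outcome except through the exposure (exclusion restriction). The
package implements the estimator suite and the diagnostics that probe these
assumptions, the observational meta-analysis arm the causal estimates are
contrasted with, and a synthetic generator so the whole workflow can be
exercised and tested without any external download.

## Estimators

**Wald ratio.** Per SNP, $\hat\theta_j = \hat\Gamma_j/\hat\gamma_j$ with the
delta-method standard error
$se_j = \sqrt{se_{\Gamma j}^2/\hat\gamma_j^2 +
\hat\Gamma_j^2 se_{\gamma j}^2/\hat\gamma_j^4}$. The second-order term is
available behind `second_order = TRUE`; it matters only for very weak
instruments.

**IVW.** Fixed-effects pooling with weights $w_j$, pooled estimate
$\sum w_j \hat\theta_j / \sum w_j$, $se = 1/\sqrt{\sum w_j}$, Cochran's $Q$
and $I^2$ for heterogeneity. By default the weights use the outcome-side
variance only, $w_j = \hat\gamma_j^2/se_{\Gamma j}^2$ — this makes the
ratio pooling *identical* to the weighted regression of outcome on exposure
effects through the origin, which is how standard two-sample MR software
computes IVW. Weighting by the full delta-method variance is available
(`weights = "delta"`), but it induces an additional correlation between
weights and ratios that biases the pooled estimate toward the null beyond
the unavoidable weak-instrument attenuation; we measured roughly $-0.011$
extra bias at the study conditions below, versus $-0.007$ for the default.
The random-effects version estimates the between-SNP variance $\tau^2$ by
the DerSimonian–Laird moment estimator and re-weights with
$1/(se_j^2 + \tau^2)$; when $Q \le k-1$ it collapses to the fixed-effects
result.

Confidence intervals and p-values use the normal reference distribution
throughout, the standard in two-sample MR.

**MR-Egger.** The weighted regression with a free intercept; the intercept
estimates the average *directional* pleiotropic effect under the InSIDE
assumption (pleiotropy independent of instrument strength) and its p-value
is the pleiotropy test. Exposure effects are re-oriented non-negative first,
so results are invariant to how alleles were coded. Standard errors come
from resampling SNPs with replacement (10,000 bootstrap resamples by
default, mirroring common practice for this estimator); analytic
weighted-least-squares errors are the `n_boot = 0` fallback.

**$I^2_{GX}$ and SIMEX.** Egger's slope assumes the SNP-exposure effects are
measured without error (NOME); $I^2_{GX}$ quantifies how close the data come
to that ideal. When it is low the slope is diluted, and the package corrects
it by simulation extrapolation: noise of variance
$\lambda \, se_{\gamma j}^2$ is added to the exposure effects for
$\lambda \in \{0, 0.5, 1, 1.5, 2\}$ (1,000 simulations per grid point), the
mean slope is modelled as a quadratic in $\lambda$, and the model is
extrapolated to $\lambda = -1$. The grid and the quadratic extrapolant are
standard SIMEX practice; the SE bootstraps the whole procedure over SNPs
(100 resamples by default, the expensive knob).

**Weighted median.** Ratios are ordered, cumulative midpoint percentiles
$p_j = \sum_{i \le j} w_i' - w_j'/2$ computed from normalized weights, and
the estimate interpolated at $p = 0.5$; it is consistent while under half
the weight comes from invalid instruments. Its SE is a parametric bootstrap
drawing $\hat\theta_j^* \sim N(\hat\theta_j, se_j^2)$.

**Steiger directionality.** Each SNP's variance explained on either trait is
recovered from its Wald $z$ and sample size, $r^2 = z^2/(z^2+n-2)$, on the
observed log-odds scale for both binary traits (a liability-scale conversion
is deliberately out of scope, and the choice is documented rather than
inferred from any external convention). A valid instrument should explain
more variance in the exposure; per-SNP and pooled Fisher-z tests are
reported.

**Multivariable MR.** Outcome effects are regressed jointly on cannabis and
tobacco instrument effects (weights $1/se_{\Gamma j}^2$, no intercept); the
cannabis coefficient is the tobacco-adjusted causal estimate. SNPs absent
from the tobacco dataset are dropped and counted, never imputed. Collinear
exposure columns raise an explicit estimation error. SEs bootstrap over
SNPs.

**Observational arm.** Study ORs/HRs/RRs are pooled on a common log scale
without conversion; SEs are recovered from reported 95% CIs as
$(\ln u - \ln l)/(2 \times 1.96)$, and intervals that are asymmetric on the
log scale beyond a 10% tolerance are rejected rather than silently
accepted. Pooling is DerSimonian–Laird (shared code with `ivw_random`);
funnel asymmetry is the weighted regression of effects on their standard
errors, with the algebraically equivalent precision form behind a flag; the
`between_group_q` test compares the pooled observational and population-scale
causal estimates with a 1-df Cochran's Q.

## Population-scale conversion

MR estimates for a binary exposure are per 1-log-unit of exposure odds; the
observational literature reports ever- versus never-users. The conversion is
a strictly increasing linear map on the log-OR scale: the causal log-OR, SE
and CI bounds are all multiplied by an exposure-scale contrast. The contrast
can be supplied directly in the configuration. When it is not, we derive it
from the exposure prevalence $P$ alone as the difference in mean liability
between the top $P$ and bottom $1-P$ fractions of a standard logistic
distribution (closed form; `logistic_liability_contrast`). The disease-risk
parameters — population risk $K$, never-user risk $K_0$ — are used to
validate internal consistency: the implied ever-user risk
$K_1 = (K-(1-P)K_0)/P$ must lie in $(0,1)$ with $K$ between $K_0$ and
$K_1$. This fallback is the package's own documented construction, chosen
because it preserves the null, direction, and CI geometry exactly; published
analyses that state their own contrast should pass it explicitly.

```{r transform}
tp <- transform_params(disease_risk_population = 0.06,
                       disease_risk_never_users = 0.055,
                       exposure_prevalence = 0.29)
tp$contrast
est <- ivw_fixed(data.frame(ratio = c(-0.05, -0.01), se = c(0.04, 0.04)))
exp(per_log_unit_to_ever_never(est, tp)$theta)
```

## What the synthetic generator emulates — and what it does not

`simulate_two_sample()` generates summary statistics directly on the
log-odds scale with analytic SEs,
$se(\hat\gamma_j) = 1/\sqrt{2Np_j(1-p_j)}$ and
$se(\hat\Gamma_j) = \sqrt{(1/n_{cases}+1/n_{controls})/(2p_j(1-p_j))}$,
rather than simulating genotypes: two-sample MR consumes only summary data,
and closed forms make expected values checkable. Defaults are the study
conditions of the real design: 64 approximately independent instruments
jointly explaining exactly 1% of exposure variance (effects rescaled to hit
the total), an exposure GWAS of 184,765, and a CAD-scale outcome sample of
60,801 cases and 123,504 controls. Under these conditions the per-SNP
F-statistic averages $\approx 29$, matching the design's cumulative F.

Two structural choices deserve emphasis:

* **Instrument-magnitude truncation.** Effect magnitudes are half-normal
  *truncated below at one SD* (`gamma_trunc = 1`) before rescaling. An
  untruncated half-normal makes ~20% of instruments essentially null; their
  estimated allele orientation is then random, which destroys the
  directional-pleiotropy structure described next. Truncation emulates the
  significance selection every published instrument list has undergone (all
  real exposure instruments pass $p < 5\times10^{-5}$, $z > 4$).
* **Orientation of direct effects.** Pleiotropic effects
  $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ attach to the
  exposure-increasing allele: $\Gamma_j = \theta\gamma_j +
  \mathrm{sign}(\gamma_j)\,\alpha_j$. That is the frame in which the Egger
  intercept is defined; an orientation-free $\alpha$ would average out under
  Egger's re-orientation and "directional" pleiotropy would be undetectable
  by construction. The InSIDE violation knob correlates $\alpha_j$ with
  $|\gamma_j|$; `prop_invalid`/`invalid_alpha` plant a subset of grossly
  invalid instruments for breakdown experiments; covariate effects for
  multivariable tests are generated correlated with the instrument effects.

The generator does **not** emulate: linkage disequilibrium between
instruments (independence is an input-level assumption of the whole
workflow, which accepts pre-clumped lists and never computes LD), sample
overlap between the two GWAS, winner's-curse inflation of the selected
effects, allele-frequency differences between datasets, or time-to-event
outcomes. Passing tests therefore show the estimators do what their theory
claims under the assumed sampling model — not that the assumptions hold in
any particular real dataset.

## Numerical and design choices

* **Harmonization** joins on rsID only; allele pairs are reconciled
  directly or after strand complement, outcome betas sign-flipped and EAFs
  complemented on orientation flips, and anything irreconcilable is excluded
  with an explicit reason — never silently. Strand complement is attempted
  even though the exposure GWAS reports the positive strand, because outcome
  consortium strands cannot be verified. Palindromic (A/T, C/G) SNPs are
  flagged; the ambiguity filter removes them when $|eaf - 0.5| < 0.08$, a
  conventional window, and treats a palindromic SNP with missing frequency
  as ambiguous (conservative).
* **Weak instruments.** At the default study conditions the IVW estimate
  carries an attenuation of about $\theta/F$ ($\approx -0.007$ at
  $\theta = 0.2$, $F \approx 29$); this is a property of the estimator, not
  of the implementation, and the calibration tests bound it rather than
  pretend it away. The Egger intercept inherits a leakage of the slope
  dilution at low $I^2_{GX}$; its recovery property is therefore
  demonstrated at instrument strength where the regression's NOME
  assumption approximately holds ($I^2_{GX} > 95\%$), while the SIMEX tests
  cover the diluted regime.
* **Determinism.** Every stochastic routine takes an explicit seed and
  restores the caller's RNG state; pipeline runs with identical
  configuration are byte-identical, including the JSON report.
* **Problem sizes in tests.** Monte-Carlo properties use 100–500 replicates
  at the default study conditions; SIMEX property tests use 60 instruments
  with per-SNP $F \approx 10$ and 300 simulations per grid point; full
  10,000-resample bootstraps are exercised once per outcome shape. These
  sizes were chosen so each property is well-powered while the whole suite
  stays interactive.
* **Degenerate inputs.** Zero exposure effects reject the SNP with an
  explicit error (the ratio is undefined); fewer than 2 (IVW), 3 (Egger,
  weighted median, MVMR) instruments are input errors; an empty
  post-filtering instrument set warns; `or_expected = 1` returns power equal
  to the significance level with a warning.

## Limitations

The package accepts LD-independence as an annotation and cannot detect
correlated instruments; it does not implement outlier-removal estimators
(MR-PRESSO, contamination mixture, mode-based) nor correlated-instrument
IVW; the Steiger $r^2$ is an observed-scale approximation for binary
traits; and the population-scale conversion is exact only up to the
supplied exposure contrast — with the fallback contrast its absolute level
is approximate even though null, direction and ordering are guaranteed.
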