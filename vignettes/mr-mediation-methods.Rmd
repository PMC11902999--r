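---
title: "Methods: two-sample MR and two-step mediation in mediateMR"
author: "mediateMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mediateMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediateMR)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome using genetic variants as instrumental variables,
with the variant-exposure and variant-outcome associations taken from
different GWAS cohorts. Writing $\hat\gamma_i$ for the exposure association
of SNP $i$ (standard error $\sigma_{X i}$) and $\hat\Gamma_i$ for its
outcome association (standard error $\sigma_{Y i}$), each SNP supplies a
Wald ratio $\hat\theta_i = \hat\Gamma_i / \hat\gamma_i$ with first-order
standard error $\sigma_{Y i} / |\hat\gamma_i|$. A variant is a valid
instrument if it is (1) associated with the exposure, (2) independent of
confounders of the exposure-outcome relationship, and (3) affects the
outcome only through the exposure.

Four estimators combine the ratios, each robust to a different violation:

* **IVW** — weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the
  origin with weights $1/\sigma_{Y}^2$, equivalent to the inverse-variance
  meta-analysis of the ratios. Efficient when all instruments are valid;
  biased by any directional pleiotropy.
* **MR-Egger** — the same regression with a free intercept, after
  orienting all $\hat\gamma_i > 0$. The slope is a pleiotropy-adjusted
  estimate under the InSIDE assumption; the intercept estimates the
  average directional pleiotropy.
* **Weighted median** — the ratio at cumulative inverse-variance weight
  0.5; consistent while instruments carrying at least half the weight are
  valid.
* **Weighted mode** — the argmax of a Gaussian-kernel weighted density
  over the ratios; consistent while the largest group of instruments
  sharing a causal estimate is valid.

For binary traits all effects are on the log-odds scale and reports use
$\mathrm{OR} = e^{\beta}$ with $e^{\beta \pm z\,\mathrm{se}}$ intervals.

## Instrument pipeline

`selectInstruments()` applies, in order: genome-wide-significance
selection ($p < 5\times10^{-8}$), greedy LD clumping ($r^2 \le 0.001$
within 10,000 kb, ties on p-value broken by SNP identifier for
determinism), allele harmonization, instrument-strength filtering, and
cross-trait exclusion. Stages only ever add flags to the audit table, so
every candidate's fate is reconstructible and the retained set is the
flag-free subset.

Harmonization aligns the outcome to the exposure's effect allele, flipping
the outcome beta for swapped or strand-complemented alleles. Palindromic
pairs (A/T, C/G) with minor allele frequency within 0.08 of 0.5 (eaf in
[0.42, 0.58], configurable) are dropped: their strand cannot be resolved
from alleles alone, and this window matches prevailing harmonization
practice since no sharper convention exists.

Instrument strength uses $F = R^2(N-2)/(1-R^2)$ with
$R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\,\beta^2$; SNPs with $F < 10$ are
flagged weak, the boundary $F = 10$ inclusive. Records without an allele
frequency cannot be strength-checked and are flagged with a warning rather
than silently passed — absence degrades loudly.

Cross-trait exclusion removes instruments associated (at $p < 5\times
10^{-5}$, configurable, `NULL` to disable) with the outcome or with any
supplied confounder table; the confounder tables play the role of an
offline trait-association catalogue, so the workflow has no network
dependency. The outcome-association rule deserves care: when the exposure
truly affects the outcome, strong instruments are *legitimately*
outcome-associated through the causal path, and applying the rule empties
the instrument set. The simulation-based validation therefore disables it;
it remains available for screening designs where outcome association is
read as evidence of an alternative path.

## Sensitivity battery

* **Cochran Q** over the ratios, referred to $\chi^2_{n-1}$. Q is defined
  against the *fixed-effect* IVW center regardless of which IVW variant is
  reported: that is the fit whose chi-square null the statistic assumes.
* **Egger intercept test** — a two-sided t test ($n-2$ df) of the
  intercept. Coefficient standard errors use the estimated residual
  dispersion with no lower bound, which makes the test exactly sized under
  the null (the suite verifies the 5% rejection rate by simulation); the
  reported IVW keeps the conventional multiplicative random-effects
  dispersion floor $\sqrt{\max(1, Q/(n-1))}$.
* **MR-PRESSO** — the observed residual sum of squares about the
  leave-one-out IVW fit is compared with seeded parametric replicates
  generated under the no-pleiotropy model (exposure and outcome betas both
  redrawn), giving an empirical global p; per-SNP residual contributions
  against their simulated distributions give the outlier test
  (Bonferroni-corrected at 0.05 across instruments); the distortion test
  compares the estimate shift after removing flagged outliers with shifts
  from removing random subsets of the same size. Defaults: 1000
  replicates, mandatory seed, bit-reproducible.
* **Leave-one-out** — the primary IVW re-estimated with each instrument
  removed.
* **FDR** — Benjamini-Hochberg across the IVW p-values of a run's
  exposure-outcome pairs; the grouping is configurable because "per
  subgroup" has no single convention.

## Two-step mediation

With total effect $\hat\tau$ (exposure to outcome, exposure instruments),
step A $\hat a$ (exposure to mediator, exposure instruments) and step B
$\hat b$ (mediator to outcome, mediator instruments), the indirect effect
is the product $\hat a \hat b$ with first-order delta-method standard
error $\sqrt{\hat a^2 s_b^2 + \hat b^2 s_a^2}$, and the mediated
proportion is $\hat a \hat b / \hat\tau$ with a delta-method interval
treating the three estimates as independent — the standard position for
two-sample designs with non-overlapping cohorts, stated in the output
metadata. Proportions are formatted as integer percents rounding half away
from zero; inconsistent mediation (proportion outside [0, 1]) is reported
with a warning, never clamped, and a zero total effect makes the
proportion explicitly undefined.

Two reporting conventions coexist for the "mediation effect" odds ratio:
the product-of-coefficients $e^{\hat a \hat b}$ and the combined
$e^{\hat a + \hat b} = \mathrm{OR}_A \cdot \mathrm{OR}_B$. Published
tables in this literature print the latter, so both are emitted with
explicit labels (`indirect` in the effects table; `combinedOR` for the
product of step ORs).

Step B is deliberately *univariable* — the mediator's instruments, not a
multivariable fit adjusted for the exposure — so its estimand assumes the
exposure does not confound the mediator-outcome relationship. One
practical safeguard is applied: the exposure table joins the confounder
tables for the step-B leg, so mediator instruments associated with the
exposure at the cross-trait threshold are excluded. Without this, exposure
loci that reach genome-wide significance in the mediator GWAS enter step B
carrying the *total* effect rather than the mediator path and bias the
mediated proportion upward; with it, the chain-recovery simulations are
unbiased to well within a percentage point.

```{r mediation-example}
total <- mrFromOR(1.26, 1.07, 1.48)
stepA <- mrFromOR(1.04, 1.03, 1.05)
stepB <- mrFromOR(1.33, 1.00, 1.77)
twoStepMediation(total, stepA, stepB)
```

## The synthetic generator

`simulatePair()` and `simulateMediationChain()` generate summary-level
GWAS triplets with known truth. Design choices, fixed once:

* Generation is summary-level: standard errors follow
  $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$ with $n$ read as the
  *effective* sample size (for a case/control GWAS,
  $n_\mathrm{eff} = 4/(1/n_\mathrm{cases} + 1/n_\mathrm{controls})$), and
  observed betas are drawn normally around their truth. No
  individual-level genotypes are simulated: the summary level is what
  two-sample MR consumes, and genotype simulation would add cost without
  exercising more of the pipeline.
* Minor allele frequencies are uniform on [0.05, 0.5]; allele pairs are
  drawn uniformly, so realistic palindromic SNPs occur and are dropped by
  harmonization exactly as in real data.
* True instrument effects are magnitudes of a normal with spread
  `gamma_sd` (default 0.15 on the log-odds scale, typical of
  genome-wide-significant hits in large biobank GWAS of cardiometabolic
  disease), rejection-sampled to sit three standard errors beyond the
  genome-wide-significance boundary so the selection stage is exercised
  without decimating the preset, and oriented positive — the effect
  allele is taken as the exposure-increasing allele. This orientation is
  what makes "directional" pleiotropy directional on the ratio scale.
* Pleiotropy regimes: `none`, `balanced` (zero-mean, sd 0.05) and
  `directional` (mean 0.05, sd 0.02) on a configurable fraction of
  instruments (30% in the presets).
* LD blocks, when configured, are block-diagonal at a fixed within-block
  $r^2$, with block members 10 kb apart and blocks 20,000 kb apart so the
  clumping window sees exactly one block at a time.

Scenario presets (`mrScenario()`) freeze the validation conditions:
VALID (50 instruments, effective n 100,000, true effect 0.3),
NULL_EFFECT, BALANCED, DIRECTIONAL, OUTLIER (one outcome beta displaced
by 10 standard errors), WEAK (significance enforcement off, tiny
effects), CHAIN ($\theta_{XM} = 0.2$, $\theta_{MY} = 0.3$,
$\theta_\mathrm{direct} = 0.1$, true mediated proportion 37.5%).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: sample overlap between cohorts,
winner's curse in the exposure associations, genome-wide LD structure
beyond idealized blocks, allele-frequency differences between cohorts,
population stratification, and misreported or strand-ambiguous alleles
beyond the palindrome mechanism.

## Numerical choices

* Confidence level 95% ($z = 1.959964$) unless configured; IVW p-values
  are normal, Egger p-values $t_{n-2}$.
* Wald-ratio standard errors use the first-order approximation (exposure
  uncertainty ignored), the convention consistent with IVW weighting by
  outcome variance alone. With instruments forced past genome-wide
  significance the neglected term is small; the suite's coverage check
  (92-98% band) quantifies the residual effect.
* Weighted-median interpolation places sorted ratio $i$ at cumulative
  midpoint $(\sum_{j \le i} w_j) - w_i/2$ and interpolates linearly at
  0.5, clamping to the extreme ratios outside the midpoint range.
* Weighted-mode bandwidth is $0.9 \cdot s \cdot n^{-1/5}$ times a
  configurable factor, with $s$ the scaled MAD of the ratios; when the
  MAD is zero or numerically negligible (tied ratios) the standard
  deviation substitutes, and fully degenerate ratio sets return the
  common ratio directly. The argmax is located on a 1024-point grid and
  refined with golden-section search between the bracketing grid points.
* Bootstrap standard errors (median, mode) resample both exposure and
  outcome betas from their sampling distributions; 1000 replicates by
  default, seed mandatory. All pipeline randomness derives from one run
  seed through a documented linear child-seed rule.
* Exact regression fits (zero residuals) yield p = 1 for a zero
  coefficient rather than 0/0.
* Empirical p-values use $(1 + k)/(1 + m)$ so they are never zero.

## Validation problem sizes

The test suite validates estimator recovery over 500 replicates of the
VALID scenario (bias and interval coverage), null calibration of Cochran
Q and the Egger intercept over 1000 replicates, MR-PRESSO outlier
detection over 200 replicates each of the OUTLIER and VALID scenarios,
and mediated-proportion recovery over 200 replicates of CHAIN — all at 50
instruments and effective n 100,000.

## Known limitations

* The Egger intercept test's power against the DIRECTIONAL preset falls
  short of the conventional 50% benchmark (the suite measures roughly
  45%). This is a property of the configuration, not the implementation
  (which matches a reference weighted-least-squares solve to 12 digits):
  the intercept's standard error is scale-free in the instrument-effect
  magnitudes, and the residual variance is dominated by the irreducible
  bimodal spread of 30%-prevalence pleiotropy, capping attainable power
  near 50% for any parameterization of these conditions.
* Step-B univariable estimation changes the estimand when the exposure
  confounds the mediator-outcome relationship; multivariable MR is out of
  scope.
* No proxy-SNP lookup, Steiger directionality filtering, liftover, or
  binary LD formats; PhenoScanner-style screening requires a
  user-supplied association table.
* The mediated-proportion delta interval ignores covariance between legs;
  with overlapping cohorts it would be anticonservative.
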