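---
title: "Falsifying MR instrument models with the instrumental inequalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Falsifying MR instrument models with the instrumental inequalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrfalsify)
library(dplyr)
```

## The problem

Mendelian randomization (MR) proposes genetic variants as instruments for an
exposure: the variant must be associated with the exposure (relevance), must
affect the outcome only through the exposure (exclusion restriction), and
must share no causes with the outcome (exchangeability). The last two
conditions are unverifiable, but they are *falsifiable*: for categorical
instrument $Z$, exposure $X$ and outcome $Y$ they imply Pearl's instrumental
inequalities

$$\max_x \sum_y \max_z P(x, y \mid z) \; \le \; 1 .$$

A dataset in which the left-hand side exceeds 1 is incompatible with the
instrumental conditions — something (horizontal pleiotropy, selection,
population stratification, or the coarsening of a continuous exposure) must
be violating them. A value at or below 1 is *not* evidence in favour of the
model: the check can falsify, never verify.

`mrfalsify` evaluates this statistic for the three instrument constructions
used in practice — each SNP individually (genotype strata 0/1/2), a SNP set
jointly (cross-classified genotype configurations), and the categories of an
unweighted allele score — together with a stabilized inverse-probability
weighted (IPW) variant that adjusts for principal components, and two
comparator falsification tests operating on per-SNP summary statistics: the
MR-Egger intercept test and the MR-PRESSO global test.

## The statistic and its numerical conventions

`empirical_conditional_joint()` tallies (optionally weighted) counts over
$(z, x, y)$ and normalizes within each instrument stratum. Strata with zero
total weight are dropped; the maxima run over *observed* strata only, which
is the only estimable choice. `pearl_inequality()` then evaluates
$\max_x \sum_y \max_z \hat P(x,y\mid z)$ with deterministic tie-breaking:
the argmax over exposure categories resolves to the lowest category index.
Useful identities, all enforced by tests:

* if $Z$ is independent of $(X, Y)$ the statistic equals $\max_x P(x)$;
* the statistic always lies between $\max_x P(x)$ (pooled) and the number
  of outcome levels;
* refining the instrument partition (e.g. moving from one SNP to a joint
  SNP set on the same rows) can only increase it;
* it is invariant to rescaling all weights by a positive constant.

No p-value is attached: there is no consensus approach to formal inference
for these inequalities, so the package reports the plug-in statistic and,
optionally, an explicitly exploratory bootstrap percentile interval
(`inequality_bootstrap()`, resampling individuals under a fixed seed).

Because the statistic is a maximum of sums of maxima of estimated cell
probabilities, it is upward-biased in small strata. With many jointly
cross-classified SNPs the number of observed strata approaches the number
of individuals and the statistic inflates towards the trivial bound;
`evaluate_joint_set()` warns loudly once strata outnumber half the rows and
records `n_strata` and `min_stratum_weight` so the sparse regime is always
visible. The `min_stratum` argument can drop light strata; it defaults to
no filtering, matching common practice of evaluating all observed strata.

## Coarsening conventions

The inequalities require categorical exposures, so continuous exposures are
cut at empirical quantiles (`categorize_quantiles()`, deciles by default).
Cut points are type-1 (order-statistic) quantiles of the weighted empirical
CDF; intervals are closed on the right, so values tied at a cut point fall
in the lower category; coincident cut points merge their categories, and
the achieved number of categories (often below `k` for heavily tied values
such as integer allele scores) is recorded in the returned category map.
This convention is deterministic, invariant under strictly monotone
transforms of the data, and oracle-checkable against rank-based binning.
Ordered factor exposures (questionnaire scales such as alcohol-consumption
frequency) bypass coarsening and are used verbatim in level order.

The unweighted allele score is the plain sum of effect-allele counts over
the SNP set (`build_allele_score()`), an integer in $[0, 2J]$; its
"deciles" are quantile categories of that integer and routinely collapse
below 10.

## When can the allele-score inequality be violated at all?

A structural point that shaped the simulation scenarios: for any two strata
$z_1 \ne z_2$,

$$P(x \mid z_1) + P(x \mid z_2) \;\le\; \frac{P(x)}{\min(P(z_1), P(z_2))},$$

and the statistic is bounded by the two largest values of
$P(x \mid z)$ at the argmax category. If both the exposure categories and
the score categories are exact balanced deciles (mass 0.1 each), the bound
collapses to 1 — *no* amount of pleiotropy or confounding can push the
population statistic above 1. Violations of the allele-score inequality
therefore live entirely in the unequal-mass structure of real categories:
score categories shrunk by integer ties, and exposure categories inflated
by ties in coarsely measured (heaped) phenotypes. This matches where
applied analyses find violations — categorical and decile-coarsened
exposures with tied categories — and it is why the generator can emulate
measurement heaping.

## The synthetic cohort generator

`simulate_cohort()` draws, in a fixed order so a seed fully reproduces the
cohort: subpopulation labels (two subpopulations at mixing proportion
`strat_prop`), genotypes SNP-by-SNP in Hardy–Weinberg proportions within
subpopulation, a standard-normal unmeasured confounder $U$, a linear
exposure
$X = \mu + \textstyle\sum_j \alpha_j G_j + \gamma_u U + \varepsilon$
(optionally rounded to `exposure_digits` decimals to emulate heaping), and
a Bernoulli outcome with log-odds
$\beta_0 + \beta_x X + \delta_u U + \sum_j \pi_j G_j + \text{shift} \cdot s$.
Per-SNP $\pi_j \ne 0$ is horizontal pleiotropy; the subpopulation shift plus
subpopulation-specific allele frequencies is population stratification; an
optional logistic inclusion model applied last induces selection. The
subpopulation label leaks only through `n_pcs` noisy PC-like covariates
(indicator plus standard normal noise) — imperfect but informative, as real
principal components are. Assortative mating and linkage disequilibrium are
out of scope (independent loci only).

Three canonical scenarios are frozen as the package's study conditions, at
cohort size 50,000:

* **`config_valid_iv()`** — 15 SNPs, MAF 0.3, 0.5 exposure units per
  allele, residual SD 1, a confounder linking exposure and a ~10%-prevalence
  outcome. The instrumental conditions hold, so the population statistic is
  $\max_x P(x) \le 1$ for every instrument; with exposure deciles it sits
  far below 1 and empirical violations are essentially absent at this
  sample size.
* **`config_pleiotropy(pleiotropy_pi =)`** — the detection-power setting.
  The exposure is coarsely measured (integer heaping, residual SD 0.3), so
  its achieved categories are few and unequal; 5 of the 15 SNPs are common
  (MAF 0.5, against 0.1) and carry a direct outcome effect
  $\pi \in \{0, 0.3, 0.8\}$ log-odds per allele. Outcome risk then switches
  between score categories nested inside one exposure category, which is
  exactly the structure the inequality detects; the outcome intercept is
  offset by $-5\pi$ so disease prevalence stays comparable along the grid.
  Population-level analysis of this design (not test-outcome tuning) puts
  the statistic just below 1 at $\pi = 0$ and above 1 at $\pi = 0.8$, so
  detection frequency rises from ~0 to ~1 along the grid.
* **`config_stratification()`** — two equally mixed subpopulations whose
  allele-frequency gap (0.2 vs 0.4) is confined to the seven *weak*-effect
  SNPs (0.05 units/allele vs 0.4 for the strong eight), plus a
  subpopulation outcome shift of 5 log-odds. Because a frequency gap along
  the same axis as the exposure cannot fold the score–exposure map (the
  statistic stays pinned at its concentration bound), the gap must sit on
  variants that move the score without moving the exposure — members of the
  shifted subpopulation then reach high scores at ordinary exposures, and
  score strata within one exposure category mix the subpopulations in
  different proportions. That is a genuine exchangeability violation, and
  one that IPW on the emitted PCs removes.

The outcome intercepts include small constant offsets chosen once, at the
design stage, to centre stratum-level outcome probabilities where the
logistic link is steep; all scenario parameters were fixed from this
population-level reasoning before the acceptance properties were run, and
are not re-tuned.

## Inverse-probability weighting

`fit_instrument_model()` fits a multinomial logistic model (binary
logistic for two levels) of the instrument category on the covariates —
the standard IPW construction for a categorical treatment — and
`compute_stabilized_weights()` forms stabilized weights
$w_i = P(Z = z_i) / P(Z = z_i \mid C_i)$. In the weighted pseudo-population
the instrument is independent of the covariates, so stratification captured
by the PCs no longer confounds it. Numerical guard-rails: models over more
than 25 instrument levels are refused (IPW is meant for the allele-score
instrument, not for hundreds of joint-genotype strata); separation is
detected and reported; fitted probabilities below $10^{-12}$ for an
observed combination raise a positivity error; optional symmetric
percentile truncation (off by default) caps extreme weights. Near-complete
separation of the instrument by the covariates inflates weights and can
make the *weighted* statistic noisier than the unweighted one — the
stratification scenario was therefore designed with enough overlap that
weights stay moderate.

## Comparator tests

`estimate_snp_associations()` computes one-sample per-SNP summary
statistics: linear regression of the exposure on allele count, and
logistic regression of the outcome on allele count (log-odds scale, the MR
convention for binary outcomes). Both regressions use the same
individuals, reproducing the one-sample setting of biobank analyses —
including the known caveat that MR-Egger can be biased in one sample; the
package reproduces the setting rather than correcting it.

`egger_intercept_test()` is the inverse-variance weighted regression
(weights $1/\mathrm{se}_{out}^2$) of outcome associations on exposure
associations with an intercept; the two-sided intercept p-value uses the
$t$ distribution on $J - 2$ degrees of freedom. `presso_global_test()`
computes the observed residual sum of squares around leave-one-out IVW
ratio estimates and compares it with a parametric simulation of the no-
pleiotropy null; the p-value $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$ is
bounded below by $1/(n_{sim}+1)$, order-invariant (the simulation stream is
tied to sorted SNP identifiers) and reproducible under its mandatory seed.

The three methods are deliberately complementary: balanced (mean-zero)
pleiotropy leaves the Egger intercept near 0 while PRESSO's heterogeneity
check fires; the inequalities respond to any distributional incompatibility
but only through categorical structure, and can be triggered by coarsening
alone.

## What the tests do and do not show

The test suite verifies the statistic against an exhaustive triple-loop
oracle on random tables (to $10^{-12}$), analytic fixtures (a deterministic
switching law with value exactly 2; independence laws; a confounded 2×2×2
law), the refinement and weight-invariance properties, null calibration and
detection power at the scenario scales above (200, 3×100 and 100 replicates
of cohorts of 50,000; 500 and 200 replicates of the summary-statistic
scenarios), and closed-form cross-checks of both comparators. These scales
were chosen as the package's study conditions; Monte-Carlo error at these
sizes is reflected in the tolerances used.

Passing them shows the implementation is faithful to the stated models and
that the statistical behaviour holds *under the generator's assumptions*:
independent loci, linear exposure, logistic outcome, Gaussian confounding,
two subpopulations, heaping as the only measurement error. Real cohorts
add linkage disequilibrium, assortative mating, non-linear and
heteroskedastic phenotypes, genotyping error, and richer selection — none
of which the generator emulates, so test results certify the software and
the qualitative mechanisms, not real-data performance.

## Known limitations

* Falsification only: no causal bounds or point estimation.
* The joint-SNP statistic is reported in arbitrarily sparse regimes (with
  loud diagnostics) because literal cross-classification is what the
  definition prescribes; interpreting it there is the user's burden.
* The IPW model is multinomial-logistic with linear terms; a badly
  misspecified instrument–covariate relationship leaves residual
  confounding in the weighted statistic.
* With very unbalanced outcome classes the logistic per-SNP fits can
  separate; the associated errors name the SNP rather than attempting
  penalized fits.
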