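---
title: "Methods: two-sample MR with adiposity mediation"
author: "mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with adiposity mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The model

`mrmediate` estimates the causal effect of a continuous exposure (here,
physical activity measured three ways: self-reported moderate-to-vigorous
activity, accelerometer vector-magnitude activity, and sedentary time) on a
binary outcome (colorectal cancer, on the log-odds scale) from GWAS summary
statistics, and decomposes that effect into a direct component and a
component mediated through adiposity (BMI, body fat percentage, waist
circumference, or segmental fat ratios).

The structural assumption is the usual instrumental-variable diagram: for
variant $j$ with effect $\gamma_j$ on the exposure $X$ (in SD units),

$$\beta_{Yj} = \theta_{\mathrm{total}}\,\gamma_j + \alpha_j, \qquad
\theta_{\mathrm{total}} = \theta_{\mathrm{direct}} + \kappa\,\theta_{M},$$

where $\kappa$ is the exposure-to-mediator effect (SD/SD), $\theta_M$ the
mediator-to-outcome effect (log-OR/SD), and $\alpha_j$ a possible direct
("horizontally pleiotropic") variant effect, which is zero for a valid
instrument. All causal effects are log-odds ratios per SD of exposure.

# Harmonisation

Exposure and outcome GWASs report alleles independently, so records are
aligned to the effect allele of the (first) exposure before any estimation.
Non-palindromic pairs are resolved by direct match, swap (beta sign flipped,
frequency complemented), or strand complement. Palindromic pairs (A/T, C/G)
are their own complement; the effect-allele frequency is the only
orientation signal, so variants whose frequency falls within a window of
0.5 (default `palindrome_eaf_window = 0.08`, i.e. eaf in (0.42, 0.58)) are
dropped as `palindromic-ambiguous`. This window is a conservative default;
the source analysis does not state how its alleles were harmonised, so the
truth table here is the standard convention, not the original authors'.
Harmonisation is idempotent and invariant to wholesale allele flips, and
both properties are tested.

# Instruments

Instruments are selected by p-value threshold (the source design used
$5\times10^{-8}$ or $5\times10^{-9}$ depending on the exposure) and pruned
for linkage disequilibrium by a greedy pass in ascending p-value (ties
broken lexicographically by rsID), dropping any variant with $r^2 > 0.2$
against a kept one. The greedy-ascending convention is the dominant one in
the field; the original text does not state its algorithm. Alternatively
the full correlated set can be retained (`retain_correlated = TRUE`) for
the estimators that accept an LD correlation matrix — IVW, Egger and the
robust fit — while order-statistic methods (weighted median, modes) require
pruning first; `prune_correlated()` reproduces the published exclusion of
one variant from the median-based method on exactly this ground.

Instrument strength is summarised by
$R^2 = \sum_j 2\,\mathrm{EAF}_j(1-\mathrm{EAF}_j)\,\beta_j^2$ and
$F = R^2 (N-2)/(1-R^2)$, with $F < 10$ flagged as weak. Applied to the ten
published instrument descriptions (`study_instruments()`), the minimum F is
about 91, well above the conventional bound.

# Estimators

With weights $w_j = 1/\mathrm{se}(\beta_{Yj})^2$:

* **IVW** — weighted regression of $\beta_Y$ on $\beta_X$ through the
  origin. With an LD matrix $R$ attached the fit is generalised least
  squares under $\Sigma_{jk} = \mathrm{se}_{Yj}\,\mathrm{se}_{Yk}\,r_{jk}$.
  The random-effects model is multiplicative,
  $\mathrm{se}_{\mathrm{RE}} = \mathrm{se}_{\mathrm{FE}} \times
  \max(1, \sqrt{Q/(J-1)})$ — the mainstream summary-MR convention; the
  source text says only "random-effects IVW".
* **MR-Egger** — the same regression with an intercept, after orienting all
  rows so exposure betas are positive (the intercept is meaningless
  otherwise; the source is silent on orientation). A non-zero intercept at
  p < 0.05 indicates directional pleiotropy or an InSIDE violation.
* **Weighted median** — the inverse-variance weighted median of Wald
  ratios, interpolated on the weighted empirical CDF at cumulative weight
  0.5; consistent when at least half the weight is valid. Requires
  (near-)independent instruments.
* **Mode-based** — the maximiser of a normal-kernel density of the Wald
  ratios with a modified-Silverman bandwidth
  ($0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$, scaled by `phi`); the
  weighted variant with `phi = 1` is the default and the simple variant is
  also exposed, because the source does not state which it used.
* **Robust** — MM regression with Tukey's bisquare ($c = 4.685$) of the
  precision-standardised betas through the origin, via `MASS::rlm`
  (IRLS, tolerance $10^{-10}$, 200 iterations). Exact linear data have
  zero residual scale, which defeats the robust scale estimate, so that
  degenerate case falls back to the (identical) weighted least-squares
  solution.
* Bootstrap standard errors (median, modes) are parametric — betas redrawn
  from their sampling distributions — with 10,000 replicates by default,
  seedable, and converted to normal-approximation CIs for comparability
  across methods. All 95% intervals use $\pm 1.959964$.

Heterogeneity is Cochran's $Q$ against $\chi^2_{J-1}$ (or $J-2$ with an
intercept), flagged at p < 0.10 as in the source analysis.

# Outlier diagnostics and the joint rule

`mr_presso()` implements the pleiotropy residual-sum-and-outlier test: the
observed statistic is the weighted sum of squared leave-one-out predicted
residuals; its null distribution is simulated parametrically (exposure and
outcome betas redrawn around the leave-one-out fits), giving a rank-based
global p with resolution $1/(n_{\mathrm{sim}}+1)$. Per-variant squared
residuals are compared with their own simulated distributions and
Bonferroni-adjusted — note that flagging at level $\alpha$ is only possible
when $n_{\mathrm{sim}} > J/\alpha$, and the function warns otherwise. The
weighting of the RSS is a package choice (the statistic is then
scale-equivariant); the Monte-Carlo p-value is insensitive to it because
simulations use the same statistic. The global test is mildly conservative
by construction (the simulation redraws exposure betas around their
observed values, double-counting that noise), which is inherited from the
original algorithm; measured null rejection is about 0.03 at the 0.05
level.

`leave_one_out()` scores each variant by
$|\hat\theta_{\mathrm{full}} - \hat\theta_{(-j)}| /
\mathrm{se}_{\mathrm{FE,full}}$. The *fixed-effects* SE is used
deliberately: a gross outlier inflates $Q$ and hence the random-effects SE,
which would mask its own influence.

`joint_outlier_rule()` removes a variant only when the PRESSO outlier test
flags it *and* its influence score reaches `influence_threshold`
(default 1.0 — omission moves the estimate by at least one fixed-effects
SE; the source gives no numeric rule for "leave-one-out indicated an
outlier"). The main analysis is then refit on the reduced set, mirroring
the published workflow in which one variant — the strongest exposure
association — was removed from an eight-variant instrument.

# Multivariable MR and the debiased option

`mvmr_ivw()` regresses outcome betas on the matrix of exposure betas
(union of the per-exposure instruments, pruned across the union at
$r^2 > 0.2$, keeping the smaller discovery p), without intercept, weights
$1/\mathrm{se}_Y^2$; coefficient $k$ is the direct effect of exposure $k$.
Variants missing from any exposure table are dropped, never zero-imputed —
zero-imputation drags the coefficient towards the univariable estimate.
Collinearity is surfaced loudly (condition number limit $10^6$, error
naming the most correlated exposure pair), because adiposity instruments
are mutually correlated at $r \approx 0.7$–$0.8$ in this application.

One estimator property matters enough to expose a switch. The observed
exposure betas carry sampling noise, and
$\mathbb{E}[\hat\beta_{Xj}^2] = \gamma_j^2 + \mathrm{se}_{Xj}^2$, so the
weighted Gram matrix overstates the exposure signal. When the union panel
contains many variants that instrument only the covariate (68 BMI-type
variants against 5 activity variants, in the accelerometer model), the
exposure column is mostly noise rows and the plain estimator is diluted by
roughly 30% under those conditions. `debias = TRUE` subtracts the known
sampling variances from the diagonal of the normal equations — the
multivariable analogue of the debiased IVW estimator — and is consistent
at some cost in variance. The default remains the conventional estimator
(`FALSE`), which is what the source analysis used; the package's own
recovery checks use the debiased variant because they target the
generating direct effect.

# Mediation

The difference method takes the total effect from univariable IVW and the
direct effect from multivariable MR:
$\mathrm{indirect} = \theta_{\mathrm{total}} - \theta_{\mathrm{direct}}$,
proportion mediated $= 100\,(1 - \theta_{\mathrm{direct}} /
\theta_{\mathrm{total}})$, always on the log-odds scale. The two-step
(product) method multiplies the exposure-to-mediator and
mediator-to-outcome estimates instead; the two coincide in expectation on
the linear generating model, and a simulation test verifies this.

The source does not describe its interval construction for the mediated
proportion, so the package declares one: Monte-Carlo propagation of the
point estimates through independent normal draws, percentile 2.5/97.5, with
the interval (never the point estimate) truncated to [0, 100] — the lower
truncation mirrors the published "2% (95% CI: 0, 14)" style. Independence
of total and direct is an approximation (they share instruments); treating
it as exact tends to overstate the interval width slightly. Draws with
$|\theta_{\mathrm{total}}|$ below $10^{-8}$ are discarded and counted.
Because the proportion is a ratio of (approximately) normal estimates it
has heavy tails; summaries over replicates should winsorise or use
quantiles, which is what the package's own tests do.

# Power

For a binary outcome the IVW z statistic has non-centrality
$\mathrm{ncp} = N_{\mathrm{outcome}}\, R^2\, \phi(1-\phi)\, \theta^2$ with
case fraction $\phi$, and
$\mathrm{power} = 1 - \Phi(z_{1-\alpha/2} - \sqrt{\mathrm{ncp}}) +
\Phi(-z_{1-\alpha/2} - \sqrt{\mathrm{ncp}})$; the $\phi(1-\phi)$ factor is
the Burgess-style binary-outcome approximation (the source prints only the
$R^2$ and $F$ formulas). `power(0) = alpha` exactly, and
`detectable_effect()` inverts the formula by bisection to $10^{-8}$.
Against a full two-sample rejection-rate simulation the formula is accurate
to about 0.01–0.015 absolute; the small deficit is exposure-beta noise
that the non-centrality argument ignores.

# The synthetic generator

`generate_dataset()` produces two-sample summary statistics directly at
the summary level: true per-variant effects are fixed and observed betas
add normal noise with the analytic standard errors
$\mathrm{se}_X = 1/\sqrt{2p(1-p)N_X}$ and
$\mathrm{se}_Y = 1/\sqrt{2p(1-p)N_Y\phi(1-\phi)}$. Design choices:

* Instrument effects $\gamma_j$ are half-normal draws scaled so
  $\sum 2p(1-p)\gamma^2$ equals the requested $R^2$ exactly — effect
  alleles are coded as the exposure-increasing allele, the usual reporting
  convention; without that, Egger's orientation step would fold a
  directional pleiotropy mean into a balanced one.
* Mediator-specific instruments (`j_mediator_snps`) with effects on the
  mediator only are required to identify the multivariable direct effect;
  with shared instruments alone the two exposure columns are proportional
  ($\gamma$ and $\kappa\gamma$) and the model is rank-1.
* Pleiotropy modes: `balanced` (zero mean), `directional` (mean
  `pleiotropy_sd`, sd half that), `inside_violating` ($\alpha_j$
  proportional to $\gamma_j$ plus noise).
* LD blocks induce *correlated estimation noise* with the block
  correlation — exactly the covariance the correlation-aware estimators
  assume. True LD between causal effects and realistic MAF spectra are
  out of scope.
* A sample-overlap fraction correlates exposure and outcome noise,
  emulating shared participants; a flip fraction re-emits some rows on the
  opposite allele orientation so harmonisation always has real work.

What passing tests on this generator do **not** show about real data:
winner's curse in instrument discovery, allele-frequency differences
between cohorts, LD with truly causal variants, non-collapsibility of the
odds ratio, and selection effects are all absent by construction.

`study_scenario()` pins the generator to the published instrument
descriptions (activity instruments of 7/5/3/6 variants explaining
0.07–0.2% of variance in GWASs of 91,105–385,790 people; a BMI-shaped
mediator instrument of 68 variants, $R^2 = 0.0232$, $N = 322{,}154$; an
outcome GWAS of 31,197 cases and 61,770 controls) with the headline total
effects (ORs 0.56, 0.60, 0.54, null) and mediated proportions (2% and 32%
through BMI) as defaults.

# Problem sizes and numerical choices

The test suite runs its heavier checks at deliberately chosen sizes:
parameter recovery uses 500 replicates of the accelerometer scenario
(3-MC-SE bands), test calibration 200 replicates with 300-draw PRESSO
simulations, outlier handling 100 replicates with 500-draw simulations,
and the power grid 2,000 simulations per cell with a
Bonferroni-adjusted 3-MC-SE band across the nine cells. Degenerate inputs
have defined behaviour throughout: single-variant sets degrade IVW to the
Wald ratio with a warning, identical ratios give the mode directly,
all-zero exposure columns are dropped from multivariable fits with an NA
coefficient, p-values that underflowed to zero are clamped to the smallest
positive double, and ties in LD pruning break lexicographically so every
selection is deterministic.

# Known limitations

Reproducing the published per-SNP analysis requires the article's
supplementary effect tables, which are not redistributable here; the
replication path (documented in the acceptance tests) runs whenever a
transcription is placed under `inst/extdata/replication/`. The PRESSO
global test inherits the original algorithm's mild conservativeness. The
mediation interval assumes independent total and direct estimates. MVMR
power has no closed form and is handled by simulation only.
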