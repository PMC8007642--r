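# mrmediate

Two-sample and multivariable Mendelian randomisation (MR) with mediation
decomposition, built around the question of whether physical activity
lowers colorectal cancer risk beyond what is carried through body fat.

Genetic variants associated with an exposure are used as instrumental
variables: because alleles assort randomly at conception, the regression of
variant–outcome effects on variant–exposure effects estimates a causal
effect free of classical confounding. For variant *j* with exposure effect
γ<sub>j</sub> (SD units) and outcome effect β<sub>Yj</sub> (log-OR), the
inverse-variance-weighted (IVW) estimator pools the Wald ratios
β<sub>Yj</sub>/γ<sub>j</sub> with weights 1/se(β<sub>Yj</sub>)²; a
multivariable regression on several exposures' genetic effects gives each
exposure's *direct* effect holding the others constant, and the mediated
share of a total effect θ<sub>total</sub> through an adiposity trait is
100 × (1 − θ<sub>direct</sub>/θ<sub>total</sub>) on the log-odds scale.

The package is aimed at analysts working with GWAS summary statistics. It
provides:

- reading/writing/validation of summary-statistics tables and LD
  correlation matrices, and allele harmonisation (strand flips,
  palindromic-variant handling) — `read_summary_stats()`, `harmonise()`
- instrument construction: p-value thresholding, greedy LD pruning,
  variance explained R² = Σ 2·EAF(1−EAF)β² and instrument strength
  F = R²(N−2)/(1−R²) — `select_instruments()`, `f_statistic()`
- the univariable estimator suite: fixed/random-effects IVW (with or
  without correlated instruments), MR-Egger with its intercept test,
  weighted median, weighted/simple mode, robust MM regression, and
  Cochran's Q — `mr_ivw()`, `mr_egger()`, `mr_weighted_median()`,
  `mr_mode()`, `mr_robust()`, `mr_all()`
- outlier diagnostics: MR-PRESSO (global, per-variant, distortion tests),
  leave-one-out influence, and the joint removal rule — `mr_presso()`,
  `leave_one_out()`, `joint_outlier_rule()`
- multivariable MR (IVW and Egger variants, optional measurement-error
  debiasing) and beta–beta trait correlations — `mvmr_ivw()`,
  `mvmr_egger()`, `beta_beta_correlation()`
- mediation by the difference and product (two-step network) methods with
  Monte-Carlo intervals — `proportion_mediated()`, `two_step_network()`
- non-centrality-parameter power and minimum detectable effects —
  `mr_power()`, `detectable_effect()`
- a seeded synthetic summary-statistics generator with known causal
  structure (direct + mediated paths, pleiotropy modes, LD blocks, sample
  overlap) and presets matching the published study design —
  `generate_dataset()`, `study_scenario()`
- a config-driven pipeline and a thin command-line front end —
  `run_pipeline()`, `inst/cli/mr_pipeline.R`

## Worked example

Simulate an accelerometer-activity scenario (5 instruments explaining 0.2%
of exposure variance in a GWAS of 91,105; a BMI-shaped mediator; an outcome
GWAS of 31,197 cases / 61,770 controls; true total OR 0.60 with 32%
mediated), then run the analysis:

```r
library(mrmediate)

truth <- study_scenario("ampa", seed = 7)
ds <- generate_dataset(truth)

h <- harmonise(ds$exposure[ds$exposure$variant_id %in%
                             ds$exposure_instruments, ], ds$outcome)
mr_ivw(h)
#> ivw_random: beta = -0.4025 (SE 0.3151), OR = 0.669 (95% CI 0.361, 1.240), p = 0.202, 5 SNPs
#>   Cochran's Q = 14.289 on 4 df, p = 0.00643 (heterogeneity at P < 0.10)

hm <- harmonise(list(ampa = ds$exposure, bmi = ds$mediator), ds$outcome)
mv <- mvmr_ivw(hm, model_label = "Model 1 (AMPA + BMI)", debias = TRUE)
mv
#> Multivariable MR (mvmr_ivw): Model 1 (AMPA + BMI), 73 SNPs
#>   ampa: OR = 0.714 (0.493, 1.033), p = 0.0737
#>   bmi: OR = 0.606 (0.551, 0.667), p = 6.91e-25
#>   Q = 76.694 on 71 df (p = 0.301)

proportion_mediated(mr_ivw(h), mv$direct_estimates$ampa, seed = 7,
                    exposure_id = "ampa", mediator_id = "bmi")
#> Mediation (difference method): ampa through bmi
#>   total = -0.4025, direct = -0.3371, indirect = -0.0654
#>   proportion mediated = 16.3% (95% CI 0.0, 100.0)

mr_power(truth$instrument_r2, truth$n_outcome, truth$case_fraction,
         truth$theta_total)
#>   alpha    r2 n_outcome case_fraction     effect  or      ncp     power
#> 1  0.05 0.002     92967     0.3355707 -0.5108256 0.6 10.81775 0.9080878
```

Reading the output: this single replicate estimates a total OR of 0.669
per SD of activity (the truth is 0.60; the instrument explains only 0.2%
of exposure variance, so single-dataset CIs are wide), a direct OR of
0.714 holding BMI constant, and a mediated share of 16% with an interval
covering the generating 32%. The power row says a design of this size
detects a true OR of 0.60 with 91% power at α = 0.05. Averaged over many
replicates the estimators centre on the generating values; the test suite
performs exactly those checks.

The same analysis runs from a YAML config via `run_pipeline()` or from the
shell:

```sh
Rscript inst/cli/mr_pipeline.R simulate --scenario ampa --seed 7 --out data/
Rscript inst/cli/mr_pipeline.R mr --exposure data/exposure.tsv --outcome data/outcome.tsv --method all
```

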