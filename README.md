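# saltsynergy

Additive gene–environment interaction analysis for cohort-based (nested)
case-control studies of incident hypertension — built around the question
of whether the GNB3 C825T (rs5443) TT genotype amplifies the effect of a
high-sodium diet, i.e. whether the two exposures act synergistically on the
additive scale.

The package is aimed at epidemiologists analysing a dichotomous genetic
factor and a dichotomous dietary exposure against a binary outcome. It
provides:

* **Contingency machinery** — 2×2 and four-category (genotype × sodium)
  tabulation, crude odds ratios `ad/bc` with Woolf confidence intervals
  `exp(ln OR ± z·√(1/a+1/b+1/c+1/d))`, Wald or Pearson p-values, and
  Haldane–Anscombe zero-cell handling.
* **A logistic MLE engine** — dummy-coded design matrices and IRLS
  (Newton–Raphson with step-halving, score-norm convergence at 1e-8,
  explicit separation errors, optional Firth correction), returning the
  coefficient vector and variance–covariance matrix.
* **Additive-interaction statistics** — with odds ratios for the four
  joint-exposure categories (reference OR00 ≡ 1, OR10, OR01, OR11):

      RERI = OR11 − OR10 − OR01 + 1
      AP   = RERI / OR11
      S    = (OR11 − 1) / ((OR10 − 1) + (OR01 − 1))

  with delta-method intervals from the model's covariance matrix (ln-scale
  for S, natural scale for RERI and AP) and a case-control-stratified
  percentile bootstrap as a cross-check.
* **A synthetic cohort generator** — Hardy–Weinberg genotypes, two-class
  sodium exposure, configurable odds-scale effects (the joint OR is an
  independent knob), covariates, ten-year incident outcomes generated
  directly on the odds scale, and 1:k gender frequency matching — so the
  entire pipeline is testable with no external data.

## Worked example

Evaluate the interaction statistics from three adjusted odds ratios
(joint 3.23, genotype-only 1.08, sodium-only 1.51):

```r
library(saltsynergy)
reri(3.23, 1.08, 1.51)
#> [1] 1.64
attributable_proportion(3.23, 1.08, 1.51)
#> [1] 0.5077399
synergy_index(3.23, 1.08, 1.51)
#> [1] 3.779661
```

So 51% of the odds of hypertension in TT carriers on a high-sodium diet is
attributable to the interaction of the two factors, and the joint excess
odds are 3.8 times the sum of the separate excesses — strong synergy.

The full pipeline, from simulated cohort to report:

```r
cfg <- run_config(mode = "simulate",
                  simulation = sim_config(seed = 20180530 %% 2^31),
                  seed = 20180530 %% 2^31, ci_method = "both",
                  output_dir = "results/interaction")
bundle <- run_pipeline(cfg)
print(bundle$interaction)
```

which on this seed prints (a single 1,301-subject realization, so the
estimates scatter around the generator's true values 1.08 / 2.03 / 2.88):

```
Additive interaction on the odds-ratio scale (delta intervals)
  OR10 (gene only):     1.191
  OR01 (exposure only): 1.982
  OR11 (joint):         4.729
  RERI: 2.555 (95% CI -1.196-6.307)
  AP:   0.540 (95% CI 0.133-0.948)
  S:    3.178 (95% CI 0.864-11.694)
```

The numbered drivers under `analysis/` run the same steps as a narrative
workflow: `01_simulate_cohort.R` (cohort + parameter manifest),
`02_case_control_analysis.R` (exclusions, matching, marginal tables),
`03_interaction_analysis.R` (joint table, RERI/AP/S with delta and
bootstrap intervals), `04_published_tables.R` (reanalysis of the published
table counts). Each writes its tables under `results/`.

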