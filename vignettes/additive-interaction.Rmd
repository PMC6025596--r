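---
title: "Additive gene-sodium interaction: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive gene-sodium interaction: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saltsynergy)
```

## The scientific question

Salt sensitivity of blood pressure — the inter-individual variability in
blood-pressure response to dietary sodium — is thought to be partly genetic.
The GNB3 C825T polymorphism (rs5443) in the G-protein beta-3 subunit gene
enhances intracellular signal transduction and is a candidate marker of salt
sensitivity: carriers of the TT genotype may develop hypertension more
readily on a high-sodium diet. The question is not whether either factor
acts alone, but whether their joint effect exceeds the sum of their separate
effects — *additive* interaction, the scale that maps onto the
sufficient-component-cause model and onto public-health decisions.

`saltsynergy` implements the complete analysis chain for this question in a
cohort-based (nested) case-control design: subjects free of hypertension at
entry are followed, incident cases are identified, and controls are drawn
from the same cohort by gender frequency matching, preserving
exposure-before-outcome temporality.

## The statistical model

Let the four genotype-by-sodium categories be: reference (CC/CT genotype and
low sodium), gene-only (TT, low sodium), exposure-only (CC/CT, high sodium)
and joint (TT, high sodium), with odds ratios $OR_{00} \equiv 1$,
$OR_{10}$, $OR_{01}$, $OR_{11}$ against the reference. The adjusted odds
ratios come from one dummy-coded logistic model

$$\mathrm{logit}\, p = \alpha + \beta_g G + \beta_e E + \beta_{ge} GE +
\boldsymbol\gamma^\top \mathbf{z},$$

where $G$, $E$, $GE$ indicate the three non-reference categories and
$\mathbf{z}$ holds the covariates (age-band dummies, BMI, lipid classes,
smoking, alcohol, diabetes). Then $OR_{10} = e^{\beta_g}$,
$OR_{01} = e^{\beta_e}$, $OR_{11} = e^{\beta_{ge}}$, and the three
additive-interaction statistics (with odds ratios substituting for risk
ratios, as usual in case-control data) are

$$\mathrm{RERI} = OR_{11} - OR_{10} - OR_{01} + 1, \qquad
\mathrm{AP} = \frac{\mathrm{RERI}}{OR_{11}}, \qquad
S = \frac{OR_{11} - 1}{(OR_{10} - 1) + (OR_{01} - 1)}.$$

Under exact additivity RERI $= 0$, AP $= 0$ and $S = 1$; $S > 1$ (equivalently
RERI $> 0$ when the denominator is positive) indicates synergy. Note the AP
variant here divides by $OR_{11}$, not $OR_{11} - 1$.

```{r}
reri(3.23, 1.08, 1.51)
attributable_proportion(3.23, 1.08, 1.51)
synergy_index(3.23, 1.08, 1.51)
```

### Confidence intervals

Crude odds ratios use Woolf intervals,
$\exp(\ln OR \pm z\sqrt{1/a + 1/b + 1/c + 1/d})$, with the Wald test of
$\ln OR = 0$ as the default p-value (it matches the interval machinery; a
Pearson chi-square is available). Tables containing a zero cell receive the
Haldane-Anscombe correction (+0.5 to every cell) and are flagged; two empty
cells in one margin make the OR not estimable.

For RERI, AP and $S$ the intervals come from the delta method on the
relevant 3x3 block of the fitted model's variance-covariance matrix: the
gradient of the statistic with respect to $(\beta_g, \beta_e, \beta_{ge})$
is evaluated at the MLE and the variance is $g^\top V g$. RERI and AP use
symmetric natural-scale intervals. For $S$ the interval is constructed on
$\ln S$ and exponentiated (the Hosmer-Lemeshow construction): this
guarantees a positive interval and produces the strong right skew that a
ratio of excess odds actually exhibits; a natural-scale interval cannot.
$S$ is undefined when $(OR_{10}-1)+(OR_{01}-1) \le 0$ and sign-incoherent
when $OR_{11} \le 1$ (Rothman's own caveat); both return an explicit
not-estimable marker rather than a signed value.

A case-control-stratified percentile bootstrap (resampling cases among
cases and controls among controls, refitting per replicate) provides an
independent interval; replicates where the statistic is not estimable are
counted, and an interval with more than 20% failed replicates is flagged
unreliable.

## The logistic engine

`fit_logistic()` maximizes the Bernoulli likelihood by Newton-Raphson on
the canonical logit link (observed information equals expected information,
so this is classical IRLS), with:

* convergence declared when $\max_j |\partial \ell / \partial \beta_j| <
  10^{-8}$ (default; `max_iter = 50`), giving coefficients that agree with
  saturated-table closed forms to better than ten significant digits;
* step-halving, so the log-likelihood trace is non-decreasing at every
  iteration (asserted in the tests);
* an explicit separation error when any $|\beta| > 15$ — diverging
  coefficients are reported, never silently returned — with Firth's
  bias-reduced score available as a flag for separated or sparse data;
* the variance-covariance matrix as the inverse observed information at the
  optimum, which feeds the delta-method intervals.

On a saturated 2x2 (or 2x4 joint) model with no covariates, the exponentiated
coefficients equal the contingency crude odds ratios and the Wald standard
errors equal the Woolf form — a cross-module identity the test suite checks
to ten significant digits.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the study conditions: a cohort
of 1,301 adults followed ten years, genotypes drawn under Hardy-Weinberg
equilibrium with T-allele frequency 0.532 (so $P(TT) = q^2 \approx 0.283$,
the control-group frequency, taken as the source-population estimate),
high-sodium prevalence 0.112 (again the control value), covariate
prevalences and odds ratios from the descriptive table's control column and
crude ORs, and age-band weights from the controls. Incident hypertension is
generated *directly on the odds scale* through the four-category coding
(log odds = log baseline odds + the category's log OR + covariate
contributions): the analysis only ever consumes the dichotomous outcome,
and this construction makes the generating odds ratios exact truths that
downstream estimators must recover. The default exposure effects are
$OR_{10} = 1.08$, $OR_{01} = 2.03$, $OR_{11} = 2.88$; the joint OR is an
independent knob, so any mixture of additive and multiplicative interaction
can be configured. `baseline_odds = 0.028` places the overall ten-year
incidence near 21%, inside the ~20-25% band the design targets (checked
once at $n = 10^5$ when the generator was built).

Sodium intake is a two-point distribution (1,800 and 6,000 mg/day by
default): in the emulated design every analysed subject is either low or
high, so a two-class generator is the honest choice. `classify_sodium()`
still supports the intermediate band for real data, which the pipeline
excludes with a logged count. The exposure thresholds are a parameter with
default (2,400, 4,800) mg/day; the source tables also display a
(2,500, 5,000) header variant, and the package deliberately documents
rather than resolves that discrepancy — both variants classify the
generator's two mass points identically.

What the generator does **not** emulate: continuous blood-pressure
trajectories, measurement error in dietary recall, covariate-exposure
correlation (covariates are drawn independently of genotype and sodium),
linkage with other variants, or informative loss to follow-up (a
`p_loss_followup` knob exists but defaults to 0, since complete follow-up
reproduces every targeted quantity). Passing tests therefore demonstrate
the estimators' correctness under a clean generating model, not robustness
to confounded or mismeasured real data. In particular, because covariates
are independent of the exposures, the *conditional* (adjusted) odds ratios
equal the generating values while marginal crude ones are attenuated by
non-collapsibility — which is why recovery checks fit the adjusted model.

Matching: `frequency_match()` keeps every incident case and samples
controls without replacement, uniformly within each gender stratum, at the
configured ratio (default 1:3); short strata take all available controls
and set a `partial` flag. Controls default to follow-up normotensives; a
flag allows sampling from the full baseline roster instead, since either
reading of the design is defensible.

## Model-coding decisions

* **Age bands**: three dummies (41-45, 46-50, $\ge$ 51) against a $\le$ 40
  reference — the coding with three age coefficients; band edges are
  configurable. An alternative five-band description exists in the source
  materials, but the fitted model's term count is authoritative.
* **Covariates** enter as binary abnormal/normal indicators matching the
  descriptive-table cut-offs (continuous versions can be passed as numeric
  columns).
* **Genotype grouping** is TT vs CC+CT (recessive coding for the T allele)
  by default; the genotype column keeps all three levels so other codings
  remain possible.
* **Genotype synonyms**: input validation normalizes the string `TC` to
  `CT` with a warning, since both orderings occur in practice.
* **z for 95% intervals** is `qnorm(0.975)` = 1.959964..., kept at full
  precision; rounding to 2 decimals happens only in the reporting layer.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route: printed
contingency tables against hand cross-products; the IRLS engine against
closed forms and `stats::glm`; the interaction statistics against hand
arithmetic and exact algebraic identities (AP $\cdot\, OR_{11}$ = RERI,
$S \cdot ((OR_{10}-1)+(OR_{01}-1)) = OR_{11}-1$); the delta intervals
against a symbolic diagonal-covariance expansion and against the bootstrap.
Simulation-based checks use: parameter recovery at $n = 50{,}000$ (within
two standard errors of the generating log odds ratios); coverage of the
95% ln-$S$ delta interval over 500 cohorts of $n = 4{,}000$ at the default
effect sizes, required to land in 93-97%; and delta-versus-bootstrap
endpoint agreement within 15% relative at $n = 8{,}000$ with 2,000
replicates. The bootstrap comparison uses the synergy index: $S$ is
strictly positive, so relative endpoint comparison is well posed, whereas
RERI and AP interval endpoints can sit arbitrarily close to zero where any
relative criterion degenerates.

## Known limitations

* Odds ratios only: RERI on true risk ratios from full-cohort follow-up is
  not implemented, matching the case-control substitution used here.
* No conditional logistic regression; frequency matching is handled by
  including the matching variable in the model, not by conditioning.
* No stepwise model selection; the covariate set is specified explicitly.
* The delta method is first-order: in small samples or near the boundary
  of the $S$ domain its intervals can misbehave, which is exactly what the
  bootstrap cross-check and the not-estimable markers are for.
* Published *adjusted* odds ratios and their intervals depend on
  subject-level covariate data that no summary table can reconstruct; the
  package reproduces every crude quantity from printed counts exactly and
  validates the adjusted machinery by simulation instead.
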