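---
title: "Risk-adjustment scoring and decile calibration: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk-adjustment scoring and decile calibration: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskcalib)
```

## The scoring model

A patient-year is priced as

$$ r_i \;=\; d(\mathrm{sex}_i, \mathrm{age}_i) \;+\; \sum_{h \in H_i} \beta_h , $$

where $d$ is a coefficient from sex-by-age demographic cells (half-open
$(\mathrm{lo}, \mathrm{hi}]$ age bands) and $H_i$ is the patient's set of
hierarchical condition categories after hierarchy imposition. Categories
come from a table-driven map of prior-year diagnosis codes; codes the map
does not know are counted and skipped, never errors, because production
claims always contain such codes. Two coefficient tables exist per model:
*community*, and *institutional* for patients with **more than** 90 days of
skilled-nursing or long-term care (exactly 90 days is community — the rule
is strict).

**Hierarchy semantics.** Rules are (dominant, suppressed) pairs forming an
acyclic graph, validated at load time. We apply each rule once, in severity
(topological) order, against the evolving set: a category that has itself
been suppressed no longer suppresses its subordinates. With rules A>B and
B>C, the input {A, B, C} yields {A, C}. This matches the sequential,
most-severe-first application used by published HCC software; the test
suite pins it against an independent recursive oracle over every subset of
a six-category fixture. The output is always a subset of the input and a
fixed point under re-application.

**Scales.** A specification declares whether its coefficients are
dollar-scale or relative factors. The shipped fixture model is
dollar-scale, so a score approximates an expected annual cost; nothing in
the engine depends on the choice, and published coefficient bundles in the
documented four-file layout can be dropped in.

## The psychiatric grouper and the missed population

A second, finer classifier assigns diagnoses to 47 psychiatric categories
and derives named flags (any MH/SA, PTSD, mood disorder, serious mental
illness, substance abuse, dementia, nicotine dependence). The **missed
population** is defined set-theoretically as patients with at least one
psychiatric category and **no** MH/SA condition category in the risk
profile; its per-category counts, ranked by count with alphabetical
tie-breaks, form the missed-diagnosis table. Percentages use the missed
population as denominator, rounded half away from zero to one decimal —
the rounding rule that reproduces every verifiable published percentage.
Because categories overlap, the column may sum past 100.

## Cost regressions

Three families, all with design (intercept, score, optionally the 47
indicators in fixed category order):

* `ols_linear` — OLS on dollars; this is the payment-formula scale, and
  the calibration analysis uses its predictions. Negative predictions are
  retained (clipping would distort decile membership); their count is a
  diagnostic.
* `ols_sqrt` — OLS on $\sqrt{y}$ with Duan-type smearing on the way back:
  for the square-root transform the smearing estimate of the conditional
  mean is $(X\hat\beta)^2 + \overline{e^2}$, an additive constant, because
  the OLS residuals have mean zero. $R^2$ is reported on both the fitting
  and the dollar scale, since conventions differ between studies.
* `glm_gamma_log` — gamma GLM with log link via `stats::glm`
  (`epsilon = 1e-8`, `maxit = 100`; `glm`'s IRLS convergence criterion is
  relative deviance change). The GLM models the mean directly, so no
  retransformation is needed. Non-positive costs are floored at \$1 with a
  reported count; a cohort defined by health-care use implies positive
  utilization, so the floor is a numerical guard, not a modelling choice.

Indicator columns with zero variance in the fitted cohort (categories no
one — or everyone — has, common at small n with rare conditions) carry no
information and are dropped with a record in `dropped_columns`; their
increment is implicitly zero at prediction time. Any remaining rank
deficiency (for example a constant score) aborts with the collinear
columns named.

**Inference.** The coefficient covariance is carried both classically and
HC1-robust (`sandwich`). Slope intervals default to the robust version:
health-care costs have multiplicative, heavy-tailed noise, so the error
variance grows with the mean and classical OLS intervals under-cover. In
the package's own recovery study (50 replicates, n = 20 000) the robust
intervals cover the true slope 92–98% of the time while classical ones
cover about 72%.

## Decile calibration

Patients are sorted by (prediction, patient id) — the id breaks ties
deterministically — and split into 10 contiguous groups, the first
`n mod 10` groups one larger. For each decile: expected mean $\bar E_d$
(mean prediction), actual mean $\bar A_d$, gap $\Delta_d = \bar E_d - \bar
A_d$ (negative = underestimate), and percent gap $100\,\Delta_d/\bar E_d$
rounded half away from zero to the nearest integer. Subgroup tables
restrict first and re-decile within the subgroup, so each subgroup has its
own expected-cost range — the convention required to reproduce published
subgroup tables. The identity $\sum_d n_d \Delta_d = \sum_i (\hat y_i -
y_i)$ holds exactly and is asserted in the tests; with full-cohort OLS
predictions it is ~0 by residual orthogonality.

The shipped reference tables (`reference_decile_fit()`,
`reference_prevalence()`) carry the printed per-decile means, differences
and prevalences of a published national evaluation of this model family in
a 5.47-million-patient veteran cohort. Recomputing the difference and
percent columns from the printed means reproduces every percent exactly;
three dollar differences disagree by \$1 because the published means and
differences were rounded independently, so the tests compare dollars at a
documented ±1 display tolerance.

## The synthetic generator

The generator emulates that study population's structure at desk scale
with a known truth. Defaults are the emulated conditions, chosen once:

* demographics: 93.5% male; age ~ Normal(63.0, 16.1), rounded, clipped to
  [22, 100];
* general-medical conditions: diabetes 22.1% (30% of diabetics also carry
  the complicated-diabetes code, which dominates in the hierarchy), heart
  failure 10%, COPD 12%, renal disease 5%, cancer 4%, independent draws;
* the 47 psychiatric categories share a latent Gaussian propensity with
  pairwise correlation 0.3, so comorbidity clusters exist. Marginals are
  anchored where the emulated population pins them (PTSD 10.4%, dementia
  0.85% across its three categories) and the remaining marginals were
  calibrated once so the *any psychiatric* union lands near 36% and the
  risk-model-visible MH/SA share near 13%. With a single shared factor,
  the mood/SMI/substance flag unions land a little under their emulated
  targets (~15%, ~4.5%, ~13%) — an accepted compromise, since no
  one-factor copula can hit every union simultaneously;
* long-term-care days are dementia-linked (40% of dementia patients exceed
  90 days vs 0.4% otherwise), which drives the institutional variant;
* true expected cost = the fixture model's own score (dollar scale) plus
  any unpriced component; observed cost multiplies it by mean-one
  lognormal noise $\exp(\varepsilon)$, $\varepsilon \sim N(-\sigma^2/2,
  \sigma^2)$ with $\sigma = 1.1$, giving the heavy right tail (median less
  than half the mean) characteristic of annual cost data;
* the Medicare share of total cost is 0 below age 65 and ramps as
  $\min(0.65,\; 0.25 + 0.02\,(\mathrm{age}-65))$ above, splitting into
  Parts A/B/D (60/30/10); all splits are computed in integer cents so
  payer additivity is exact;
* ~2% of patients carry exclusion flags purely to exercise cohort
  assembly, and 5% get a diagnosis dated in the cost year to exercise the
  prior-year window.

**Under-pricing channels.** `inject_mispricing()` switches one channel and
nothing else:

* `NONE` — every cost-bearing condition is priced by the score; the model
  is correctly specified.
* `MH_UNPRICED` — the 43 psychiatric categories invisible to the risk
  model carry real dollar increments (\$500–\$3000, e.g. PTSD \$2500,
  unspecified depression \$1800, nicotine dependence \$900); the four
  model-mapped groups stay priced through their category coefficients.
  This is the mechanism under study: the model prices 4 MH/SA categories
  and misses the rest.
* `DEMENTIA_CUSTODIAL` — dementia multiplies true cost by 1.6 while the
  institutional coefficients stay at community levels. The custodial
  burden scales with overall illness, which is what produces a
  monotone-in-decile shortfall; a flat dollar increment would produce a
  flat one.

## What the synthetic checks do and do not show

Passing tests demonstrate that the machinery is correct: scoring matches a
per-record oracle, hierarchies match brute force, deciles conserve the
total prediction error, OLS recovers the generator's slope, the augmented
model's $R^2$ is never lower (nesting), and the injected channels produce
their signatures — all 10 mental-health deciles negative under
`MH_UNPRICED`, and a growing dementia shortfall under
`DEMENTIA_CUSTODIAL`. They do not show that real claims behave like the
generator: real coding intensity varies by site, costs are not exactly
lognormal, comorbidity has richer structure than one latent factor, and
the fixture model has 10 categories, not 83.

Two statistical limits of the desk-scale conditions are worth stating
plainly. At n = 100 000 with $\sigma = 1.1$, a decile of 10 000 patients
has a relative standard error of about 1.5% on its actual-cost mean, so
even a perfectly calibrated cohort shows occasional rounded percent gaps
of 3–4; and the dementia subgroup (0.8% prevalence → deciles of ~80
patients) is too small for its decile profile to be reliably monotone,
something only the emulated study's hundredfold larger cohort can show.
The acceptance checks assert the strict forms at fixed seed and are
expected to be tight there; the underlying implementation behaviour is
separately verified at low noise, where all gaps vanish.

## Numerical and design choices

* Costs live in integer cents internally; dollars at the interfaces.
* Percentages: half away from zero (one decimal for prevalences, integers
  for decile percent gaps) — reproduces all verifiable published values.
* Age is taken at the start of the cost year; the ≥65 stratum boundary is
  age ≥ 65 at that date.
* Codes are stored undotted and upper-cased; dotted input is accepted.
* The augmented design supplements the score with the 47 indicators — it
  does not remove the model's own MH/SA categories from the score.
* Decile and ranking tie-breaks are by patient id and category name
  respectively, for determinism.
* Problem sizes in the shipped checks — n = 100 000 for calibration
  signatures, 50 × 20 000 for recovery, 4 000 for shared unit fixtures —
  were chosen as the smallest sizes at which the respective signals are
  clearly resolved.
* Reproducibility: everything downstream of `generator_config(seed = s)`
  is deterministic, including written files; the pipeline manifest records
  seeds and MD5 digests of every artifact.
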