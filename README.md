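# riskcalib

Hierarchical-condition-category (HCC) risk scoring and decile calibration
for dual-payer (VA + Medicare) patient-year claims.

## The problem

Cost risk-adjustment models of the CMS-HCC family price a patient-year from
demographics plus a small set of hierarchical condition categories derived
from the prior year's diagnosis codes. The V21 variant carries 83
categories but only 4 for mental health and substance use, so psychiatric
illness that falls outside those 4 categories carries cost the model cannot
see. For a health system with a heavy psychiatric case mix — a veteran
population being the canonical example — that turns into systematic
underprediction: calibration tables by decile of predicted cost show the
mental-health subgroup underestimated in every decile, and custodial
dementia care shows a shortfall that grows with the decile.

`riskcalib` implements that entire evaluation loop for researchers who want
to study it, or reproduce its mechanics, without restricted claims data:

- **claims handling** — delimited-text readers with row-level error
  reports, cohort assembly rules (medication-only and no-VA-use exclusions,
  prior-year diagnosis window, exact integer-cent payer additivity), and
  stratified descriptive summaries;
- **hcc engine** — a fully table-driven scorer: code→category map, acyclic
  suppression hierarchies applied in severity order, sex-by-age demographic
  cells, community vs. institutional coefficient tables (institutional for
  > 90 long-term-care days);
- **psycms grouper** — a 47-category psychiatric case-mix classifier with
  derived flags (any MH/SA, PTSD, mood, SMI, substance, dementia, …) and
  the missed-diagnosis table: patients with psychiatric categories but no
  MH/SA condition category in the risk model;
- **cost models** — OLS of cost on score (the payment scale), the same
  design augmented with the 47 psychiatric indicators, square-root OLS with
  Duan smearing, and a gamma log-link GLM; HC1-robust standard errors;
- **calibration** — deciles of predicted cost (deterministic tie-breaks),
  per-decile expected/actual means, dollar and percent gaps
  (gap = expected − actual; negative = underestimate), subgroup re-deciling,
  and base-vs-augmented improvement series;
- **synthetic data** — a deterministic dual-payer claims generator with a
  known true cost model (score-priced conditions, mean-one lognormal noise,
  age-ramped Medicare share) and switchable under-pricing channels
  (`NONE`, `MH_UNPRICED`, `DEMENTIA_CUSTODIAL`);
- **pipeline** — `run_pipeline()` orchestrates
  simulate → score → group → fit → calibrate → report with a JSON manifest.

The core quantity is the risk score

    r_i = d(sex_i, age_i) + Σ_{h ∈ HCC(dx_i)} β_h,

the cost regressions `y_i = a + b·r_i (+ Σ_j γ_j m_ij) + ε_i`, and the
per-decile calibration gap `Δ_d = Ē_d − Ā_d` with percent gap
`100·Δ_d/Ē_d`.

## Worked example

```r
library(riskcalib)

g   <- generate_cohort(inject_mispricing(
         generator_config(n = 50000, seed = 99), "MH_UNPRICED"))
hcc <- score_cohort(g$cohort, g$spec)
psy <- classify_cohort(g$cohort, g$codelist)

base <- fit_cost_model(g$cohort, hcc$profiles$score)
aug  <- fit_cost_model(g$cohort, hcc$profiles$score, psy, g$codelist)
compare_fit(base, aug)[c("r2_base", "r2_augmented")]
#> $r2_base
#> [1] 0.1352
#> $r2_augmented
#> [1] 0.1403

tab <- calibration_table(g$cohort, predict(base, hcc$profiles$score),
                         psy$flags$any_mh_sa, label = "mental health")
tab$deciles$gap < 0
#> [1] TRUE TRUE TRUE TRUE TRUE TRUE TRUE TRUE TRUE TRUE
```

Every decile of the mental-health subgroup is underestimated (negative
gap), while the augmented model's R² is strictly higher — the qualitative
signature the package exists to reproduce. The missed-diagnosis analysis
(`missed_mh_analysis(hcc, psy, g$codelist)`) ranks which psychiatric
groups those underpriced patients carry, nicotine dependence and
unspecified depression typically leading.

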