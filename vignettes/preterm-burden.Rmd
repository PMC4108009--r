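---
title: "Methods: modelling the ten-year economic burden of preterm birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the ten-year economic burden of preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(pretermburden)
```

## Scope

`pretermburden` estimates the per-infant and national cost of preterm
birth from delivery to age ten, by gestational-age stratum: **early**
(<28 completed weeks), **moderate** (28–32) and **late** (33–36).
`assign_ga_category()` accepts whole weeks 20–36 and rejects term
gestations. All dollar figures are $CAD (2012 price level).

## Cohort model

Each stratum is simulated as a closed cohort through a fixed sequence of
states:

1. **Delivery**: death in the delivery room with probability
   `p_death_delivery`.
2. **Neonatal admission**: survivors are admitted to neonatal care with
   probability `p_admit_neonatal` and discharged alive with probability
   `p_live_discharge_neonatal`; non-admitted survivors go directly home
   (a realistic outcome only for late-preterm infants).
3. **Discharge to age 2**: one state with survival
   `survival_discharge_to_age2`.
4. **Ages 2–10**: eight annual survival probabilities.

`run_cohort()` returns the survival curve `S(a)` for ages 0–10. The
survival fraction at age 1 — used to weight the discharge-to-age-2 cost
component at its midpoint — is interpolated geometrically:
`S(1) = sqrt(S(discharge) * S(2))`.

From age 2 the surviving cohort carries a distribution over four
disability levels (none / mild / moderate / severe), initialized at age 2
and propagated annually by a row-stochastic 4×4 transition matrix
(row vector × matrix). The distribution is conditional on survival, so it
always sums to one.

### Calibration

The stage probabilities at and around birth come from external clinical
sources and are stated directly
(`DEFAULT_STAGE_PROBS`). The two downstream survival parameters are
**back-calculated** so the composite survival curve reproduces published
composite values by construction:

- `survival_discharge_to_age2 = S2_target / S(discharge)`
- `annual_survival = (S10_target / S2_target)^(1/8)` (constant across the
  eight years, for want of published annual detail)

with `S2_target` = 0.560 / 0.928 / 0.984 and `S10_target` = 0.559 /
0.926 / 0.982 for early / moderate / late. `validate_epi_params()`
reports every violated invariant by field path; `write_epi_params()` /
`read_epi_params()` round-trip the parameter set through YAML.

## Costing

`unit_costs()` holds all prices (prenatal items, delivery modes, neonatal
per-diems, post-discharge per-diems and procedures, school years, hourly
wages). Costs incurred at age `a` are multiplied by `S(a)` and discounted
at `rate` (default 5%/year): `discount(x, a, rate) = x / (1 + rate)^a`.

Per-infant components (`aggregate_per_infant()`), all with live births as
denominator:

- **delivery** — expectation over the four delivery modes, age 0.
- **neonatal** — intensive plus normal care days at their per-diems,
  times the admitted-alive fraction, age 0. The delivery-mode mixes and
  mean stays are not published; `calibrate_delivery_mix()` and
  `default_neonatal_stay()` back-calculate them from the published
  per-live-birth cost targets ($578/623/613 delivery,
  $53,520/42,298/3,757 neonatal), fixing the instrumental share (10%),
  an even caesarean split, and assumed intensive-day fractions
  (0.70/0.55/0.25).
- **discharge_to_age2** — inpatient days (PICU included, priced at the
  general per-diem) plus outpatient billings; discounted at age 1, the
  period midpoint, weighted by `S(1)`.
- **medical_2_4 / medical_5_10** — annual PICU days, other inpatient
  days, procedures and outpatient billings at ages 2–4 and 5–9 (the year
  starting at age 9 is the last accrual year before the age-10 horizon).
- **indirect_2_4 / indirect_5_10** — caregiver time off work: 2 hours per
  outpatient visit, 8 per inpatient day, at $23.18/h, from age 2 (a
  full-time caregiver is assumed available before age 2).
- Optional sensitivity layers (`sensitivity_options()`): prenatal excess
  care for the 50% of preterm births identified as high-risk; education
  costs (mainstream vs special school by disability level) from age 5;
  a neonatal infrastructure per-diem amortizing a $2.5M, 25-bed, 30-year
  facility ($9.13/day).

`national_scale()` multiplies by the stratum birth counts
(1,828 / 4,685 / 20,795) and adds the all-preterm row (sum of totals;
count-weighted per-infant average). `render_table3()` formats the result
in the published wide layout, rounding half-up to whole dollars.

Visit counts are not published, only billed costs; `default_utilization()`
converts cost means to visit means with an external mean billing of
$36/visit.

## Claims ETL

`claims_bundle()` validates four linked tables (registry, hospital
episodes, physician claims, deaths) sharing `infant_id`.
`apply_exclusions()` applies, in precedence order: (1) transfer during
the birth hospitalization; (2) early/moderate preterm with no neonatal
hospitalization record; (3) no post-birth contact and no death record.
Late-preterm infants without a birth episode are retained as
"direct home".

`compute_utilization()` estimates, per (stratum, age period), means and
standard errors of inpatient days (non-PICU), PICU days, procedures,
outpatient billed costs and visits (distinct service dates):

- The birth hospitalization is excluded; events before its discharge day
  are ignored.
- Age-`k` boundaries sit at `round(k * 365.25)` days after birth; the
  generator uses the identical convention, so period assignment is
  calendar-free.
- Inpatient days are nights (`discharge − admit`), minimum 1 for same-day
  stays.
- Denominators are **survivors**: infants alive on the period's closing
  birthday (age 2 for the discharge-to-age-2 cell). Survivors with no
  events contribute zeros; cells with no survivors are missing (`NA`),
  not zero.
- SE = sample SD / sqrt(n), 0 when n = 1.

## Synthetic claims generator

`generate_cohort()` simulates a 1996–97 birth cohort with the structure
above: stratum membership (published birth shares by default), staged
mortality from an `epi_params` set, neonatal length of stay
(Poisson-based, means 53/42/9 days), and per-period utilization drawn
**only for infants alive at the period's end** — the estimator's
survivor denominators — so no event postdates a death and cell means are
unbiased for the targets. Counts are negative binomial (dispersion
`size = 1`, allowing realistic overdispersion) with means equal to the
published utilization table; billed amounts per visit are gamma
(mean $36, shape 4) rounded to cents so files round-trip exactly;
procedures are drawn only for infant-periods with an inpatient stay.
Linkage noise: 1% birth-transfer flags, 2% loss to follow-up (all
post-birth records removed). Identical `(config, seed)` gives
byte-identical output.

These defaults describe the study conditions; they are not fitted to any
downstream check. What the generator does *not* model: seasonality,
readmission clustering within infants beyond the NB dispersion,
stratum-specific billing distributions, or migration.

## Probabilistic sensitivity analysis

`sample_parameters()` perturbs, per iteration (seeded by
`(seed + iteration) mod 2^31−1`):

- utilization cell means ~ Normal(mean, SE) truncated at zero
  (inverse-CDF method, exact mass at the boundary);
- probabilities ~ method-of-moments Beta with
  SD = `probability_se_frac × sqrt(m(1−m))`;
- disability simplexes ~ Dirichlet with total concentration
  `dirichlet_concentration` (`Inf` fixes them);
- optionally unit costs ~ truncated Normal with CV `unit_cost_cv`.

`run_psa()` reruns the full deterministic model per draw, resampling any
draw that fails validation (deterministically, from a shifted iteration
index), and summarizes total costs with the mean and empirical
2.5th/97.5th percentiles (`stats::quantile`, linear interpolation). A
zero-variance specification reproduces the deterministic result exactly,
which the tests assert.

## Pipeline

`run_pipeline()` chains simulate → exclusions → estimate → model → PSA
and writes trajectories, utilization, the exclusion log, the rendered
burden table, the PSA summary and a YAML manifest (config hash, seed,
package version). The command-line surface is deliberately these plain R
functions plus `scripts/acceptance.R`; configuration is a YAML file read
by `read_pipeline_config()`, which rejects unknown fields by name.

## Numerical conventions and limitations

- Presentation rounding is half-up (`round_half_up()`), matching the
  published tables; internal arithmetic is double precision throughout.
- The discharge-to-age-2 component is discounted at its midpoint (age 1);
  annual components at their starting integer age.
- The shipped reference table (`table3_reference()`) is internally
  consistent in its totals, but its post-discharge category rows cannot
  be reproduced exactly from the published utilization means and unit
  costs under any survival weighting; end-to-end model output therefore
  matches the reference totals approximately (within ~5%), not cell for
  cell.
- Constant annual survival between ages 2 and 10 is an assumption forced
  by the published two-point composite survival.
- Costs stop at age 10; lifetime burdens (lost earnings, adult care) are
  out of scope.
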