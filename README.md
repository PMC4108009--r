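# pretermburden

Health-economic model of the ten-year cost burden of preterm birth,
stratified by gestational age at delivery.

## The problem

Infants born preterm (before 37 completed weeks of gestation) face higher
mortality and use far more health care than term infants, from the
delivery room through the first decade of life. Quantifying that burden —
per infant and scaled to a national birth cohort — requires joining
several pieces that usually live in different places:

- a **cohort (Markov) model** of survival from delivery through neonatal
  intensive care, discharge, and ages 2–10, with long-term disability
  states;
- **unit costs** for every layer of care (prenatal, delivery, neonatal
  per-diems, post-discharge hospital days, procedures, education, and
  caregiver lost productivity), discounted to present value;
- **utilization estimates** (hospital days, physician billings) derived
  from linked administrative claims, with cohort exclusion rules and
  survivor-based denominators;
- a **probabilistic sensitivity analysis (PSA)** propagating parameter
  uncertainty through the whole chain.

`pretermburden` implements all of these as composable R functions, plus a
synthetic claims generator so the full claims-to-burden pipeline can be
exercised and tested without access to confidential health records.

The model follows the standard structure for this analysis: three
gestational-age strata — early (<28 weeks), moderate (28–32), late
(33–36) — each simulated through delivery-room death, neonatal admission
and death, a single discharge-to-age-2 state, and annual survival to age
10. Costs incurred at age *a* are weighted by the fraction of live births
surviving to *a* and discounted at 5%/year:

```
E[cost] = sum_a  S(a) * C(a) / (1 + r)^a
```

National totals multiply per-infant costs by the annual preterm birth
counts (1,828 / 4,685 / 20,795 for the three strata).

## Worked example

Run one stratum through the cohort engine:

```r
library(pretermburden)
traj <- run_cohort(default_epi_params(), "early")
traj
#> <cohort_trajectory> stratum: early
#>   survival at ages 0/2/10: 1.0000 0.5600 0.5590
#>   P(direct home): 0.0000
```

Evaluate the full deterministic model and render the national burden
table (per-category national totals and per-infant costs, by stratum):

```r
result <- run_burden_model(model_inputs())
render_table3(result$national)
#> # A tibble: 8 × 9
#>   category          all_national_total all_cost_per_infant early_national_total
#> 1 delivery                    16722674                 612              1056584
#> 2 neonatal                   374127505               13700             97834560
#> 3 discharge_to_age2           86151787                3155             13219928
#> 4 medical_2_4                 30226827                1107              1891082
#> 5 indirect_2_4                22343982                 818              1340576
#> 6 medical_5_10                22153023                 811              1450751
#> 7 indirect_5_10               18831853                 690              1141739
#> 8 total                      570557651               20893            117935221
#> # ... per-infant and national columns for early / moderate / late follow:
#> # early 64,516 ; moderate 53,854 ; late 9,633 $ per infant
```

Propagate parameter uncertainty:

```r
psa <- run_psa(model_inputs(), psa_spec(n_iterations = 200, seed = 1))
psa
#> <psa_result> 200 iterations, 0 resampled
#> # A tibble: 4 × 7
#>   stratum  mean_cost_per_infant p2.5_cost_per_infant p97.5_cost_per_infant
#> 1 all                    20887.               20336.                21479.
#> 2 early                  64290.               59597.                68719.
#> 3 moderate               53850.               52213.                55611.
#> 4 late                    9646.                9248.                10017.
```

Or run everything — synthetic claims, exclusions, utilization estimation,
model, PSA, and CSV/manifest outputs — in one call:

```r
run_pipeline(pipeline_config(n_infants = 10000, seed = 1), "out/")
```

The published reference table is shipped as data
(`table3_reference()`) for comparison against model output.

## Package layout

| Area | Functions |
| --- | --- |
| Cohort model | `epi_params()`, `default_epi_params()`, `run_cohort()`, `disability_distribution_at()` |
| Costing | `unit_costs()`, `discount()`, `delivery_cost()`, `neonatal_cost()`, `annual_direct_cost()`, `annual_indirect_cost()`, `education_cost()`, `prenatal_excess_cost()`, `aggregate_per_infant()`, `national_scale()` |
| Claims ETL | `claims_bundle()`, `apply_exclusions()`, `compute_utilization()` |
| Synthetic data | `generator_config()`, `generate_cohort()`, `write_bundle()` / `read_bundle()` |
| PSA | `model_inputs()`, `run_burden_model()`, `psa_spec()`, `sample_parameters()`, `run_psa()` |
| Pipeline | `pipeline_config()`, `run_pipeline()`, `render_table3()`, `table3_reference()` |

See the vignette (`vignettes/preterm-burden.Rmd`) for the methods,
parameter provenance, and design decisions.
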