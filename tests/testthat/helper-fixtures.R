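# Eight-infant fixture with hand-computed utilization expectations.
#
# Included after exclusions: F01, F02 (late), F03, F04 (moderate), F08
# (early).  Excluded: F05 (birth transfer), F06 (no follow-up, no death),
# F07 (moderate with no neonatal hospitalization).  F04 dies before age 2,
# so the moderate survivor denominator is 1; F02 is a late direct-home
# infant.
eight_infant_bundle <- function() {
  d <- as.Date
  registry <- tibble::tibble(
    infant_id = sprintf("F%02d", 1:8),
    ga_weeks = c(35L, 34L, 30L, 29L, 26L, 34L, 28L, 25L),
    birth_date = d(c("1996-03-01", "1996-04-01", "1996-05-01", "1996-06-01",
                     "1996-07-01", "1996-08-01", "1996-09-01", "1996-10-01")),
    transfer_at_birth = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                          FALSE)
  )
  episodes <- tibble::tibble(
    infant_id = c("F01", "F01", "F01",
                  "F03", "F03",
                  "F04", "F05",
                  "F08", "F08", "F08"),
    admit_date = d(c("1996-03-01", "1996-06-01", "1998-04-01",
                     "1996-05-01", "1996-08-01",
                     "1996-06-01", "1996-07-01",
                     "1996-10-01", "1997-03-01", "1997-06-01")),
    discharge_date = d(c("1996-03-03", "1996-06-04", "1998-04-02",
                         "1996-06-10", "1996-08-06",
                         "1996-07-15", "1996-08-01",
                         "1997-01-10", "1997-03-03", "1997-06-01")),
    ward = c("neonatal_normal", "general", "general",
             "neonatal_intensive", "general",
             "neonatal_intensive", "neonatal_intensive",
             "neonatal_intensive", "picu", "general"),
    procedure_count = c(0L, 1L, 0L, 0L, 2L, 0L, 0L, 0L, 0L, 0L),
    is_birth_episode = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE,
                         TRUE, FALSE, FALSE)
  )
  claims <- tibble::tibble(
    infant_id = c("F01", "F01", "F01", "F02", "F03", "F07", "F08", "F08"),
    service_date = d(c("1996-05-10", "1997-01-15", "1998-05-01",
                       "1996-09-01", "1996-08-20", "1997-01-01",
                       "1997-04-01", "1997-04-01")),
    billed_amount = c(40, 35, 50, 30, 45, 40, 60, 20)
  )
  deaths <- tibble::tibble(infant_id = "F04", death_date = d("1996-07-15"))
  claims_bundle(registry, episodes, claims, deaths)
}

# Hand-computed expected cells for the fixture above (endpoints: inpatient
# days exclude PICU days, which are reported separately; visits are
# distinct claim dates; SE = sample SD / sqrt(n), 0 when n = 1).
eight_infant_expected <- function() {
  tibble::tribble(
    ~ga, ~period, ~inpatient_days_mean, ~inpatient_days_se,
    ~picu_days_mean, ~picu_days_se, ~procedures_mean, ~procedures_se,
    ~outpatient_cost_mean, ~outpatient_cost_se,
    ~outpatient_visits_mean, ~outpatient_visits_se, ~n,
    "late", "discharge_to_2", 1.5, 1.5, 0, 0, 0.5, 0.5,
    52.5, 22.5, 1.5, 0.5, 2L,
    "late", "2", 0.5, 0.5, 0, 0, 0, 0, 25, 25, 0.5, 0.5, 2L,
    "moderate", "discharge_to_2", 5, 0, 0, 0, 2, 0, 45, 0, 1, 0, 1L,
    "early", "discharge_to_2", 1, 0, 2, 0, 0, 0, 80, 0, 1, 0, 1L
  )
}

# A tiny valid epidemiology for hand-unrolled checks.
toy_epi <- function(p_death_delivery = 0.1, p_admit = 1,
                    p_live_discharge = 0.5, s_d2 = 0.9,
                    annual = rep(0.9, 8),
                    init = c(none = 1, mild = 0, moderate = 0, severe = 0),
                    transition = diag(4)) {
  dimnames(transition) <- list(c("none", "mild", "moderate", "severe"),
                               c("none", "mild", "moderate", "severe"))
  st <- list(
    p_death_delivery = p_death_delivery, p_admit_neonatal = p_admit,
    p_live_discharge_neonatal = p_live_discharge,
    survival_discharge_to_age2 = s_d2, annual_survival = annual,
    disability_init_age2 = init, disability_transition = transition
  )
  epi_params(list(early = st, moderate = st, late = st))
}
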