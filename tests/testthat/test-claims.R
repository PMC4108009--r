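test_that("exclusion rules assign one reason each, in precedence order", {
  cohort <- apply_exclusions(eight_infant_bundle())
  exc <- cohort$exclusions
  expect_equal(exc$reason[exc$infant_id == "F05"], "birth_transfer")
  expect_equal(exc$reason[exc$infant_id == "F06"], "no_followup_no_death")
  expect_equal(exc$reason[exc$infant_id == "F07"],
               "early_moderate_no_neonatal_hospitalization")
  expect_setequal(exc$infant_id, c("F05", "F06", "F07"))
  # late preterm without a birth hospitalization is retained, flagged
  expect_equal(cohort$direct_home, "F02")
  # included and excluded partition the registry
  reg_ids <- eight_infant_bundle()$registry$infant_id
  kept <- cohort$bundle$registry$infant_id
  expect_setequal(c(kept, exc$infant_id), reg_ids)
  expect_length(intersect(kept, exc$infant_id), 0)
})

test_that("exclusions are idempotent", {
  cohort <- apply_exclusions(eight_infant_bundle())
  again <- apply_exclusions(cohort$bundle)
  expect_equal(nrow(again$exclusions), 0)
  expect_equal(again$bundle$registry, cohort$bundle$registry)
})

test_that("utilization estimates match the hand-computed fixture cells", {
  cohort <- apply_exclusions(eight_infant_bundle())
  util <- compute_utilization(cohort)
  expected <- eight_infant_expected()
  for (i in seq_len(nrow(expected))) {
    ex <- expected[i, ]
    cell <- util[util$ga == ex$ga & util$period == ex$period, ]
    expect_equal(nrow(cell), 1)
    for (col in setdiff(names(expected), c("ga", "period", "n"))) {
      expect_equal(cell[[col]], ex[[col]], tolerance = 1e-9,
                   label = paste0(ex$ga, "/", ex$period, " ", col))
    }
    expect_equal(cell$n, ex$n)
  }
  # survivors with no events contribute zero rows, not missing cells
  late3 <- util[util$ga == "late" & util$period == "3", ]
  expect_equal(late3$n, 2L)
  expect_equal(late3$inpatient_days_mean, 0)
  expect_equal(late3$outpatient_cost_mean, 0)
  # the non-survivor (F04, died before age 2) is in no denominator
  expect_equal(unique(util$n[util$ga == "moderate"]), 1L)
})

test_that("sample SE follows sd/sqrt(n) and is zero for singletons", {
  util <- compute_utilization(apply_exclusions(eight_infant_bundle()))
  # late discharge-to-2 inpatient days are {3, 0}: mean 1.5, SE 1.5
  cell <- util[util$ga == "late" & util$period == "discharge_to_2", ]
  expect_equal(cell$inpatient_days_se,
               stats::sd(c(3, 0)) / sqrt(2), tolerance = 1e-12)
  single <- util[util$ga == "early" & util$period == "discharge_to_2", ]
  expect_equal(single$n, 1L)
  expect_equal(single$outpatient_cost_se, 0)
})

test_that("age-period boundaries fall on rounded fractional birthdays", {
  d <- as.Date("1996-01-01")
  registry <- tibble::tibble(infant_id = "B01", ga_weeks = 35L,
                             birth_date = d, transfer_at_birth = FALSE)
  claims <- tibble::tibble(
    infant_id = "B01",
    service_date = d + c(729, 730, 3651, 3652),
    billed_amount = c(10, 20, 40, 80)
  )
  empty_ep <- tibble::tibble(infant_id = character(), admit_date = as.Date(character()),
                             discharge_date = as.Date(character()),
                             ward = character(), procedure_count = integer(),
                             is_birth_episode = logical())
  empty_d <- tibble::tibble(infant_id = character(),
                            death_date = as.Date(character()))
  cohort <- apply_exclusions(claims_bundle(registry, empty_ep, claims, empty_d))
  util <- compute_utilization(cohort)
  get <- function(p) util$outpatient_cost_mean[util$ga == "late" &
                                                 util$period == p]
  expect_equal(get("discharge_to_2"), 10)  # day 729: before 2nd birthday
  expect_equal(get("2"), 20)               # day 730: on the 2nd birthday
  expect_equal(get("9"), 40)               # day 3651: last accrual day
  # day 3652 (10th birthday) is past the horizon and never counted
  expect_equal(sum(util$outpatient_cost_mean, na.rm = TRUE), 70)
})

test_that("the claims bundle validates linkage and dates", {
  b <- eight_infant_bundle()
  bad_claims <- dplyr::bind_rows(
    b$claims,
    tibble::tibble(infant_id = "ZZZ", service_date = as.Date("1997-01-01"),
                   billed_amount = 10))
  expect_error(claims_bundle(b$registry, b$episodes, bad_claims, b$deaths),
               "unknown infant id.*ZZZ")
  bad_ep <- b$episodes
  bad_ep$discharge_date[1] <- bad_ep$admit_date[1] - 1
  expect_error(claims_bundle(b$registry, bad_ep, b$claims, b$deaths),
               "discharge before admission")
  bad_death <- tibble::tibble(infant_id = "F01",
                              death_date = as.Date("1995-01-01"))
  expect_error(claims_bundle(b$registry, b$episodes, b$claims, bad_death),
               "death before birth")
})
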