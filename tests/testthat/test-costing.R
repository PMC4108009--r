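test_that("discounting follows the closed form and its identities", {
  expect_equal(discount(100, 0, 0.05), 100)
  expect_equal(discount(105, 1, 0.05), 100)
  expect_equal(discount(1000, 10, 0.05), 613.9133, tolerance = 1e-6)
  expect_equal(discount(250, 7, 0), 250)
  expect_error(discount(100, -1), "non-negative")
})

test_that("infrastructure per-diem is the facility cost over bed-days", {
  expect_equal(infrastructure_per_diem(365, 1, 1, 365), 1)
  expect_equal(infrastructure_per_diem(1000000, 10, 10, 365), 27.40,
               tolerance = 1e-3)
  expect_error(infrastructure_per_diem(beds = 0), "positive")
})

test_that("delivery cost is the expectation over delivery modes", {
  costs <- unit_costs()
  expect_equal(delivery_cost(c(spontaneous = 1)), 498.70)
  expect_equal(delivery_cost(c(emergency_caesarean = 1)), 786.51)
  expect_equal(delivery_cost(rep(0.25, 4)), 666.995)
  expect_error(delivery_cost(c(spontaneous = 0.5)), "summing to 1")
  expect_error(delivery_cost(c(breech = 1)), "unknown delivery mode")
})

test_that("calibrated delivery mixes hit their target expected costs", {
  costs <- unit_costs()
  for (target in c(578, 623, 613)) {
    mix <- calibrate_delivery_mix(target, costs)
    expect_equal(sum(mix), 1, tolerance = 1e-12)
    expect_true(all(mix >= 0))
    expect_equal(delivery_cost(mix, costs), target, tolerance = 1e-9)
  }
  expect_error(calibrate_delivery_mix(100), "not attainable")
})

test_that("neonatal cost prices intensive and normal days, plus per-diem", {
  stay <- neonatal_stay_params(list(
    early = list(mean_intensive_days = 10, mean_normal_days = 5,
                 delivery_mode_dist = c(1, 0, 0, 0)),
    moderate = list(mean_intensive_days = 0, mean_normal_days = 0,
                    delivery_mode_dist = c(1, 0, 0, 0)),
    late = list(mean_intensive_days = 0, mean_normal_days = 0,
                delivery_mode_dist = c(1, 0, 0, 0))
  ))
  expect_equal(neonatal_cost("moderate", stay), 0)
  expect_equal(neonatal_cost("early", stay), 10 * 1628.60 + 5 * 388.00)
  with_infra <- neonatal_cost("early", stay,
                              opts = sensitivity_options(include_infrastructure = TRUE))
  expect_equal(with_infra, 18226 + 15 * infrastructure_per_diem())
})

test_that("calibrated neonatal stays reproduce per-live-birth cost targets", {
  epi <- default_epi_params()
  stay <- default_neonatal_stay(epi)
  targets <- c(early = 53520, moderate = 42298, late = 3757)
  for (ga in names(targets)) {
    p_admitted <- run_cohort(epi, ga)$p_admitted
    expect_equal(p_admitted * neonatal_cost(ga, stay), targets[[ga]],
                 tolerance = 1e-9)
  }
})

test_that("annual direct costs price the utilization cells", {
  util <- default_utilization()
  # discharge-to-2, late: published means
  expect_equal(annual_direct_cost("late", "discharge_to_2", util),
               2.40 * 628.49 + 734.14, tolerance = 1e-9)
  # zero utilization is free
  u0 <- util
  for (col in grep("_mean$", names(u0), value = TRUE)) u0[[col]] <- 0
  expect_equal(annual_direct_cost("early", "3", utilization_table(u0)), 0)
  # one PICU day plus one procedure at age 4
  u1 <- u0
  i <- which(u1$ga == "late" & u1$period == "4")
  u1$picu_days_mean[i] <- 1
  u1$procedures_mean[i] <- 1
  expect_equal(annual_direct_cost("late", "4", utilization_table(u1)),
               2002.86 + 111.88)
  expect_error(annual_direct_cost("late", "12", util), "no cell")
})

test_that("indirect costs convert contacts to hours off work times wage", {
  cell <- list(outpatient_visits_mean = 2, inpatient_days_mean = 1,
               picu_days_mean = 0)
  expect_equal(annual_indirect_cost(cell), (2 * 2 + 1 * 8) * 23.18)
  cell10 <- list(outpatient_visits_mean = 10, inpatient_days_mean = 0,
                 picu_days_mean = 0)
  expect_equal(annual_indirect_cost(cell10), 463.60)
  expect_equal(annual_indirect_cost(list(outpatient_visits_mean = 0,
                                         inpatient_days_mean = 0,
                                         picu_days_mean = 0)), 0)
  expect_error(annual_indirect_cost(list(outpatient_visits_mean = -1,
                                         inpatient_days_mean = 0,
                                         picu_days_mean = 0)),
               "non-negative")
})

test_that("education cost is the expectation over levels and school types", {
  all_mainstream <- matrix(c(1, 0), nrow = 4, ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("mainstream", "special")))
  expect_equal(education_cost(c(1, 0, 0, 0), all_mainstream), 7720.05)
  all_special <- matrix(c(0, 1), nrow = 4, ncol = 2, byrow = TRUE)
  expect_equal(education_cost(c(0, 0, 0, 1), all_special), 15666.45)
  half <- matrix(c(0.5, 0.5), nrow = 4, ncol = 2, byrow = TRUE)
  expect_equal(education_cost(c(0.25, 0.25, 0.25, 0.25), half), 11693.25)
  expect_error(education_cost(c(1, 0, 0, 0),
                              matrix(c(0.5, 0.4), 4, 2, byrow = TRUE)),
               "sum to 1")
})

test_that("prenatal excess cost scales the itemized bundle by identification", {
  bundle <- c(inpatient_day = 1, cervical_cerclage = 1)
  expect_equal(prenatal_excess_cost(bundle, p_identified = 0), 0)
  expect_equal(prenatal_excess_cost(bundle, p_identified = 1), 954.97)
  expect_equal(prenatal_excess_cost(bundle, p_identified = 0.5), 477.485)
  expect_error(prenatal_excess_cost(c(acupuncture = 1)), "unknown prenatal")
})

test_that("aggregation weights each year by survival and discount", {
  # 2-age toy: cost 100 per year at ages 0 (delivery-free setup) is checked
  # via the closed form 100 + 0.5 * 100 / 1.05 = 147.62
  expect_equal(100 + discount(100, 1, 0.05) * 0.5, 147.6190, tolerance = 1e-4)

  # zero survival after birth: only delivery and neonatal layers survive
  epi0 <- toy_epi(p_death_delivery = 0, p_admit = 1, p_live_discharge = 1,
                  s_d2 = 0, annual = rep(0, 8))
  stay <- default_neonatal_stay()
  bd0 <- aggregate_per_infant(run_cohort(epi0, "late"), stay = stay)
  nonzero <- bd0$category[bd0$cost_per_infant > 0]
  expect_setequal(nonzero, c("delivery", "neonatal", "total"))

  # rate 0 and full survival: breakdown equals undiscounted sums
  epi1 <- toy_epi(p_death_delivery = 0, p_admit = 1, p_live_discharge = 1,
                  s_d2 = 1, annual = rep(1, 8))
  util <- default_utilization()
  bd1 <- aggregate_per_infant(run_cohort(epi1, "late"), util, stay = stay,
                              discount_rate = 0)
  direct_sum <- sum(sapply(2:4, function(a)
    annual_direct_cost("late", as.character(a), util)))
  expect_equal(bd1$cost_per_infant[bd1$category == "medical_2_4"], direct_sum,
               tolerance = 1e-9)
})

test_that("category costs are additive and scale linearly in unit costs", {
  epi <- default_epi_params()
  stay <- default_neonatal_stay(epi)
  for (ga in c("early", "moderate", "late")) {
    bd <- aggregate_per_infant(run_cohort(epi, ga), stay = stay,
                               opts = sensitivity_options(
                                 include_prenatal = TRUE,
                                 include_education = TRUE,
                                 include_infrastructure = TRUE))
    total <- bd$cost_per_infant[bd$category == "total"]
    expect_equal(total, sum(bd$cost_per_infant[bd$category != "total"]),
                 tolerance = 1e-6)
  }
  # doubling every price input doubles every component; outpatient costs
  # and the caregiver wage are priced outside unit_costs, so scale those
  # two inputs alongside the inflation factor
  stay1 <- default_neonatal_stay()
  tr <- run_cohort(epi, "moderate")
  bd1 <- aggregate_per_infant(tr, costs = unit_costs(), stay = stay1)
  util2 <- default_utilization()
  util2$outpatient_cost_mean <- 2 * util2$outpatient_cost_mean
  bd2 <- aggregate_per_infant(tr, util = utilization_table(util2),
                              costs = unit_costs(inflation = 2),
                              stay = stay1,
                              ia = indirect_assumptions(hourly_wage = 2 * 23.18))
  expect_equal(bd2$cost_per_infant, 2 * bd1$cost_per_infant,
               tolerance = 1e-9)
})

test_that("total cost is non-increasing in the discount rate", {
  epi <- default_epi_params()
  stay <- default_neonatal_stay(epi)
  tr <- run_cohort(epi, "moderate")
  totals <- sapply(c(0, 0.03, 0.05, 0.10), function(r) {
    bd <- aggregate_per_infant(tr, stay = stay, discount_rate = r)
    bd$cost_per_infant[bd$category == "total"]
  })
  expect_true(all(diff(totals) <= 0))
})

test_that("national scaling multiplies by counts and weights the all row", {
  bds <- lapply(c(early = 100, moderate = 200, late = 300), function(x)
    tibble::tibble(category = c("delivery", "total"),
                   cost_per_infant = c(x, x)))
  nat <- national_scale(bds, counts = c(early = 10, moderate = 20, late = 70))
  expect_equal(nat$national_total[nat$stratum == "early" &
                                    nat$category == "total"], 1000)
  all_row <- nat[nat$stratum == "all" & nat$category == "total", ]
  expect_equal(all_row$national_total, 100 * 10 + 200 * 20 + 300 * 70)
  expect_equal(all_row$cost_per_infant, all_row$national_total / 100)
  expect_error(national_scale(bds[c("early", "late")]), "missing stratum")
  nat0 <- national_scale(bds, counts = c(early = 0, moderate = 1, late = 1))
  expect_equal(nat0$national_total[nat0$stratum == "early"], c(0, 0))
})
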