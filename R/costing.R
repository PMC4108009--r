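## Published per-infant (all live births) delivery and neonatal costs by
## stratum, $CAD 2012, used only to back-calculate the unprinted
## delivery-mode mixes and neonatal lengths of stay (external-source
## defaults, overridable).
DELIVERY_COST_PER_INFANT <- c(early = 578, moderate = 623, late = 613)
NEONATAL_COST_PER_INFANT <- c(early = 53520, moderate = 42298, late = 3757)

## Published population counts of annual preterm live births by stratum.
PRETERM_COUNTS <- c(early = 1828L, moderate = 4685L, late = 20795L)

## National birth count and preterm shares used by the synthetic generator.
NATIONAL_LIVE_BIRTHS <- 380863L
PRETERM_SHARES <- c(early = 0.0040, moderate = 0.0114, late = 0.0619)

#' Discount a future cost to present value
#'
#' Costs are discounted at 5% annually in the base case:
#' `amount / (1 + rate)^age`.
#'
#' @param amount Cost in $CAD.
#' @param age Years after birth at which the cost is incurred.
#' @param rate Annual discount rate (fraction/year); 0 is the identity.
#' @return Present value in $CAD.
#' @export
#' @examples
#' discount(105, 1, 0.05) # 100
discount <- function(amount, age, rate = 0.05) {
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  if (any(rate <= -1)) stop("`rate` must exceed -1", call. = FALSE)
  amount / (1 + rate)^age
}

#' Neonatal infrastructure cost per infant-day
#'
#' Amortizes the cost of building a neonatal facility over its bed-days:
#' `facility_cost / (beds * lifetime_years * days_per_year)`.  At the
#' default inputs ($2.5M, 25 beds, 30 years) this is $9.13 per infant-day.
#'
#' @param facility_cost Cost of building the facility, $CAD.
#' @param beds Number of infants cared for simultaneously.
#' @param lifetime_years Effective lifetime of the facility, years.
#' @param days_per_year Days of operation per year.
#' @return $CAD per infant-day.
#' @export
infrastructure_per_diem <- function(facility_cost = 2500000, beds = 25,
                                    lifetime_years = 30, days_per_year = 365) {
  if (any(c(facility_cost, beds, lifetime_years, days_per_year) <= 0)) {
    stop("all infrastructure inputs must be positive", call. = FALSE)
  }
  facility_cost / (beds * lifetime_years * days_per_year)
}

#' Expected delivery cost over modes of delivery
#'
#' @param mode_dist Probability 4-vector over (spontaneous, instrumental,
#'   elective caesarean, emergency caesarean); must sum to one.  Named
#'   vectors are matched by name.
#' @param costs A [unit_costs()] object.
#' @return Expected delivery cost, $CAD.
#' @export
delivery_cost <- function(mode_dist, costs = unit_costs()) {
  modes <- names(costs$delivery)
  if (!is.null(names(mode_dist))) {
    bad <- setdiff(names(mode_dist), modes)
    if (length(bad) > 0) {
      stop("unknown delivery mode(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    full <- setNames(numeric(4), modes)
    full[names(mode_dist)] <- mode_dist
    mode_dist <- full
  }
  stopifnot(length(mode_dist) == 4)
  if (abs(sum(mode_dist) - 1) > 1e-9 || any(mode_dist < 0)) {
    stop("`mode_dist` must be a probability vector summing to 1",
         call. = FALSE)
  }
  sum(mode_dist * costs$delivery)
}

#' Back-calculate a delivery-mode mix from a target expected cost
#'
#' The stratified delivery-mode distributions are not published; given a
#' target expected delivery cost, this fixes the instrumental share and an
#' even elective/emergency caesarean split and solves for the spontaneous
#' versus caesarean balance.
#'
#' @param target_cost Target expected delivery cost, $CAD.
#' @param costs A [unit_costs()] object.
#' @param p_instrumental Fixed instrumental-delivery share.
#' @return Named probability 4-vector over delivery modes.
#' @export
calibrate_delivery_mix <- function(target_cost, costs = unit_costs(),
                                   p_instrumental = 0.10) {
  cs <- costs$delivery
  caes <- (cs[["elective_caesarean"]] + cs[["emergency_caesarean"]]) / 2
  rest <- 1 - p_instrumental
  ## target = p_instr*instr + p_spont*spont + (rest - p_spont)*caes
  p_spont <- (p_instrumental * cs[["instrumental"]] + rest * caes - target_cost) /
    (caes - cs[["spontaneous"]])
  if (p_spont < 0 || p_spont > rest) {
    stop("target delivery cost ", target_cost,
         " is not attainable with the given mode costs", call. = FALSE)
  }
  c(spontaneous = p_spont, instrumental = p_instrumental,
    elective_caesarean = (rest - p_spont) / 2,
    emergency_caesarean = (rest - p_spont) / 2)
}

#' Neonatal stay parameters
#'
#' Per-stratum mean neonatal intensive and normal care days per admitted
#' infant, plus the delivery-mode distribution.
#'
#' @param strata Named list per stratum with elements
#'   `mean_intensive_days`, `mean_normal_days`, `delivery_mode_dist`.
#' @param source_flags Provenance tags.
#' @return An object of class `neonatal_stay_params`.
#' @export
neonatal_stay_params <- function(strata, source_flags = character()) {
  stopifnot(setequal(names(strata), GA_LEVELS))
  for (ga in GA_LEVELS) {
    st <- strata[[ga]]
    stopifnot(st$mean_intensive_days >= 0, st$mean_normal_days >= 0)
    if (abs(sum(st$delivery_mode_dist) - 1) > 1e-9) {
      stop("delivery-mode distribution for ", ga, " must sum to 1",
           call. = FALSE)
    }
  }
  structure(list(strata = strata[GA_LEVELS], source_flags = source_flags),
            class = "neonatal_stay_params")
}

#' Default (calibrated) neonatal stay parameters
#'
#' Neonatal lengths of stay and delivery-mode mixes are not published;
#' the defaults are back-calculated so that, combined with the default
#' epidemiology and unit costs, the per-live-birth delivery and neonatal
#' costs reproduce the published stratum values ($578/623/613 delivery;
#' $53,520/42,298/3,757 neonatal).  The split of stay days between the
#' intensive and normal tiers uses assumed intensive-day fractions.
#'
#' @param epi An `epi_params` object (supplies the admitted-alive fraction
#'   per stratum).
#' @param costs A [unit_costs()] object.
#' @param intensive_frac Named fractions of neonatal days in intensive care.
#' @return A `neonatal_stay_params` object.
#' @export
default_neonatal_stay <- function(epi = default_epi_params(),
                                  costs = unit_costs(),
                                  intensive_frac = c(early = 0.70,
                                                     moderate = 0.55,
                                                     late = 0.25)) {
  assert_epi_params(epi)
  strata <- lapply(GA_LEVELS, function(ga) {
    sp <- epi$strata[[ga]]
    p_admitted <- (1 - sp$p_death_delivery) * sp$p_admit_neonatal
    per_admitted <- NEONATAL_COST_PER_INFANT[[ga]] / p_admitted
    f <- intensive_frac[[ga]]
    blended <- f * costs$neonatal[["intensive_day"]] +
      (1 - f) * costs$neonatal[["normal_day"]]
    total_days <- per_admitted / blended
    list(
      mean_intensive_days = f * total_days,
      mean_normal_days = (1 - f) * total_days,
      delivery_mode_dist = calibrate_delivery_mix(
        DELIVERY_COST_PER_INFANT[[ga]], costs)
    )
  })
  names(strata) <- GA_LEVELS
  neonatal_stay_params(strata, source_flags = c(
    mean_intensive_days = "external-reference",
    mean_normal_days = "external-reference",
    delivery_mode_dist = "external-reference"
  ))
}

#' Neonatal care cost per admitted infant
#'
#' Intensive days plus normal-care days at their per-diems; when the
#' infrastructure layer is switched on, the amortized facility per-diem is
#' added for every day of stay.
#'
#' @param ga Stratum label.
#' @param stay A `neonatal_stay_params` object.
#' @param costs A [unit_costs()] object.
#' @param opts A [sensitivity_options()] object.
#' @return $CAD per admitted infant.
#' @export
neonatal_cost <- function(ga, stay = default_neonatal_stay(),
                          costs = unit_costs(),
                          opts = sensitivity_options()) {
  st <- stay$strata[[ga]]
  if (is.null(st)) stop("no neonatal stay entry for stratum ", ga, call. = FALSE)
  base <- st$mean_intensive_days * costs$neonatal[["intensive_day"]] +
    st$mean_normal_days * costs$neonatal[["normal_day"]]
  if (isTRUE(opts$include_infrastructure)) {
    base <- base + (st$mean_intensive_days + st$mean_normal_days) *
      infrastructure_per_diem(opts$facility_cost, opts$beds,
                              opts$lifetime_years, opts$days_per_year)
  }
  base
}

#' Annual direct medical cost per surviving infant
#'
#' For the discharge-to-age-2 state, all inpatient days (including any PICU
#' days) are priced at the general post-discharge per-diem and outpatient
#' billed costs are added.  For annual states ages 2 onward, PICU days,
#' other inpatient days and in-hospital procedures are priced separately,
#' plus outpatient billed costs.
#'
#' @param ga Stratum label.
#' @param period Age period: `"discharge_to_2"` or `"2"` ... `"9"`.
#' @param util A [utilization_table()].
#' @param costs A [unit_costs()] object.
#' @return $CAD per infant surviving to the period.
#' @export
annual_direct_cost <- function(ga, period, util = default_utilization(),
                               costs = unit_costs()) {
  cell <- utilization_cell(util, ga, period)
  pd <- costs$post_discharge
  if (period == "discharge_to_2") {
    (cell$inpatient_days_mean + cell$picu_days_mean) * pd[["inpatient_day"]] +
      cell$outpatient_cost_mean
  } else {
    cell$picu_days_mean * pd[["picu_day"]] +
      cell$inpatient_days_mean * pd[["inpatient_day"]] +
      cell$procedures_mean * pd[["procedure"]] +
      cell$outpatient_cost_mean
  }
}

#' Annual indirect (lost-productivity) cost per surviving infant
#'
#' Caregiver hours off work attached to outpatient visits and inpatient
#' days (PICU days included), valued at the hourly wage.
#'
#' @param util_cell One row of a utilization table (or any list with
#'   `outpatient_visits_mean`, `inpatient_days_mean`, `picu_days_mean`).
#' @param ia An [indirect_assumptions()] object.
#' @return $CAD per infant surviving to the period.
#' @export
annual_indirect_cost <- function(util_cell, ia = indirect_assumptions()) {
  visits <- util_cell$outpatient_visits_mean
  days <- util_cell$inpatient_days_mean +
    (util_cell$picu_days_mean %||% 0)
  if (any(c(visits, days) < 0)) {
    stop("utilization counts must be non-negative", call. = FALSE)
  }
  (visits * ia$hours_per_outpatient_visit +
     days * ia$hours_per_inpatient_day) * ia$hourly_wage
}

#' Annual education cost given a disability distribution
#'
#' Expectation over disability level and school type of the annual school
#' cost (mainstream vs special school).
#'
#' @param disability_dist Probability 4-vector over disability levels.
#' @param school_dist 4x2 matrix of school-type shares by level (rows sum
#'   to one).
#' @param costs A [unit_costs()] object.
#' @return $CAD per surviving child per school year.
#' @export
education_cost <- function(disability_dist,
                           school_dist = DEFAULT_SCHOOL_DIST,
                           costs = unit_costs()) {
  stopifnot(length(disability_dist) == 4)
  if (any(abs(rowSums(school_dist) - 1) > 1e-9)) {
    stop("each school-type distribution must sum to 1", call. = FALSE)
  }
  per_level <- school_dist %*% c(costs$education[["mainstream_year"]],
                                 costs$education[["special_year"]])
  sum(disability_dist * per_level)
}

#' Excess prenatal cost per preterm birth
#'
#' Itemized prenatal resource counts for an identified high-risk pregnancy,
#' priced at the prenatal unit costs and scaled by the share of preterm
#' births identified as high-risk (50% in the base assumption).
#'
#' @param bundle Named non-negative counts; names must match the prenatal
#'   unit-cost items.
#' @param costs A [unit_costs()] object.
#' @param p_identified Share of preterm births with excess prenatal care.
#' @return $CAD per preterm birth.
#' @export
prenatal_excess_cost <- function(bundle = DEFAULT_PRENATAL_BUNDLE,
                                 costs = unit_costs(), p_identified = 0.5) {
  assert_prob(p_identified, "p_identified")
  bad <- setdiff(names(bundle), names(costs$prenatal))
  if (length(bad) > 0) {
    stop("unknown prenatal item(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(bundle < 0)) stop("prenatal counts must be non-negative", call. = FALSE)
  p_identified * sum(bundle * costs$prenatal[names(bundle)])
}

#' Survival-weighted, discounted cost breakdown per live birth
#'
#' Aggregates every cost layer for one stratum into a per-infant breakdown
#' whose denominator is all live births: each age-specific component is
#' weighted by the fraction of live births surviving to that age and
#' discounted back to birth.  Delivery costs apply to every live birth at
#' age 0; neonatal costs to the admitted-alive fraction at age 0; the
#' discharge-to-age-2 component is discounted at age 1 (the period
#' midpoint) and weighted by the age-1 survival fraction; annual components
#' accrue at ages 2 through 9.  Optional layers (prenatal, education) are
#' included per the sensitivity options.
#'
#' @param traj A `cohort_trajectory` from [run_cohort()].
#' @param util A [utilization_table()].
#' @param costs A [unit_costs()] object.
#' @param stay A `neonatal_stay_params` object.
#' @param ia An [indirect_assumptions()] object.
#' @param opts A [sensitivity_options()] object.
#' @param discount_rate Annual discount rate.
#' @return A tibble of class `cost_breakdown` with columns `category` and
#'   `cost_per_infant`, ending in a `total` row; the stratum and rate are
#'   stored as attributes.
#' @export
aggregate_per_infant <- function(traj, util = default_utilization(),
                                 costs = unit_costs(),
                                 stay = default_neonatal_stay(),
                                 ia = indirect_assumptions(),
                                 opts = sensitivity_options(),
                                 discount_rate = 0.05) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  ga <- traj$ga
  have <- util$period[util$ga == ga]
  missing_periods <- setdiff(AGE_PERIODS, have)
  if (length(missing_periods) > 0) {
    stop("utilization table does not cover period(s) ",
         paste(missing_periods, collapse = ", "), " for stratum ", ga,
         call. = FALSE)
  }
  s <- traj$survival_by_age

  w_disc <- function(x, age) s[[as.character(age)]] * discount(x, age, discount_rate)

  comp <- c(
    delivery = delivery_cost(stay$strata[[ga]]$delivery_mode_dist, costs),
    neonatal = traj$p_admitted * neonatal_cost(ga, stay, costs, opts),
    discharge_to_age2 = w_disc(
      annual_direct_cost(ga, "discharge_to_2", util, costs), 1)
  )

  direct_at <- function(a) w_disc(annual_direct_cost(ga, as.character(a), util, costs), a)
  indirect_at <- function(a) {
    if (a < ia$start_age) return(0)
    w_disc(annual_indirect_cost(utilization_cell(util, ga, as.character(a)), ia), a)
  }
  comp[["medical_2_4"]] <- sum(vapply(2:4, direct_at, numeric(1)))
  comp[["indirect_2_4"]] <- sum(vapply(2:4, indirect_at, numeric(1)))
  comp[["medical_5_10"]] <- sum(vapply(5:9, direct_at, numeric(1)))
  comp[["indirect_5_10"]] <- sum(vapply(5:9, indirect_at, numeric(1)))

  if (isTRUE(opts$include_prenatal)) {
    comp[["prenatal"]] <- prenatal_excess_cost(opts$prenatal_bundle, costs,
                                               opts$p_identified_high_risk)
  }
  if (isTRUE(opts$include_education)) {
    edu_ages <- seq(max(2, opts$education_start_age), 9)
    comp[["education"]] <- sum(vapply(edu_ages, function(a) {
      w_disc(education_cost(disability_distribution_at(traj, a),
                            opts$school_dist, costs), a)
    }, numeric(1)))
  }

  out <- tibble(category = c(names(comp), "total"),
                cost_per_infant = c(unname(comp), sum(comp)))
  structure(out, class = c("cost_breakdown", class(out)),
            ga = ga, discount_rate = discount_rate)
}

#' Scale per-infant breakdowns to national totals
#'
#' Multiplies per-infant costs by the stratum population counts and adds an
#' `all` column: the all-preterm national total is the sum over strata and
#' its per-infant cost is the population-weighted average.
#'
#' @param breakdowns Named list of `cost_breakdown` tibbles, one per
#'   stratum (names `early`, `moderate`, `late`).
#' @param counts Named positive integer counts of annual live preterm
#'   births per stratum.
#' @return A tibble with columns `category`, `stratum`, `cost_per_infant`,
#'   `national_total`, including the `all` stratum.
#' @export
national_scale <- function(breakdowns, counts = PRETERM_COUNTS) {
  missing_strata <- setdiff(GA_LEVELS, names(breakdowns))
  if (length(missing_strata) > 0) {
    stop("missing stratum breakdown(s): ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  }
  if (!all(GA_LEVELS %in% names(counts)) || any(counts[GA_LEVELS] < 0)) {
    stop("`counts` must hold non-negative counts for every stratum",
         call. = FALSE)
  }
  per_stratum <- purrr::map_dfr(GA_LEVELS, function(ga) {
    bd <- breakdowns[[ga]]
    tibble(category = bd$category, stratum = ga,
           cost_per_infant = bd$cost_per_infant,
           national_total = bd$cost_per_infant * counts[[ga]])
  })
  n_all <- sum(counts[GA_LEVELS])
  all_row <- per_stratum |>
    group_by(.data$category) |>
    summarise(stratum = "all",
              national_total = sum(.data$national_total),
              cost_per_infant = if (n_all > 0) {
                sum(.data$national_total) / n_all
              } else 0,
              .groups = "drop") |>
    select("category", "stratum", "cost_per_infant", "national_total")
  bind_rows(all_row, per_stratum) |>
    mutate(stratum = factor(.data$stratum, levels = c("all", GA_LEVELS))) |>
    arrange(match(.data$category, unique(per_stratum$category)), .data$stratum)
}
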