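## Unit costs, $CAD 2012 (Ontario sources; physician billings per outpatient
## visit are taken directly from the claims data and so have no unit cost).
DEFAULT_UNIT_COSTS <- list(
  prenatal = c(
    inpatient_day = 809.87,
    midwife_visit = 23.20,
    obstetrician_visit = 101.70,
    cervical_cerclage = 145.10,
    beta_agonist = 6.00,
    oxytocin_antagonist = 67.75
  ),
  delivery = c(
    spontaneous = 498.70,
    instrumental = 625.66,
    elective_caesarean = 757.11,
    emergency_caesarean = 786.51
  ),
  neonatal = c(
    intensive_day = 1628.60,
    normal_day = 388.00
  ),
  post_discharge = c(
    inpatient_day = 628.49,
    picu_day = 2002.86,
    procedure = 111.88
  ),
  education = c(
    mainstream_year = 7720.05,
    special_year = 15666.45
  ),
  wages = c(
    male_ft = 26.33,
    female_ft = 23.18,
    male_pt = 15.62,
    female_pt = 17.36
  )
)

#' Unit costs ($CAD 2012)
#'
#' Nested unit-cost table for all expenditure layers: prenatal items for
#' women at risk of preterm labour, modes of delivery, neonatal care
#' per-diems (intensive and normal tiers), post-discharge care (general
#' inpatient and paediatric ICU per-diems, in-hospital procedures), annual
#' education costs (mainstream vs special school) and hourly wages used for
#' indirect costs.  Defaults are the published 2012 Ontario values; any
#' entry can be overridden.
#'
#' @param ... Named group overrides, e.g.
#'   `neonatal = c(intensive_day = 1700)`: named entries within a group are
#'   replaced, the rest keep their defaults.
#' @param inflation Scalar factor applied to every unit cost (default 1).
#' @return An object of class `unit_costs`.
#' @export
#' @examples
#' costs <- unit_costs()
#' costs$delivery[["spontaneous"]]
unit_costs <- function(..., inflation = 1) {
  stopifnot(is.numeric(inflation), length(inflation) == 1, inflation > 0)
  out <- DEFAULT_UNIT_COSTS
  dots <- list(...)
  for (grp in names(dots)) {
    if (!grp %in% names(out)) {
      stop("unknown unit-cost group: ", grp, call. = FALSE)
    }
    repl <- dots[[grp]]
    bad <- setdiff(names(repl), names(out[[grp]]))
    if (length(bad) > 0) {
      stop("unknown unit-cost item(s) in `", grp, "`: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    out[[grp]][names(repl)] <- repl
  }
  out <- lapply(out, function(g) g * inflation)
  if (any(unlist(out) < 0)) stop("unit costs must be non-negative", call. = FALSE)
  structure(out, class = "unit_costs")
}

#' Assumptions linking medical contacts to caregiver time off work
#'
#' Indirect (lost-productivity) costs attach two hours off work to each
#' outpatient visit and eight hours to each inpatient day, valued at the
#' full-time female hourly wage, and accrue from age two onwards (a
#' full-time caregiver is assumed available before age two).
#'
#' @param hours_per_outpatient_visit Hours off work per outpatient visit.
#' @param hours_per_inpatient_day Hours off work per inpatient day.
#' @param hourly_wage Hourly wage in $CAD.
#' @param start_age First age (years) at which indirect costs accrue.
#' @return An object of class `indirect_assumptions`.
#' @export
indirect_assumptions <- function(hours_per_outpatient_visit = 2,
                                 hours_per_inpatient_day = 8,
                                 hourly_wage = 23.18,
                                 start_age = 2) {
  stopifnot(hours_per_outpatient_visit > 0, hours_per_inpatient_day > 0,
            hourly_wage > 0, start_age >= 0)
  structure(
    list(hours_per_outpatient_visit = hours_per_outpatient_visit,
         hours_per_inpatient_day = hours_per_inpatient_day,
         hourly_wage = hourly_wage, start_age = start_age),
    class = "indirect_assumptions"
  )
}

## Distribution of school type (mainstream, special) by disability level,
## used when education costs are switched on.  The published supplementary
## distribution is not reproduced here; this synthetic default preserves its
## qualitative pattern (special schooling concentrated in severe disability).
DEFAULT_SCHOOL_DIST <- matrix(
  c(1.00, 0.00,
    0.85, 0.15,
    0.50, 0.50,
    0.10, 0.90),
  nrow = 4, byrow = TRUE,
  dimnames = list(DISABILITY_LEVELS, c("mainstream", "special"))
)

## Itemized prenatal resource counts per identified high-risk pregnancy.
## Synthetic default (the published supplementary bundle is not public).
DEFAULT_PRENATAL_BUNDLE <- c(
  inpatient_day = 2, midwife_visit = 2, obstetrician_visit = 3,
  cervical_cerclage = 0.1, beta_agonist = 1, oxytocin_antagonist = 0.2
)

#' Options for costs considered in sensitivity analysis
#'
#' Controls the three cost layers outside the base case: excess prenatal
#' costs (assumed to apply to 50% of preterm births, those identified as
#' high-risk in pregnancy), education costs from age five onwards, and the
#' neonatal infrastructure per-diem derived from building a $2.5M,
#' 25-bed facility with a 30-year lifetime.
#'
#' @param include_prenatal,include_education,include_infrastructure Logical
#'   switches; all `FALSE` in the base case.
#' @param p_identified_high_risk Share of preterm births with excess
#'   prenatal resource use.
#' @param prenatal_bundle Named counts of prenatal items (names must match
#'   the prenatal unit-cost items).
#' @param education_start_age First age with education costs.
#' @param school_dist 4x2 matrix of school-type shares by disability level
#'   (rows sum to one).
#' @param facility_cost,beds,lifetime_years,days_per_year Inputs to the
#'   infrastructure per-diem.
#' @return An object of class `sensitivity_options`.
#' @export
sensitivity_options <- function(include_prenatal = FALSE,
                                p_identified_high_risk = 0.5,
                                prenatal_bundle = DEFAULT_PRENATAL_BUNDLE,
                                include_education = FALSE,
                                education_start_age = 5,
                                school_dist = DEFAULT_SCHOOL_DIST,
                                include_infrastructure = FALSE,
                                facility_cost = 2500000,
                                beds = 25,
                                lifetime_years = 30,
                                days_per_year = 365) {
  assert_prob(p_identified_high_risk, "p_identified_high_risk")
  stopifnot(facility_cost > 0, beds > 0, lifetime_years > 0, days_per_year > 0)
  stopifnot(is.matrix(school_dist), nrow(school_dist) == 4,
            ncol(school_dist) == 2,
            all(abs(rowSums(school_dist) - 1) < 1e-9))
  structure(
    list(include_prenatal = include_prenatal,
         p_identified_high_risk = p_identified_high_risk,
         prenatal_bundle = prenatal_bundle,
         include_education = include_education,
         education_start_age = education_start_age,
         school_dist = school_dist,
         include_infrastructure = include_infrastructure,
         facility_cost = facility_cost, beds = beds,
         lifetime_years = lifetime_years, days_per_year = days_per_year),
    class = "sensitivity_options"
  )
}
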