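WARD_LEVELS <- c("neonatal_intensive", "neonatal_normal", "picu", "general")

EXCLUSION_REASONS <- c("birth_transfer",
                       "early_moderate_no_neonatal_hospitalization",
                       "no_followup_no_death")

#' Linked claims tables
#'
#' Bundles the four linked delimited tables the analysis consumes: an
#' infant registry, hospital episodes, outpatient physician-billing claims
#' and death records, joined on `infant_id`.  Construction validates
#' linkage (episodes, claims or deaths for unknown infants raise an error
#' listing the orphan ids) and the per-table invariants.
#'
#' @param registry Tibble: `infant_id`, `ga_weeks` (20--36), `birth_date`
#'   (Date), `transfer_at_birth` (logical).
#' @param episodes Tibble: `infant_id`, `admit_date`, `discharge_date`,
#'   `ward` (one of neonatal_intensive / neonatal_normal / picu / general),
#'   `procedure_count`, `is_birth_episode`.
#' @param claims Tibble: `infant_id`, `service_date`, `billed_amount`.
#' @param deaths Tibble: `infant_id`, `death_date`.
#' @return An object of class `claims_bundle`.
#' @export
claims_bundle <- function(registry, episodes, claims, deaths) {
  registry <- as_tibble(registry); episodes <- as_tibble(episodes)
  claims <- as_tibble(claims); deaths <- as_tibble(deaths)

  orphan <- function(tbl, what) {
    bad <- setdiff(unique(tbl$infant_id), registry$infant_id)
    if (length(bad) > 0) {
      stop("linkage error: ", what, " reference unknown infant id(s): ",
           paste(head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  orphan(episodes, "hospital episodes")
  orphan(claims, "outpatient claims")
  orphan(deaths, "death records")

  if (nrow(registry) > 0) assign_ga_category(registry$ga_weeks)
  if (any(duplicated(registry$infant_id))) {
    stop("duplicate infant ids in registry", call. = FALSE)
  }
  if (nrow(episodes) > 0) {
    stopifnot(all(episodes$ward %in% WARD_LEVELS),
              all(episodes$procedure_count >= 0))
    if (any(episodes$discharge_date < episodes$admit_date)) {
      stop("episode discharge before admission", call. = FALSE)
    }
  }
  if (nrow(claims) > 0 && any(claims$billed_amount < 0)) {
    stop("negative billed amounts", call. = FALSE)
  }
  if (nrow(deaths) > 0) {
    dd <- left_join(deaths, registry[, c("infant_id", "birth_date")],
                    by = "infant_id")
    if (any(dd$death_date < dd$birth_date)) {
      stop("death before birth", call. = FALSE)
    }
  }
  structure(list(registry = registry, episodes = episodes,
                 claims = claims, deaths = deaths),
            class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>", nrow(x$registry), "infants,",
      nrow(x$episodes), "episodes,", nrow(x$claims), "claims,",
      nrow(x$deaths), "deaths\n")
  invisible(x)
}

#' Apply the cohort exclusion rules
#'
#' Builds the analysis cohort: infants with a recorded transfer to another
#' hospital during the birth hospitalization are excluded; early and
#' moderate preterm infants with no record of a neonatal (birth)
#' hospitalization are excluded (assumed to have died before admission or
#' been lost to follow-up), while late preterm infants without one are
#' retained and flagged as discharged directly home; infants with no
#' medical or hospital contact after the birth hospitalization and no death
#' record are excluded.  Each excluded infant receives exactly one reason
#' code, assigned in that order of precedence.
#'
#' @param bundle A [claims_bundle()].
#' @return A list of class `preterm_cohort` with elements `bundle` (the
#'   included subset), `direct_home` (character ids), and `exclusions`
#'   (tibble `infant_id`, `reason`).
#' @export
apply_exclusions <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  reg <- bundle$registry
  ga <- as.character(assign_ga_category(reg$ga_weeks))

  has_birth_ep <- reg$infant_id %in%
    bundle$episodes$infant_id[bundle$episodes$is_birth_episode]
  has_later_ep <- reg$infant_id %in%
    bundle$episodes$infant_id[!bundle$episodes$is_birth_episode]
  has_claim <- reg$infant_id %in% bundle$claims$infant_id
  has_death <- reg$infant_id %in% bundle$deaths$infant_id

  reason <- rep(NA_character_, nrow(reg))
  reason[is.na(reason) & reg$transfer_at_birth] <- "birth_transfer"
  reason[is.na(reason) & !has_birth_ep & ga %in% c("early", "moderate")] <-
    "early_moderate_no_neonatal_hospitalization"
  reason[is.na(reason) & !has_later_ep & !has_claim & !has_death] <-
    "no_followup_no_death"

  keep <- is.na(reason)
  ids <- reg$infant_id[keep]
  cohort_bundle <- claims_bundle(
    registry = reg[keep, ],
    episodes = filter(bundle$episodes, .data$infant_id %in% ids),
    claims = filter(bundle$claims, .data$infant_id %in% ids),
    deaths = filter(bundle$deaths, .data$infant_id %in% ids)
  )
  structure(
    list(bundle = cohort_bundle,
         direct_home = reg$infant_id[keep & !has_birth_ep & ga == "late"],
         exclusions = tibble(infant_id = reg$infant_id[!keep],
                             reason = reason[!keep])),
    class = "preterm_cohort"
  )
}

## Assigns day offsets (days since birth) to age periods; offsets at or
## past the 10th birthday fall outside the accrual horizon (NA).
period_of_day <- function(day) {
  breaks <- c(0, vapply(2:10, birthday_offset, integer(1)))
  as.character(cut(day, breaks = breaks, labels = AGE_PERIODS,
                   right = FALSE))
}

## Inpatient day counting: date difference (nights), minimum one day for
## same-day stays.
episode_days <- function(admit, discharge) {
  pmax(1L, as.integer(discharge - admit))
}

#' Estimate stratified utilization means and standard errors
#'
#' Assigns every post-birth-hospitalization event to an age period by its
#' date relative to the infant's birth (age-k boundaries at
#' `round(k * 365.25)` days) and computes, per (stratum, period), the mean
#' and standard error of inpatient days (non-PICU wards), PICU days,
#' in-hospital procedures, outpatient billed costs and outpatient visits
#' (distinct claim service dates).  The denominator of each cell is the set
#' of infants surviving to that age (alive on the k-th birthday; the
#' discharge-to-age-2 cell uses survivors to age two); surviving infants
#' with no events contribute zeros.  The birth hospitalization itself is
#' excluded.  SE is the sample SD over the denominator divided by sqrt(n)
#' (0 when n = 1); cells with an empty denominator are reported as missing
#' (NA), not zero.
#'
#' @param cohort A `preterm_cohort` from [apply_exclusions()].
#' @return A [utilization_table()] including the `n` denominators.
#' @export
compute_utilization <- function(cohort) {
  stopifnot(inherits(cohort, "preterm_cohort"))
  b <- cohort$bundle
  reg <- b$registry
  if (nrow(reg) == 0) stop("cohort is empty", call. = FALSE)

  inf <- reg |>
    mutate(ga = as.character(assign_ga_category(.data$ga_weeks))) |>
    left_join(b$deaths, by = "infant_id") |>
    mutate(death_day = if_else(is.na(.data$death_date),
                               Inf,
                               as.numeric(.data$death_date - .data$birth_date)))

  ## discharge day of the birth hospitalization (0 for direct-home infants)
  birth_eps <- filter(b$episodes, .data$is_birth_episode)
  disch0 <- if (nrow(birth_eps) == 0) {
    tibble(infant_id = character(), disch0 = numeric())
  } else {
    birth_eps |>
      left_join(reg[, c("infant_id", "birth_date")], by = "infant_id") |>
      mutate(disch0 = as.numeric(.data$discharge_date - .data$birth_date)) |>
      group_by(.data$infant_id) |>
      summarise(disch0 = max(.data$disch0), .groups = "drop")
  }
  inf <- inf |>
    left_join(disch0, by = "infant_id") |>
    mutate(disch0 = if_else(is.na(.data$disch0), 0, .data$disch0))

  ep <- b$episodes |>
    filter(!.data$is_birth_episode) |>
    left_join(inf[, c("infant_id", "birth_date", "disch0")], by = "infant_id") |>
    mutate(day = as.numeric(.data$admit_date - .data$birth_date)) |>
    filter(.data$day >= .data$disch0) |>
    mutate(period = period_of_day(.data$day),
           days = episode_days(.data$admit_date, .data$discharge_date)) |>
    filter(!is.na(.data$period)) |>
    group_by(.data$infant_id, .data$period) |>
    summarise(
      inpatient_days = sum(.data$days[.data$ward != "picu"]),
      picu_days = sum(.data$days[.data$ward == "picu"]),
      procedures = sum(.data$procedure_count),
      .groups = "drop")

  cl <- b$claims |>
    left_join(inf[, c("infant_id", "birth_date", "disch0")], by = "infant_id") |>
    mutate(day = as.numeric(.data$service_date - .data$birth_date)) |>
    filter(.data$day >= .data$disch0) |>
    mutate(period = period_of_day(.data$day)) |>
    filter(!is.na(.data$period)) |>
    group_by(.data$infant_id, .data$period) |>
    summarise(outpatient_cost = sum(.data$billed_amount),
              outpatient_visits = n_distinct(.data$service_date),
              .groups = "drop")

  ## survivor denominators: one row per (infant, period) the infant reaches
  req_age <- setNames(c(2, 2:9), AGE_PERIODS)
  grid <- tidyr::crossing(
    inf[, c("infant_id", "ga", "death_day")],
    tibble(period = AGE_PERIODS)
  ) |>
    filter(.data$death_day >= vapply(req_age[.data$period],
                                     birthday_offset, integer(1)))

  full <- grid |>
    left_join(ep, by = c("infant_id", "period")) |>
    left_join(cl, by = c("infant_id", "period")) |>
    mutate(across(all_of(UTIL_COLUMNS), ~ if_else(is.na(.x), 0, as.numeric(.x))))

  se_of <- function(x) if (length(x) <= 1) 0 else sd(x) / sqrt(length(x))
  stats <- full |>
    group_by(.data$ga, .data$period) |>
    summarise(across(all_of(UTIL_COLUMNS),
                     list(mean = mean, se = se_of),
                     .names = "{.col}_{.fn}"),
              n = dplyr::n(), .groups = "drop")

  ## strata present in the cohort get a row for every period; empty cells
  ## are missing, not zero
  stats <- stats |>
    tidyr::complete(ga = unique(inf$ga), period = AGE_PERIODS,
                    fill = list(n = 0L)) |>
    mutate(period = factor(.data$period, levels = AGE_PERIODS)) |>
    arrange(.data$ga, .data$period) |>
    mutate(period = as.character(.data$period))

  utilization_table(stats)
}

#' Write the exclusion log as delimited text
#'
#' @param cohort A `preterm_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  readr::write_csv(cohort$exclusions, path)
  invisible(path)
}
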