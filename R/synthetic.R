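GA_WEEK_RANGES <- list(early = 23:27, moderate = 28:32, late = 33:36)

#' Configuration for the synthetic claims generator
#'
#' Describes a linked physician-billing / hospital-discharge cohort with
#' the statistical structure the analysis assumes: a 1996--97 birth cohort
#' of preterm infants followed to age ten, with gestational-age-dependent
#' mortality (taken from an [epi_params()] set) and per-period utilization
#' drawn from an over-dispersible count model whose cell means default to
#' the published utilization table.
#'
#' Utilization counts are negative binomial (`size` is the dispersion
#' parameter; large values approach Poisson).  Outpatient billed amounts
#' per visit are gamma with mean `amount_per_visit`, so per-period expected
#' outpatient cost equals the visit-mean target times `amount_per_visit`,
#' matching the published cost means.  In-hospital procedures are drawn
#' only for infant-periods with an inpatient stay.  Utilization is drawn
#' for infants alive at the end of each period (the survivor denominators
#' used downstream); infants dying mid-period contribute no events, so no
#' event ever postdates a death.
#'
#' @param n_infants Number of preterm infants to simulate.
#' @param stratum_counts Optional named counts per stratum (overrides
#'   `n_infants`/`stratum_shares`); use e.g. `c(early = 0, moderate = 0,
#'   late = 20000)` for a single-stratum cohort.
#' @param stratum_shares Relative shares of the three strata among preterm
#'   births (defaults to the published 0.40/1.14/6.19% birth shares,
#'   renormalized).
#' @param epi An [epi_params()] set supplying mortality.
#' @param utilization_targets A [utilization_table()] of target cell means.
#' @param neonatal_los_mean Named mean birth-hospitalization length of stay
#'   (days) per stratum for admitted infants.
#' @param procedures_per_hospitalization Mean procedures per infant-period
#'   with an inpatient stay.
#' @param size_days,size_visits,size_procedures Negative-binomial dispersion
#'   per endpoint.
#' @param amount_per_visit,amount_shape Gamma model for billed amounts.
#' @param p_birth_transfer Probability an infant is flagged as transferred
#'   during the birth hospitalization.
#' @param p_lost_to_followup Probability all post-birth-hospitalization
#'   records (and any death record) are missing.
#' @param seed Integer seed; identical (config, seed) gives byte-identical
#'   output.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_infants = 10000,
                             stratum_counts = NULL,
                             stratum_shares = PRETERM_SHARES,
                             epi = default_epi_params(),
                             utilization_targets = default_utilization(),
                             neonatal_los_mean = c(early = 53, moderate = 42,
                                                   late = 9),
                             procedures_per_hospitalization = 0.5,
                             size_days = 1,
                             size_visits = 1,
                             size_procedures = 1,
                             amount_per_visit = DEFAULT_AMOUNT_PER_VISIT,
                             amount_shape = 4,
                             p_birth_transfer = 0.01,
                             p_lost_to_followup = 0.02,
                             seed = 1L) {
  assert_epi_params(epi)
  assert_prob(p_birth_transfer, "p_birth_transfer")
  assert_prob(p_lost_to_followup, "p_lost_to_followup")
  stopifnot(n_infants >= 0,
            all(stratum_shares >= 0), sum(stratum_shares) > 0,
            all(neonatal_los_mean > 0),
            procedures_per_hospitalization >= 0,
            size_days > 0, size_visits > 0, size_procedures > 0,
            amount_per_visit > 0, amount_shape > 0)
  if (!is.null(stratum_counts)) {
    stopifnot(setequal(names(stratum_counts), GA_LEVELS),
              all(stratum_counts >= 0))
  }
  structure(
    list(n_infants = as.integer(n_infants),
         stratum_counts = stratum_counts,
         stratum_shares = stratum_shares / sum(stratum_shares),
         epi = epi, utilization_targets = utilization_targets,
         neonatal_los_mean = neonatal_los_mean,
         procedures_per_hospitalization = procedures_per_hospitalization,
         size_days = size_days, size_visits = size_visits,
         size_procedures = size_procedures,
         amount_per_visit = amount_per_visit, amount_shape = amount_shape,
         p_birth_transfer = p_birth_transfer,
         p_lost_to_followup = p_lost_to_followup,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

empty_bundle <- function() {
  claims_bundle(
    registry = tibble(infant_id = character(), ga_weeks = integer(),
                      birth_date = as.Date(character()),
                      transfer_at_birth = logical()),
    episodes = tibble(infant_id = character(),
                      admit_date = as.Date(character()),
                      discharge_date = as.Date(character()),
                      ward = character(), procedure_count = integer(),
                      is_birth_episode = logical()),
    claims = tibble(infant_id = character(),
                    service_date = as.Date(character()),
                    billed_amount = double()),
    deaths = tibble(infant_id = character(),
                    death_date = as.Date(character()))
  )
}

#' Generate a synthetic linked claims cohort
#'
#' Simulates each infant through the stages of the cohort model
#' (delivery-room death, neonatal admission and death, discharge, annual
#' survival), then draws per-period utilization for survivors and dates
#' every event consistently with the birth date.  See
#' [generator_config()] for the statistical model.
#'
#' @param config A [generator_config()].
#' @return A [claims_bundle()].
#' @export
#' @examples
#' cfg <- generator_config(n_infants = 200, seed = 42)
#' bundle <- generate_cohort(cfg)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)

  if (!is.null(config$stratum_counts)) {
    n_by <- config$stratum_counts[GA_LEVELS]
  } else {
    n_by <- as.integer(stats::rmultinom(1, config$n_infants,
                                        config$stratum_shares[GA_LEVELS]))
    names(n_by) <- GA_LEVELS
  }
  n <- sum(n_by)
  if (n == 0) return(empty_bundle())

  ga <- rep(GA_LEVELS, times = n_by)
  ga_weeks <- unlist(lapply(GA_LEVELS, function(g) {
    wk <- GA_WEEK_RANGES[[g]]
    wk[1 + (stats::runif(n_by[[g]]) * length(wk)) %/% 1]
  }))
  birth_days <- seq(as.Date("1996-01-01"), as.Date("1997-12-31"), by = "day")
  birth_date <- birth_days[sample.int(length(birth_days), n, replace = TRUE)]
  infant_id <- sprintf("I%07d", seq_len(n))

  par_of <- function(field) {
    vapply(config$epi$strata, function(st) st[[field]], numeric(1))[ga]
  }
  dies_delivery <- rbinom(n, 1, par_of("p_death_delivery")) == 1
  admitted <- !dies_delivery & rbinom(n, 1, par_of("p_admit_neonatal")) == 1
  nicu_death <- admitted &
    rbinom(n, 1, 1 - par_of("p_live_discharge_neonatal")) == 1

  los <- integer(n)
  los[admitted] <- 1L + rpois(sum(admitted),
                              config$neonatal_los_mean[ga[admitted]] - 1)
  los[admitted & nicu_death] <-
    pmax(1L, as.integer(ceiling(runif(sum(admitted & nicu_death)) *
                                  los[admitted & nicu_death])))

  ## death day offsets (Inf = survives the horizon)
  death_day <- rep(Inf, n)
  death_day[dies_delivery] <- 0
  death_day[nicu_death] <- los[nicu_death]
  alive <- !dies_delivery & !nicu_death
  disch_day <- ifelse(admitted, los, 0L)

  b2 <- birthday_offset(2)
  die_d2 <- alive & rbinom(n, 1, 1 - par_of("survival_discharge_to_age2")) == 1
  k_d2 <- which(die_d2)
  death_day[k_d2] <- disch_day[k_d2] +
    floor(runif(length(k_d2)) * pmax(1, b2 - disch_day[k_d2]))
  alive <- alive & !die_d2
  annual <- do.call(rbind, lapply(config$epi$strata,
                                  function(st) st$annual_survival))[ga, ,
                                                                    drop = FALSE]
  for (k in 2:9) {
    dies <- alive & rbinom(n, 1, 1 - annual[, k - 1]) == 1
    kk <- which(dies)
    lo <- birthday_offset(k); hi <- birthday_offset(k + 1)
    death_day[kk] <- lo + floor(runif(length(kk)) * (hi - lo))
    alive <- alive & !dies
  }

  transfer <- rbinom(n, 1, config$p_birth_transfer) == 1
  ltf <- rbinom(n, 1, config$p_lost_to_followup) == 1

  registry <- tibble(infant_id = infant_id, ga_weeks = as.integer(ga_weeks),
                     birth_date = birth_date, transfer_at_birth = transfer)

  birth_ep <- tibble(
    infant_id = infant_id[admitted],
    admit_date = birth_date[admitted],
    discharge_date = birth_date[admitted] + los[admitted],
    ward = if_else(ga[admitted] == "late", "neonatal_normal",
                   "neonatal_intensive"),
    procedure_count = 0L,
    is_birth_episode = TRUE
  )

  ## per-period utilization for infants alive at the period's end
  targets <- config$utilization_targets
  ep_rows <- list(); cl_rows <- list()
  for (p in AGE_PERIODS) {
    if (p == "discharge_to_2") {
      start <- disch_day; end <- rep(b2, n)
    } else {
      k <- as.integer(p)
      start <- rep(birthday_offset(k), n)
      end <- rep(birthday_offset(k + 1), n)
    }
    eligible <- which(death_day >= end)
    if (length(eligible) == 0) next
    mu <- function(col) {
      m <- setNames(numeric(3), GA_LEVELS)
      for (g in GA_LEVELS) {
        m[[g]] <- utilization_cell(targets, g, p)[[paste0(col, "_mean")]]
      }
      m[ga[eligible]]
    }
    days <- rnbinom(length(eligible), mu = mu("inpatient_days"),
                    size = config$size_days)
    picu <- rnbinom(length(eligible), mu = mu("picu_days"),
                    size = config$size_days)
    visits <- rnbinom(length(eligible), mu = mu("outpatient_visits"),
                      size = config$size_visits)
    procs <- integer(length(eligible))
    hosp <- days > 0
    procs[hosp] <- rnbinom(sum(hosp),
                           mu = config$procedures_per_hospitalization,
                           size = config$size_procedures)

    place <- function(idx, dur, ward, n_proc) {
      dur <- pmin(dur, end[idx] - start[idx] - 1)
      span <- pmax(1, end[idx] - start[idx] - dur)
      off <- start[idx] + floor(runif(length(idx)) * span)
      tibble(infant_id = infant_id[idx],
             admit_date = birth_date[idx] + off,
             discharge_date = birth_date[idx] + off + dur,
             ward = ward, procedure_count = as.integer(n_proc),
             is_birth_episode = FALSE)
    }
    if (any(days > 0)) {
      sel <- days > 0
      ep_rows[[length(ep_rows) + 1]] <-
        place(eligible[sel], days[sel], "general", procs[sel])
    }
    if (any(picu > 0)) {
      sel <- picu > 0
      ep_rows[[length(ep_rows) + 1]] <-
        place(eligible[sel], picu[sel], "picu", 0L)
    }
    if (any(visits > 0)) {
      idx <- rep(eligible, visits)
      off <- start[idx] + floor(runif(length(idx)) * (end[idx] - start[idx]))
      amt <- round(rgamma(length(idx), shape = config$amount_shape,
                          rate = config$amount_shape / config$amount_per_visit),
                   2)
      cl_rows[[length(cl_rows) + 1]] <-
        tibble(infant_id = infant_id[idx],
               service_date = birth_date[idx] + off,
               billed_amount = amt)
    }
  }

  episodes <- bind_rows(c(list(birth_ep), ep_rows))
  claims <- if (length(cl_rows) > 0) bind_rows(cl_rows) else
    empty_bundle()$claims
  deaths <- tibble(infant_id = infant_id[is.finite(death_day)],
                   death_date = birth_date[is.finite(death_day)] +
                     death_day[is.finite(death_day)])

  ## loss to follow-up removes every record after the birth hospitalization
  lost_ids <- infant_id[ltf]
  episodes <- filter(episodes,
                     .data$is_birth_episode | !(.data$infant_id %in% lost_ids))
  claims <- filter(claims, !(.data$infant_id %in% lost_ids))
  deaths <- filter(deaths, !(.data$infant_id %in% lost_ids))

  episodes <- arrange(episodes, .data$infant_id, .data$admit_date, .data$ward)
  claims <- arrange(claims, .data$infant_id, .data$service_date,
                    .data$billed_amount)
  deaths <- arrange(deaths, .data$infant_id)

  claims_bundle(registry, episodes, claims, deaths)
}

strip_readr_attrs <- function(df) {
  attr(df, "spec") <- NULL
  attr(df, "problems") <- NULL
  class(df) <- c("tbl_df", "tbl", "data.frame")
  df
}

#' Write / read a claims bundle as delimited text
#'
#' The four tables are written as `registry.csv`, `episodes.csv`,
#' `claims.csv` and `deaths.csv` under `path`, with ISO-8601 dates.
#' `read_bundle()` is the exact inverse: `read_bundle(write_bundle(b))`
#' reproduces `b` field for field.  Malformed dates raise a parse error
#' naming the file and row.
#'
#' @param bundle A [claims_bundle()].
#' @param path Directory to write to / read from.
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()`
#'   returns a [claims_bundle()].
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  readr::write_csv(bundle$registry, file.path(path, "registry.csv"))
  readr::write_csv(bundle$episodes, file.path(path, "episodes.csv"))
  readr::write_csv(bundle$claims, file.path(path, "claims.csv"))
  readr::write_csv(bundle$deaths, file.path(path, "deaths.csv"))
  invisible(path)
}

parse_iso_dates <- function(df, cols, file) {
  for (col in cols) {
    parsed <- as.Date(df[[col]], format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop("parse error in ", file, ", row ", bad[1], ": `", df[[col]][bad[1]],
           "` is not an ISO-8601 date in column ", col, call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  rd <- function(file, col_types) {
    strip_readr_attrs(readr::read_csv(file.path(path, file),
                                      col_types = col_types,
                                      progress = FALSE))
  }
  registry <- rd("registry.csv", readr::cols(
    infant_id = "c", ga_weeks = "i", birth_date = "c",
    transfer_at_birth = "l"))
  episodes <- rd("episodes.csv", readr::cols(
    infant_id = "c", admit_date = "c", discharge_date = "c", ward = "c",
    procedure_count = "i", is_birth_episode = "l"))
  claims <- rd("claims.csv", readr::cols(
    infant_id = "c", service_date = "c", billed_amount = "d"))
  deaths <- rd("deaths.csv", readr::cols(infant_id = "c", death_date = "c"))

  registry <- parse_iso_dates(registry, "birth_date", "registry.csv")
  episodes <- parse_iso_dates(episodes, c("admit_date", "discharge_date"),
                              "episodes.csv")
  claims <- parse_iso_dates(claims, "service_date", "claims.csv")
  deaths <- parse_iso_dates(deaths, "death_date", "deaths.csv")

  claims_bundle(registry, episodes, claims, deaths)
}
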