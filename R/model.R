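#' Run the Markov cohort engine for one stratum
#'
#' Propagates a cohort of live births deterministically from birth to age
#' ten.  Infants who do not die in the delivery room are either admitted to
#' a neonatal care facility (surviving it with the live-discharge
#' probability) or discharged directly home; a single state covers the time
#' from discharge to age two, after which survival is applied annually.
#' From age two the distribution across the four disability levels starts
#' at the stratum-specific initial distribution and is propagated each year
#' by the row-stochastic transition matrix (the probability of entering a
#' disability state depends only on the current state).
#'
#' Survival at age 1 has no model state of its own; it is reported as the
#' geometric mean of survival at neonatal discharge and at age two, and is
#' the weight used when costing the discharge-to-age-2 state at its
#' midpoint.
#'
#' @param epi An `epi_params` object (validated before use).
#' @param ga Stratum label: `"early"`, `"moderate"` or `"late"`.
#' @return An object of class `cohort_trajectory` with elements
#'   `ga`, `survival_by_age` (named fractions of live births alive, ages
#'   0--10), `survival_at_discharge`, `p_direct_home`, and
#'   `disability_dist_by_age` (9x4 matrix, ages 2--10).
#' @export
#' @examples
#' traj <- run_cohort(default_epi_params(), "early")
#' traj$survival_by_age[["2"]]
run_cohort <- function(epi, ga = GA_LEVELS) {
  ga <- match.arg(ga)
  assert_epi_params(epi)
  st <- epi$strata[[ga]]

  s_discharge <- (1 - st$p_death_delivery) *
    (st$p_admit_neonatal * st$p_live_discharge_neonatal +
       (1 - st$p_admit_neonatal))
  s2 <- s_discharge * st$survival_discharge_to_age2

  survival <- numeric(11)
  names(survival) <- as.character(0:10)
  survival[["0"]] <- 1
  survival[["1"]] <- sqrt(s_discharge * s2)
  survival[["2"]] <- s2
  for (age in 3:10) {
    survival[[as.character(age)]] <-
      survival[[as.character(age - 1)]] * st$annual_survival[age - 2]
  }

  dis <- matrix(NA_real_, nrow = 9, ncol = 4,
                dimnames = list(age = as.character(2:10), DISABILITY_LEVELS))
  d <- st$disability_init_age2
  dis["2", ] <- d
  for (age in 3:10) {
    d <- as.numeric(d %*% st$disability_transition)
    dis[as.character(age), ] <- d
  }

  structure(
    list(
      ga = ga,
      survival_by_age = survival,
      survival_at_discharge = s_discharge,
      p_admitted = (1 - st$p_death_delivery) * st$p_admit_neonatal,
      p_direct_home = (1 - st$p_death_delivery) * (1 - st$p_admit_neonatal),
      disability_dist_by_age = dis
    ),
    class = "cohort_trajectory"
  )
}

#' @export
print.cohort_trajectory <- function(x, ...) {
  cat("<cohort_trajectory> stratum:", x$ga, "\n")
  cat("  survival at ages 0/2/10:",
      sprintf("%.4f", x$survival_by_age[c("0", "2", "10")]), "\n")
  cat("  P(direct home):", sprintf("%.4f", x$p_direct_home), "\n")
  invisible(x)
}

#' Disability distribution at a given age
#'
#' @param traj A `cohort_trajectory`.
#' @param age Integer age in years, between 2 and 10.
#' @return Named 4-vector over none/mild/moderate/severe, summing to one.
#' @export
disability_distribution_at <- function(traj, age) {
  stopifnot(inherits(traj, "cohort_trajectory"))
  if (length(age) != 1 || age != as.integer(age) || age < 2 || age > 10) {
    stop("`age` must be an integer between 2 and 10", call. = FALSE)
  }
  traj$disability_dist_by_age[as.character(age), ]
}

#' Export trajectories as delimited text
#'
#' One row per (stratum, age) with the survival fraction and the four
#' disability columns (disability columns are NA before age two).
#'
#' @param trajs List of `cohort_trajectory` objects.
#' @param path Output CSV path (optional; omit to just get the tibble).
#' @return The tidy tibble, invisibly when written.
#' @export
trajectory_table <- function(trajs, path = NULL) {
  rows <- purrr::map_dfr(trajs, function(tr) {
    ages <- 0:10
    dis <- matrix(NA_real_, nrow = 11, ncol = 4,
                  dimnames = list(NULL, DISABILITY_LEVELS))
    dis[3:11, ] <- tr$disability_dist_by_age
    tibble(
      ga = tr$ga, age = ages,
      survival = unname(tr$survival_by_age),
      none = dis[, "none"], mild = dis[, "mild"],
      moderate = dis[, "moderate"], severe = dis[, "severe"]
    )
  })
  if (!is.null(path)) {
    readr::write_csv(rows, path)
    return(invisible(rows))
  }
  rows
}
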