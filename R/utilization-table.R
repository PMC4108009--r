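## Published stratified utilization means and standard errors: average
## inpatient hospital days and outpatient (physician-billed) costs per
## surviving infant, by stratum and age period.  Rows run from the
## discharge-to-age-2 state through age 9, the final accrual year.
TABLE2_INPATIENT_DAYS <- list(
  early    = list(mean = c(17.45, 0.89, 0.65, 0.42, 0.50, 0.32, 0.45, 0.24, 0.04),
                  se   = c(3.32, 0.21, 0.20, 0.13, 0.19, 0.09, 0.20, 0.08, 0.02)),
  moderate = list(mean = c(8.75, 1.60, 0.50, 0.35, 0.39, 0.24, 0.22, 0.19, 0.09),
                  se   = c(1.27, 0.80, 0.13, 0.08, 0.09, 0.04, 0.06, 0.05, 0.02)),
  late     = list(mean = c(2.40, 0.40, 0.26, 0.20, 0.16, 0.20, 0.17, 0.10, 0.10),
                  se   = c(0.17, 0.04, 0.02, 0.01, 0.01, 0.06, 0.03, 0.01, 0.02))
)

TABLE2_OUTPATIENT_COST <- list(
  early    = list(mean = c(2403.02, 336.17, 280.46, 271.14, 234.18, 223.13,
                           212.22, 193.54, 110.47),
                  se   = c(223.01, 24.82, 22.61, 32.03, 25.90, 26.59,
                           27.18, 28.88, 9.07)),
  moderate = list(mean = c(1453.34, 277.79, 230.30, 191.50, 195.20, 163.56,
                           155.44, 142.84, 123.19),
                  se   = c(102.99, 16.29, 14.57, 8.69, 8.35, 7.65,
                           10.27, 9.50, 6.80)),
  ## The published late-preterm outpatient SE column repeats the means (a
  ## transcription artefact); shipped SEs instead use the moderate-stratum
  ## coefficient of variation (~6% of the mean), flagged non-published.
  late     = list(mean = c(734.14, 220.42, 182.21, 165.21, 154.99, 133.59,
                           122.36, 109.91, 107.13),
                  se   = NULL)
)
TABLE2_OUTPATIENT_COST$late$se <-
  round(0.06 * TABLE2_OUTPATIENT_COST$late$mean, 2)

## Mean physician billing per outpatient visit, $CAD.  Visit counts are not
## published (only billed costs); this external-reference scalar converts
## cost means into visit means for indirect costing and for the generator.
DEFAULT_AMOUNT_PER_VISIT <- 36

UTIL_COLUMNS <- c("inpatient_days", "picu_days", "procedures",
                  "outpatient_cost", "outpatient_visits")

#' Construct a stratified utilization table
#'
#' A utilization table holds, per (stratum, age period), the mean and
#' standard error of inpatient days, paediatric-ICU days, in-hospital
#' procedures, outpatient billed costs and outpatient visits among infants
#' surviving to that age, plus the survivor denominator `n`.
#'
#' @param df Data frame with columns `ga`, `period`, `<endpoint>_mean`,
#'   `<endpoint>_se` for each of `inpatient_days`, `picu_days`,
#'   `procedures`, `outpatient_cost`, `outpatient_visits`, and `n`.
#' @return A tibble of class `utilization_table`.
#' @export
utilization_table <- function(df) {
  need <- c("ga", "period",
            paste0(rep(UTIL_COLUMNS, each = 2), c("_mean", "_se")), "n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("utilization table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(df$period %in% AGE_PERIODS)) {
    stop("unknown age period(s): ",
         paste(setdiff(df$period, AGE_PERIODS), collapse = ", "), call. = FALSE)
  }
  se_cols <- paste0(UTIL_COLUMNS, "_se")
  if (any(df[se_cols] < 0, na.rm = TRUE)) {
    stop("standard errors must be non-negative", call. = FALSE)
  }
  structure(as_tibble(df), class = c("utilization_table", class(as_tibble(df))))
}

#' Default utilization table (published means)
#'
#' Inpatient-day and outpatient-cost means/SEs are the published stratified
#' values; PICU days and procedures are not published separately and
#' default to zero; outpatient visit means are derived from cost means via
#' the mean billing per visit.
#'
#' @param amount_per_visit Mean physician billing per outpatient visit.
#' @return A `utilization_table`.
#' @export
#' @examples
#' default_utilization()
default_utilization <- function(amount_per_visit = DEFAULT_AMOUNT_PER_VISIT) {
  rows <- purrr::map_dfr(GA_LEVELS, function(ga) {
    days <- TABLE2_INPATIENT_DAYS[[ga]]
    cost <- TABLE2_OUTPATIENT_COST[[ga]]
    tibble(
      ga = ga, period = AGE_PERIODS,
      inpatient_days_mean = days$mean, inpatient_days_se = days$se,
      picu_days_mean = 0, picu_days_se = 0,
      procedures_mean = 0, procedures_se = 0,
      outpatient_cost_mean = cost$mean, outpatient_cost_se = cost$se,
      outpatient_visits_mean = cost$mean / amount_per_visit,
      outpatient_visits_se = cost$se / amount_per_visit,
      n = NA_integer_
    )
  })
  utilization_table(rows)
}

utilization_cell <- function(util, ga, period) {
  row <- util[util$ga == ga & util$period == period, ]
  if (nrow(row) != 1) {
    stop("utilization table has no cell for (", ga, ", ", period, ")",
         call. = FALSE)
  }
  row
}

#' Write a utilization table as delimited text
#'
#' @param util A `utilization_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_utilization <- function(util, path) {
  readr::write_csv(as_tibble(util), path)
  invisible(path)
}
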