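#' Bundle every model input into one object
#'
#' Convenience container holding all parameter sets the deterministic model
#' consumes; [run_burden_model()] evaluates it and [run_psa()] perturbs it.
#'
#' @param epi An [epi_params()] set.
#' @param util A [utilization_table()].
#' @param costs A [unit_costs()] object.
#' @param stay A `neonatal_stay_params` object.
#' @param ia An [indirect_assumptions()] object.
#' @param opts A [sensitivity_options()] object.
#' @param counts Named preterm birth counts per stratum.
#' @param discount_rate Annual discount rate.
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(epi = default_epi_params(),
                         util = default_utilization(),
                         costs = unit_costs(),
                         stay = default_neonatal_stay(epi, costs),
                         ia = indirect_assumptions(),
                         opts = sensitivity_options(),
                         counts = PRETERM_COUNTS,
                         discount_rate = 0.05) {
  structure(list(epi = epi, util = util, costs = costs, stay = stay,
                 ia = ia, opts = opts, counts = counts,
                 discount_rate = discount_rate),
            class = "model_inputs")
}

#' Evaluate the deterministic burden model
#'
#' Runs the cohort engine and the costing engine for every stratum and
#' scales to national totals.
#'
#' @param inputs A [model_inputs()] object.
#' @return A list of class `burden_result` with elements `trajectories`
#'   (named list of `cohort_trajectory`), `breakdowns` (named list of
#'   per-stratum cost breakdowns) and `national` (tidy national table from
#'   [national_scale()]).
#' @export
#' @examples
#' res <- run_burden_model(model_inputs())
#' dplyr::filter(res$national, category == "total")
run_burden_model <- function(inputs) {
  stopifnot(inherits(inputs, "model_inputs"))
  trajectories <- lapply(setNames(GA_LEVELS, GA_LEVELS),
                         function(ga) run_cohort(inputs$epi, ga))
  breakdowns <- lapply(trajectories, function(tr) {
    aggregate_per_infant(tr, inputs$util, inputs$costs, inputs$stay,
                         inputs$ia, inputs$opts, inputs$discount_rate)
  })
  structure(list(trajectories = trajectories, breakdowns = breakdowns,
                 national = national_scale(breakdowns, inputs$counts)),
            class = "burden_result")
}

#' Specification of the probabilistic sensitivity analysis
#'
#' Utilization cell means are drawn from normal distributions centred on
#' the estimates with their standard errors, truncated at zero.
#' Probabilities are drawn from method-of-moments Beta distributions whose
#' standard deviation is `probability_se_frac` of the binomial-sd scale
#' `sqrt(m(1-m))`.  Disability distributions and transition rows are drawn
#' from Dirichlet distributions with total concentration
#' `dirichlet_concentration`.  Unit costs are fixed by default; when
#' sampled they are truncated normal with coefficient of variation
#' `unit_cost_cv`.
#'
#' @param n_iterations Number of parameter draws (at least 2).
#' @param seed Integer seed; draw `i` is reproducible from `(seed, i)`.
#' @param utilization_se_scale Multiplier on the utilization SEs (0 gives a
#'   degenerate, zero-variance analysis).
#' @param probability_se_frac Spread of probability parameters (0 fixes
#'   them).
#' @param dirichlet_concentration Total concentration for simplex
#'   parameters (`Inf` fixes them).
#' @param sample_unit_costs Draw unit costs too?
#' @param unit_cost_cv Coefficient of variation for sampled unit costs.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(n_iterations = 1000, seed = 1L,
                     utilization_se_scale = 1,
                     probability_se_frac = 0.05,
                     dirichlet_concentration = 100,
                     sample_unit_costs = FALSE,
                     unit_cost_cv = 0.1) {
  stopifnot(n_iterations >= 2, utilization_se_scale >= 0,
            probability_se_frac >= 0, probability_se_frac < 1,
            dirichlet_concentration > 0, unit_cost_cv >= 0)
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 utilization_se_scale = utilization_se_scale,
                 probability_se_frac = probability_se_frac,
                 dirichlet_concentration = dirichlet_concentration,
                 sample_unit_costs = sample_unit_costs,
                 unit_cost_cv = unit_cost_cv),
            class = "psa_spec")
}

sample_probability <- function(m, frac) {
  if (frac == 0 || m <= 0 || m >= 1) return(m)
  se <- frac * sqrt(m * (1 - m))
  ab <- beta_from_moments(m, se)
  stats::rbeta(1, ab[["shape1"]], ab[["shape2"]])
}

#' Draw one parameter set for the PSA
#'
#' Reproducible from `(spec$seed, iteration)`; every draw respects the
#' parameter domains (truncation at zero, \[0,1\] probabilities, simplexes
#' renormalized by construction).
#'
#' @param inputs Base [model_inputs()].
#' @param spec A [psa_spec()].
#' @param iteration Iteration index (1-based).
#' @return A perturbed `model_inputs` object.
#' @export
sample_parameters <- function(inputs, spec, iteration) {
  stopifnot(inherits(inputs, "model_inputs"), inherits(spec, "psa_spec"),
            iteration >= 1)
  set.seed((spec$seed + iteration) %% .Machine$integer.max)
  draw <- inputs

  ## utilization means ~ Normal(mean, se), truncated at zero
  util <- as_tibble(inputs$util)
  if (any(util[paste0(UTIL_COLUMNS, "_se")] < 0, na.rm = TRUE)) {
    stop("negative standard error in utilization table", call. = FALSE)
  }
  for (col in UTIL_COLUMNS) {
    m <- util[[paste0(col, "_mean")]]
    se <- util[[paste0(col, "_se")]] * spec$utilization_se_scale
    ok <- !is.na(m) & !is.na(se)
    m[ok] <- rnorm_trunc0(sum(ok), m[ok], se[ok])
    util[[paste0(col, "_mean")]] <- m
  }
  draw$util <- utilization_table(util)

  ## probabilities ~ Beta, simplexes ~ Dirichlet
  conc <- spec$dirichlet_concentration
  draw$epi$strata <- lapply(inputs$epi$strata, function(st) {
    for (f in c("p_death_delivery", "p_admit_neonatal",
                "p_live_discharge_neonatal", "survival_discharge_to_age2")) {
      st[[f]] <- sample_probability(st[[f]], spec$probability_se_frac)
    }
    st$annual_survival <- vapply(st$annual_survival, sample_probability,
                                 numeric(1), frac = spec$probability_se_frac)
    if (is.finite(conc)) {
      st$disability_init_age2 <- setNames(
        rdirichlet1(st$disability_init_age2 * conc), DISABILITY_LEVELS)
      P <- st$disability_transition
      for (i in seq_len(4)) P[i, ] <- rdirichlet1(P[i, ] * conc)
      st$disability_transition <- P
    }
    st
  })

  if (isTRUE(spec$sample_unit_costs)) {
    cv <- spec$unit_cost_cv
    costs <- inputs$costs
    for (grp in names(costs)) {
      costs[[grp]] <- rnorm_trunc0(length(costs[[grp]]), costs[[grp]],
                                   cv * costs[[grp]]) |>
        setNames(names(costs[[grp]]))
    }
    draw$costs <- costs
  }
  draw
}

#' Run the probabilistic sensitivity analysis
#'
#' Repeatedly draws parameter sets, reruns the full deterministic model and
#' collects total costs per stratum; iterations whose draw fails validation
#' are recorded and resampled.
#'
#' @param inputs Base [model_inputs()].
#' @param spec A [psa_spec()].
#' @return A list of class `psa_result`: `sample` (tibble of
#'   iteration-level totals), `summary` (mean and empirical 2.5th/97.5th
#'   percentiles, linear interpolation between order statistics, per
#'   stratum and overall) and `n_resampled`.
#' @export
run_psa <- function(inputs, spec = psa_spec()) {
  stopifnot(inherits(inputs, "model_inputs"))
  rows <- vector("list", spec$n_iterations)
  n_resampled <- 0L
  for (i in seq_len(spec$n_iterations)) {
    attempt <- 0L
    res <- NULL
    while (is.null(res)) {
      idx <- i + attempt * spec$n_iterations
      res <- tryCatch(
        run_burden_model(sample_parameters(inputs, spec, idx)),
        error = function(e) NULL)
      if (is.null(res)) {
        n_resampled <- n_resampled + 1L
        attempt <- attempt + 1L
        if (attempt > 100L) {
          stop("PSA iteration ", i, " failed validation repeatedly",
               call. = FALSE)
        }
      }
    }
    rows[[i]] <- res$national |>
      filter(.data$category == "total") |>
      mutate(iteration = i) |>
      select("iteration", "stratum", "cost_per_infant", "national_total")
  }
  sample_tbl <- bind_rows(rows)
  summary_tbl <- sample_tbl |>
    group_by(.data$stratum) |>
    summarise(
      mean_cost_per_infant = mean(.data$cost_per_infant),
      p2.5_cost_per_infant = quantile(.data$cost_per_infant, 0.025,
                                      names = FALSE),
      p97.5_cost_per_infant = quantile(.data$cost_per_infant, 0.975,
                                       names = FALSE),
      mean_national_total = mean(.data$national_total),
      p2.5_national_total = quantile(.data$national_total, 0.025,
                                     names = FALSE),
      p97.5_national_total = quantile(.data$national_total, 0.975,
                                      names = FALSE),
      .groups = "drop")
  structure(list(sample = sample_tbl, summary = summary_tbl,
                 n_resampled = n_resampled, spec = spec),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$spec$n_iterations, "iterations,",
      x$n_resampled, "resampled\n")
  print(x$summary)
  invisible(x)
}
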