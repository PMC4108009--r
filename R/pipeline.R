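#' Published national burden table
#'
#' The published individual and national economic burden of prematurity
#' ($CAD 2012), by expenditure category and stratum, shipped as reference
#' data for consistency checks and comparisons.  Stratum population counts
#' are 1,828 (early), 4,685 (moderate) and 20,795 (late) annual preterm
#' live births.
#'
#' @return Tibble with columns `category`, `stratum`, `national_total`,
#'   `cost_per_infant`.
#' @export
table3_reference <- function() {
  path <- system.file("extdata", "table3_published.csv",
                      package = "pretermburden", mustWork = TRUE)
  strip_readr_attrs(readr::read_csv(path, col_types = "ccdd",
                                    progress = FALSE))
}

#' Pipeline configuration
#'
#' @param n_infants Synthetic cohort size.
#' @param seed Master seed for the run (generator and PSA seeds derive
#'   from it).
#' @param psa_iterations PSA draws.
#' @param skip_psa Skip the PSA stage?
#' @param use_estimated_utilization Use the utilization table estimated
#'   from the synthetic claims where cells are available (falling back to
#'   the published defaults for empty cells); otherwise use the published
#'   defaults throughout.
#' @param discount_rate Annual discount rate.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_infants = 10000, seed = 1L,
                            psa_iterations = 200, skip_psa = FALSE,
                            use_estimated_utilization = TRUE,
                            discount_rate = 0.05) {
  stopifnot(n_infants > 0, psa_iterations >= 2, discount_rate > -1)
  structure(list(n_infants = as.integer(n_infants), seed = as.integer(seed),
                 psa_iterations = as.integer(psa_iterations),
                 skip_psa = isTRUE(skip_psa),
                 use_estimated_utilization = isTRUE(use_estimated_utilization),
                 discount_rate = discount_rate),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose keys mirror the `pipeline_config()`
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), names(formals(pipeline_config)))
  if (length(bad) > 0) {
    stop("unknown pipeline config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

## overlay estimated cells (n > 0, non-missing) on the default table
merge_utilization <- function(estimated, fallback) {
  out <- as_tibble(fallback)
  est <- as_tibble(estimated)
  for (i in seq_len(nrow(est))) {
    j <- which(out$ga == est$ga[i] & out$period == est$period[i])
    if (length(j) == 1 && est$n[i] > 0) {
      for (col in c(paste0(rep(UTIL_COLUMNS, each = 2), c("_mean", "_se")),
                    "n")) {
        if (!is.na(est[[col]][i])) out[[col]][j] <- est[[col]][i]
      }
    }
  }
  utilization_table(out)
}

#' Run the full pipeline
#'
#' Simulate a synthetic claims cohort, apply the exclusion rules, estimate
#' stratified utilization, run the deterministic cohort and costing model,
#' run the PSA, and write every table plus a run manifest to `out_dir`.
#'
#' @param config A [pipeline_config()] or path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and output
#'   paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  gen_cfg <- generator_config(n_infants = config$n_infants,
                              seed = config$seed)
  bundle <- generate_cohort(gen_cfg)
  message("stage=simulate infants=", nrow(bundle$registry),
          " episodes=", nrow(bundle$episodes),
          " claims=", nrow(bundle$claims))

  cohort <- apply_exclusions(bundle)
  message("stage=exclusions included=", nrow(cohort$bundle$registry),
          " excluded=", nrow(cohort$exclusions))

  util_est <- compute_utilization(cohort)
  message("stage=estimate cells=", sum(util_est$n > 0, na.rm = TRUE))

  util <- if (config$use_estimated_utilization) {
    merge_utilization(util_est, default_utilization())
  } else {
    default_utilization()
  }
  inputs <- model_inputs(util = util, discount_rate = config$discount_rate)
  result <- run_burden_model(inputs)
  message("stage=model strata=", length(result$breakdowns))

  psa <- NULL
  if (!config$skip_psa) {
    psa <- run_psa(inputs, psa_spec(n_iterations = config$psa_iterations,
                                    seed = config$seed + 1L))
    message("stage=psa iterations=", config$psa_iterations,
            " resampled=", psa$n_resampled)
  }

  paths <- list(
    trajectories = file.path(out_dir, "trajectories.csv"),
    utilization = file.path(out_dir, "utilization.csv"),
    exclusions = file.path(out_dir, "exclusions.csv"),
    table3 = file.path(out_dir, "table3.csv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  trajectory_table(result$trajectories, paths$trajectories)
  write_utilization(util_est, paths$utilization)
  write_exclusion_log(cohort, paths$exclusions)
  readr::write_csv(render_table3(result$national, psa), paths$table3)
  if (!is.null(psa)) {
    paths$psa_summary <- file.path(out_dir, "psa_summary.csv")
    readr::write_csv(psa$summary, paths$psa_summary)
  }

  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("pretermburden")),
    psa_skipped = config$skip_psa,
    outputs = unname(unlist(paths[names(paths) != "manifest"])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, paths$manifest)

  invisible(list(config = config, bundle = bundle, cohort = cohort,
                 utilization = util_est, result = result, psa = psa,
                 paths = paths))
}

#' Render the national burden table
#'
#' Formats a [national_scale()] result (plus, optionally, PSA percentile
#' rows) in the published layout: one row per expenditure category plus
#' totals, and a (total, per-infant) column pair for each of the all,
#' early, moderate and late strata.  Dollars are rounded half-up to the
#' nearest dollar.
#'
#' @param national Tidy table from [national_scale()].
#' @param psa Optional [run_psa()] result supplying total-cost percentile
#'   rows.
#' @return A wide tibble.
#' @export
render_table3 <- function(national, psa = NULL) {
  strata <- c("all", GA_LEVELS)
  missing_strata <- setdiff(strata, as.character(unique(national$stratum)))
  if (length(missing_strata) > 0) {
    stop("national table is missing stratum(s): ",
         paste(missing_strata, collapse = ", "), call. = FALSE)
  }
  rows <- national
  if (!is.null(psa)) {
    psa_rows <- purrr::map_dfr(c(2.5, 97.5), function(p) {
      tibble(category = sprintf("total_psa_p%s", p),
             stratum = psa$summary$stratum,
             cost_per_infant =
               psa$summary[[sprintf("p%s_cost_per_infant", p)]],
             national_total =
               psa$summary[[sprintf("p%s_national_total", p)]])
    })
    rows <- bind_rows(rows, psa_rows)
  }
  wide <- rows |>
    mutate(stratum = as.character(.data$stratum),
           cost_per_infant = round_half_up(.data$cost_per_infant),
           national_total = round_half_up(.data$national_total)) |>
    tidyr::pivot_wider(names_from = "stratum",
                       values_from = c("national_total", "cost_per_infant"),
                       names_glue = "{stratum}_{.value}")
  ord <- unlist(lapply(strata,
                       function(s) paste0(s, c("_national_total",
                                               "_cost_per_infant"))))
  wide[, c("category", ord)]
}
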