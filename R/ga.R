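#' Gestational-age strata
#'
#' The three preterm strata used throughout the package: early (<28 completed
#' weeks), moderate (28--32 weeks) and late (33--36 weeks).  Preterm birth is
#' birth before 37 completed weeks.
#'
#' @return A tibble with columns `label`, `week_min`, `week_max`.
#' @export
#' @examples
#' ga_categories()
ga_categories <- function() {
  tibble(
    label = factor(GA_LEVELS, levels = GA_LEVELS),
    week_min = c(20L, 28L, 33L),
    week_max = c(27L, 32L, 36L)
  )
}

#' Assign a gestational-age category
#'
#' Maps completed weeks of gestation to the early/moderate/late stratum.
#' Only preterm ages (20--36 weeks) are accepted.
#'
#' @param ga_weeks Integer vector of completed weeks of gestation at birth.
#' @return Factor with levels `early`, `moderate`, `late`.
#' @export
#' @examples
#' assign_ga_category(c(27, 28, 32, 36))
assign_ga_category <- function(ga_weeks) {
  if (any(ga_weeks != as.integer(ga_weeks))) {
    stop("`ga_weeks` must be whole weeks", call. = FALSE)
  }
  if (any(ga_weeks >= 37)) {
    stop("gestational age >= 37 weeks is not preterm", call. = FALSE)
  }
  if (any(ga_weeks < 20)) {
    stop("gestational age below 20 weeks is outside the supported range",
         call. = FALSE)
  }
  cut(as.integer(ga_weeks), breaks = c(19, 27, 32, 36),
      labels = GA_LEVELS)
}
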