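#' Annual probability from a cumulative probability over several years
#'
#' Converts a cumulative event probability observed over `years` into the
#' constant annual probability with the same cumulative risk:
#' `1 - (1 - p)^(1/years)`. Used, e.g., to turn an 85% two-year oral-cancer
#' mortality after loco-regional recurrence into its annual equivalent
#' (0.6127, printed as 0.613).
#'
#' @param cumulative_prob cumulative probability in [0,1)
#' @param years observation window in years, > 0
#' @return annual probability
#' @examples
#' annual_from_cumulative(0.85, 2)
#' @export
annual_from_cumulative <- function(cumulative_prob, years) {
  if (any(cumulative_prob < 0) || any(cumulative_prob >= 1))
    stop("cumulative probability must lie in [0,1); the annual rate is ",
         "undefined at 1", call. = FALSE)
  if (any(years <= 0)) stop("years must be > 0", call. = FALSE)
  1 - (1 - cumulative_prob)^(1 / years)
}

#' Annual death probability from a median survival in months
#'
#' Assumes exponentially distributed survival, so the annual probability is
#' `1 - 0.5^(12/median_months)`; a 7.5-month median gives 0.6701 per year.
#'
#' @param median_months median survival in months, > 0
#' @return annual probability
#' @export
annual_from_median_survival <- function(median_months) {
  if (any(median_months <= 0))
    stop("median survival must be > 0 months", call. = FALSE)
  1 - 0.5^(12 / median_months)
}

#' Age-band lookup of annual all-cause mortality
#'
#' Bands follow the published life-table extract (5-year bands from 51-55 to
#' 80+). Ages at or below the lowest band's upper limit use the lowest band
#' (the cohort enters at age 50, one year below the first band); ages above
#' 80 use the open 80+ band. The band values are applied exactly as printed
#' even though the printed sequence is non-monotone between the 71-75 and
#' 76-80 bands.
#'
#' @param age age in years (vectorised)
#' @param transitions the `transitions` component of a parameter set
#' @return annual all-cause mortality probability
#' @examples
#' mortality_lookup(52, table1_defaults()$transitions)  # 0.008
#' @export
mortality_lookup <- function(age, transitions) {
  acm <- transitions$all_cause_mortality
  # band lower edges parsed from names like "51-55", final band "80+";
  # the closed band "76-80" includes age 80, so the open band starts at 81
  lowers <- suppressWarnings(as.numeric(sub("[-+].*$", "", names(acm))))
  lowers[grepl("+", names(acm), fixed = TRUE)] <-
    lowers[grepl("+", names(acm), fixed = TRUE)] + 1
  o <- order(lowers)
  lowers <- lowers[o]
  vals <- unname(acm[o])
  idx <- findInterval(age, lowers)
  idx[idx < 1] <- 1L        # below the first band: clamp to it
  vals[idx]
}

#' Present-value discount factor for an annual cycle index
#'
#' @param rate annual discount rate, >= 0
#' @param cycle cycle index (0 = model entry), vectorised
#' @return `1 / (1 + rate)^cycle`
#' @export
discount_factor <- function(rate, cycle) {
  stopifnot(rate >= 0, all(cycle >= 0))
  1 / (1 + rate)^cycle
}
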