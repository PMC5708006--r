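# Policy scenarios: each scenario bundles the demand-side improvement
# factors (reduction of the inpatient care rate and of the average length of
# stay), the supply-side bed utilization rate, the access-area threshold and
# the Monte Carlo sampling settings.

#' Define a simulation scenario
#'
#' The daily inpatient census scales by
#' `(1 - inpatient_rate_reduction) * (1 - alos_reduction)`: fewer people are
#' admitted, and shorter stays lower the number of beds occupied on any given
#' day. `utilization_rate` scales hospital capacity via [available_beds()].
#'
#' @param name scenario label (unique within a suite).
#' @param inpatient_rate_reduction fractional reduction of the inpatient care
#'   rate, in [0, 1).
#' @param alos_reduction fractional reduction of the average length of
#'   hospital stay, in [0, 1).
#' @param utilization_rate hospital bed utilization rate, in (0, 1].
#' @param external_bed_fraction cap on usable beds in out-of-region
#'   hospitals, in [0, 1].
#' @param paa_threshold_minutes travel-time threshold defining Patient
#'   Access Areas (default 60 minutes by car).
#' @param n_samples Monte Carlo samplings per scenario (default 100).
#' @param seed integer seed for all of the scenario's randomness.
#' @return an object of class `paam_scenario`.
#' @examples
#' scenario("baseline")
#' scenario("improve10", 0.10, 0.10, utilization_rate = 0.90)
#' @export
scenario <- function(name,
                     inpatient_rate_reduction = 0,
                     alos_reduction = 0,
                     utilization_rate = 0.80,
                     external_bed_fraction = 0.20,
                     paa_threshold_minutes = 60,
                     n_samples = 100,
                     seed = 1L) {
  check_frac <- function(x, what, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) stop(what, " must be in ", if (lo_open) "(" else "[", lo, ", ",
                  hi, if (hi_open) ")" else "]", call. = FALSE)
    x
  }
  check_frac(inpatient_rate_reduction, "inpatient_rate_reduction", 0, 1,
             hi_open = TRUE)
  check_frac(alos_reduction, "alos_reduction", 0, 1, hi_open = TRUE)
  check_frac(utilization_rate, "utilization_rate", 0, 1, lo_open = TRUE)
  check_frac(external_bed_fraction, "external_bed_fraction", 0, 1)
  if (!is.numeric(paa_threshold_minutes) || length(paa_threshold_minutes) != 1 ||
      is.na(paa_threshold_minutes) || paa_threshold_minutes <= 0)
    stop("paa_threshold_minutes must be positive", call. = FALSE)
  if (!is.numeric(n_samples) || length(n_samples) != 1 || is.na(n_samples) ||
      n_samples < 1 || n_samples != round(n_samples))
    stop("n_samples must be a positive integer", call. = FALSE)
  structure(
    list(name = as.character(name),
         inpatient_rate_reduction = inpatient_rate_reduction,
         alos_reduction = alos_reduction,
         utilization_rate = utilization_rate,
         external_bed_fraction = external_bed_fraction,
         paa_threshold_minutes = paa_threshold_minutes,
         n_samples = as.integer(n_samples),
         seed = as.integer(seed)),
    class = "paam_scenario"
  )
}

#' @export
print.paam_scenario <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s': inpatient rate %+.0f%%, ALOS %+.0f%%, utilization %.0f%%\n",
    x$name, -100 * x$inpatient_rate_reduction, -100 * x$alos_reduction,
    100 * x$utilization_rate))
  cat(sprintf("  PAA threshold %g min, external-bed cap %.0f%%, %d samplings, seed %d\n",
              x$paa_threshold_minutes, 100 * x$external_bed_fraction,
              x$n_samples, x$seed))
  invisible(x)
}

#' The three standard policy scenarios
#'
#' A current-projection baseline and 5% / 10% improvement scenarios:
#' \tabular{lccc}{
#'   \tab inpatient rate \tab length of stay \tab bed utilization \cr
#'   Ex.1 current projection \tab +/-0\% \tab +/-0\% \tab 80\% \cr
#'   Ex.2 5\% improvement \tab -5\% \tab -5\% \tab 85\% \cr
#'   Ex.3 10\% improvement \tab -10\% \tab -10\% \tab 90\% \cr
#' }
#'
#' @param seed base seed; each scenario gets a derived seed.
#' @param n_samples samplings per scenario.
#' @return named list of three `paam_scenario` objects.
#' @export
default_scenarios <- function(seed = 1L, n_samples = 100) {
  mk <- function(name, red, util, k)
    scenario(name, inpatient_rate_reduction = red, alos_reduction = red,
             utilization_rate = util, n_samples = n_samples,
             seed = derive_seed(seed, 101L, k))
  list(
    Ex1 = mk("Ex.1 current projection", 0.00, 0.80, 1L),
    Ex2 = mk("Ex.2 5% improvement", 0.05, 0.85, 2L),
    Ex3 = mk("Ex.3 10% improvement", 0.10, 0.90, 3L)
  )
}
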