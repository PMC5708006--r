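# Demographic and inpatient-care rate tables, indexed by sex and 5-year age
# band. Fertility is births per woman per 5-year projection step for the
# reproductive bands 15-19 .. 45-49; survival and net migration are per-step
# probabilities/rates; the inpatient rate is the probability that a person is
# a hospital inpatient on a given day.

#' Construct a rate-table set
#'
#' @param fertility numeric length-7 vector, births per woman per 5-year step
#'   for female bands 15-19 .. 45-49; all >= 0.
#' @param sex_ratio_at_birth male births per female birth (> 0).
#' @param survival 2 x 18 matrix of per-step survival probabilities in [0, 1]
#'   (rows `female`, `male`).
#' @param net_migration 2 x 18 matrix of signed per-step net migration rates,
#'   as a fraction of the band; must be >= -1.
#' @param inpatient_rate 2 x 18 matrix of daily inpatient probabilities in
#'   [0, 1].
#' @return an object of class `paam_rates`.
#' @export
rate_tables <- function(fertility, sex_ratio_at_birth, survival,
                        net_migration, inpatient_rate) {
  fertility <- as.numeric(fertility)
  if (length(fertility) != 7 || anyNA(fertility) || any(fertility < 0))
    stop("fertility must be 7 non-negative values (bands 15-19 .. 45-49)",
         call. = FALSE)
  names(fertility) <- .AGE_BANDS[.FERTILE_IDX]
  if (!is.numeric(sex_ratio_at_birth) || length(sex_ratio_at_birth) != 1 ||
      is.na(sex_ratio_at_birth) || sex_ratio_at_birth <= 0)
    stop("sex_ratio_at_birth must be a single positive number", call. = FALSE)
  survival <- as_rate_matrix(survival, "survival", lo = 0, hi = 1)
  net_migration <- as_rate_matrix(net_migration, "net_migration",
                                  lo = -1, hi = Inf)
  inpatient_rate <- as_rate_matrix(inpatient_rate, "inpatient_rate",
                                   lo = 0, hi = 1)
  structure(
    list(fertility = fertility, sex_ratio_at_birth = sex_ratio_at_birth,
         survival = survival, net_migration = net_migration,
         inpatient_rate = inpatient_rate),
    class = "paam_rates"
  )
}

as_rate_matrix <- function(m, what, lo, hi) {
  if (is.null(dim(m)) && length(m) %in% c(1L, 18L))
    m <- matrix(rep(as.numeric(m), length.out = 18), nrow = 2, ncol = 18,
                byrow = TRUE)
  if (!is.matrix(m) || !identical(dim(m), c(2L, 18L)))
    stop(what, " must be a 2 x 18 matrix (or a length-1/18 vector to recycle)",
         call. = FALSE)
  if (anyNA(m) || any(m < lo) || any(m > hi))
    stop(what, " values out of range [", lo, ", ", hi, "]", call. = FALSE)
  dimnames(m) <- list(.SEXES, .AGE_BANDS)
  m
}

#' @export
print.paam_rates <- function(x, ...) {
  cat("Rate tables (per 5-year step, 18 age bands)\n")
  cat(sprintf("  fertility sum (approx. TFR): %.2f\n", sum(x$fertility)))
  cat(sprintf("  sex ratio at birth: %.3f\n", x$sex_ratio_at_birth))
  cat(sprintf("  survival range: %.3f - %.3f\n",
              min(x$survival), max(x$survival)))
  cat(sprintf("  net migration range: %+.3f - %+.3f\n",
              min(x$net_migration), max(x$net_migration)))
  cat(sprintf("  daily inpatient rate range: %.4f - %.4f\n",
              min(x$inpatient_rate), max(x$inpatient_rate)))
  invisible(x)
}

#' Default synthetic rate tables
#'
#' A deliberately simple schedule that emulates an aging, low-fertility
#' population: total fertility near 1.4 births per woman, survival high
#' through midlife and declining steeply after 75, mild net out-migration
#' with a young-adult urban pull, and an all-cause daily inpatient rate that
#' rises from about 1 per 1000 in youth to 45 per 1000 above age 85 (the
#' population-weighted mean is about 6 per 1000, comparable to a large
#' metropolitan area). These are plain parameters, not any country's vital
#' statistics.
#'
#' @return a `paam_rates` object.
#' @export
default_rate_tables <- function() {
  surv_m <- c(0.998, 0.999, 0.999, 0.998, 0.997, 0.996, 0.995, 0.994,
              0.992, 0.989, 0.984, 0.976, 0.963, 0.941, 0.905, 0.850,
              0.750, 0.550)
  surv_f <- 1 - (1 - surv_m) * 0.6
  mig <- rep(-0.01, 18)
  mig[5:6] <- 0.02  # ages 20-29: net inflow typical of an urban region
  inp_f <- c(0.002, 0.001, 0.001, 0.001, 0.001, 0.001, 0.0012, 0.0015,
             0.0018, 0.002, 0.003, 0.004, 0.006, 0.008, 0.012, 0.018,
             0.028, 0.045)
  inp_m <- pmin(inp_f * 1.1, 1)
  rate_tables(
    fertility = c(0.02, 0.18, 0.45, 0.45, 0.25, 0.05, 0.005),
    sex_ratio_at_birth = 1.05,
    survival = rbind(female = surv_f, male = surv_m),
    net_migration = rbind(female = mig, male = mig),
    inpatient_rate = rbind(female = inp_f, male = inp_m)
  )
}
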