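# Daily inpatient demand. The expected count per area is
#   N = sum over sex x band of P * r * (1 - R_ad) * (1 - D_ad)
# where r is the daily inpatient care rate, R_ad the fractional reduction of
# that rate and D_ad the fractional reduction of the average length of stay
# (shorter stays lower the number of beds occupied on any day by the same
# factor). The stochastic form draws each person's inpatient status as a
# Bernoulli trial with the adjusted probability.

adjusted_inpatient_prob <- function(rates, R_ad, D_ad) {
  for (v in list(R_ad, D_ad))
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v >= 1)
      stop("reduction rates must be in [0, 1)", call. = FALSE)
  p <- rates$inpatient_rate * (1 - R_ad) * (1 - D_ad)
  if (any(p > 1)) stop("adjusted inpatient probability exceeds 1", call. = FALSE)
  p
}

#' Expected daily inpatients
#'
#' Deterministic expectation of the daily inpatient census for a population:
#' the sum over sex and age band of population times the adjusted inpatient
#' rate.
#'
#' @param population 2 x 18 population matrix, or a mesh table (then a named
#'   per-mesh vector is returned).
#' @param rates a `paam_rates` object.
#' @param R_ad fractional reduction of the inpatient care rate, in [0, 1).
#' @param D_ad fractional reduction of the average length of stay, in [0, 1).
#' @return expected inpatient count (single number, or named vector per mesh).
#' @examples
#' p <- population(0); p["female", "70-74"] <- 1000
#' r <- default_rate_tables()
#' expected_inpatients(p, r)                     # 1000 * rate
#' expected_inpatients(p, r, R_ad = .1, D_ad = .1)
#' @export
expected_inpatients <- function(population, rates, R_ad = 0, D_ad = 0) {
  stopifnot(inherits(rates, "paam_rates"))
  padj <- adjusted_inpatient_prob(rates, R_ad, D_ad)
  if (is.data.frame(population)) {
    validate_meshes(population, integral = FALSE)
    pm <- as.matrix(population[, pop_cols()])
    w <- c(padj["female", ], padj["male", ])
    return(setNames(as.vector(pm %*% w), population$mesh_id))
  }
  validate_population(population, integral = FALSE)
  sum(population * padj)
}

#' Sample daily inpatients person by person
#'
#' Monte Carlo counterpart of [expected_inpatients()]: for each sex x band,
#' the inpatient count is Binomial(population, adjusted rate); its mean over
#' repeated draws is the expected form. The caller controls the RNG state.
#'
#' @inheritParams expected_inpatients
#' @return integer inpatient count (single number, or named vector per mesh;
#'   for a mesh table, meshes are drawn in row order).
#' @export
sample_inpatients <- function(population, rates, R_ad = 0, D_ad = 0) {
  stopifnot(inherits(rates, "paam_rates"))
  padj <- adjusted_inpatient_prob(rates, R_ad, D_ad)
  if (is.data.frame(population)) {
    validate_meshes(population, integral = TRUE)
    pm <- as.matrix(population[, pop_cols()])
    w <- c(padj["female", ], padj["male", ])
    n <- nrow(pm)
    draws <- vapply(seq_len(n), function(i)
      sum(rbinom(36L, as.integer(pm[i, ]), w)), numeric(1))
    return(setNames(as.integer(draws), population$mesh_id))
  }
  validate_population(population, integral = TRUE)
  sum(rbinom(36L, as.integer(as.vector(population)), as.vector(padj)))
}
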