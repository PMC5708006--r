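# Cohort-component projection with per-person Monte Carlo sampling. One
# 5-year step applies, in this order: survival, net migration, aging (shift
# one band up, top band absorbing), then births from post-shift women aged
# 15-49. The expected mode runs the identical arithmetic on expectations and
# serves as the stochastic mode's oracle.

#' Projection configuration
#'
#' @param n_steps number of 5-year steps (>= 0).
#' @param step_years years per step (5).
#' @param mode `"stochastic"` (per-person sampling, integer counts) or
#'   `"expected"` (deterministic expectations, real-valued counts).
#' @param newborn_survival apply band-0 survival to children born within the
#'   step (default TRUE).
#' @param seed integer seed; each (mesh, step, sample) gets its own derived
#'   substream.
#' @return an object of class `paam_projection_config`.
#' @export
projection_config <- function(n_steps = 6L, step_years = 5L,
                              mode = c("stochastic", "expected"),
                              newborn_survival = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(n_steps) || length(n_steps) != 1 || is.na(n_steps) ||
      n_steps < 0 || n_steps != round(n_steps))
    stop("n_steps must be a non-negative integer", call. = FALSE)
  structure(list(n_steps = as.integer(n_steps),
                 step_years = as.integer(step_years), mode = mode,
                 newborn_survival = isTRUE(newborn_survival),
                 seed = as.integer(seed)),
            class = "paam_projection_config")
}

# shift every cohort up one band; the top band absorbs
shift_up <- function(p) {
  out <- p
  out[, 2:18] <- p[, 1:17]
  out[, 18] <- out[, 18] + p[, 18]
  out[, 1] <- 0
  out
}

#' Advance a population by one 5-year step
#'
#' In stochastic mode, survivors are drawn binomially per sex x band;
#' net migration adds Poisson(rate x survivors) people when the rate is
#' positive and removes Binomial(survivors, |rate|) when negative; everyone
#' ages one band (85+ absorbing); births are Poisson with mean
#' sum(fertility x post-shift women 15-49), split male/female by the sex
#' ratio at birth, and (optionally) thinned by band-0 survival. Expected
#' mode performs the same arithmetic on expectations and returns
#' real-valued counts. The caller controls the RNG state (see
#' [project_series()] for seeded substreams).
#'
#' @param population 2 x 18 matrix from [population()]; integral counts are
#'   required in stochastic mode.
#' @param rates a `paam_rates` object.
#' @param config a `paam_projection_config`; only `mode` and
#'   `newborn_survival` are used here.
#' @return a 2 x 18 population matrix one step later.
#' @examples
#' rates <- default_rate_tables()
#' p <- population(100)
#' project_step(p, rates, projection_config(mode = "expected"))
#' @export
project_step <- function(population, rates,
                         config = projection_config(mode = "expected")) {
  stopifnot(inherits(rates, "paam_rates"),
            inherits(config, "paam_projection_config"))
  stochastic <- config$mode == "stochastic"
  validate_population(population, integral = stochastic)
  surv <- rates$survival
  mig <- rates$net_migration
  male_share <- rates$sex_ratio_at_birth / (1 + rates$sex_ratio_at_birth)

  if (!stochastic) {
    survivors <- population * surv
    after_mig <- survivors * (1 + mig)  # E[Pois(r s)] = E[Binom(s, |r|)] = |r| s
    shifted <- shift_up(after_mig)
    births <- sum(rates$fertility * shifted["female", .FERTILE_IDX])
    b_m <- births * male_share
    b_f <- births - b_m
    if (config$newborn_survival) {
      b_f <- b_f * surv["female", 1]
      b_m <- b_m * surv["male", 1]
    }
    shifted["female", 1] <- b_f
    shifted["male", 1] <- b_m
    return(shifted)
  }

  # fixed draw order (36 cells column-major, then births) keeps substreams
  # reproducible regardless of the rate values
  survivors <- matrix(rbinom(36L, as.vector(population), as.vector(surv)),
                      2, 18, dimnames = dimnames(population))
  add <- matrix(rpois(36L, as.vector(pmax(mig, 0) * survivors)),
                2, 18)
  rem <- matrix(rbinom(36L, as.vector(survivors), as.vector(pmax(-mig, 0))),
                2, 18)
  after_mig <- survivors + add - rem
  shifted <- shift_up(after_mig)
  births <- rpois(1L, sum(rates$fertility * shifted["female", .FERTILE_IDX]))
  b_m <- rbinom(1L, births, male_share)
  b_f <- births - b_m
  if (config$newborn_survival) {
    b_f <- rbinom(1L, b_f, surv["female", 1])
    b_m <- rbinom(1L, b_m, surv["male", 1])
  }
  shifted["female", 1] <- b_f
  shifted["male", 1] <- b_m
  shifted
}

# Precompute the rate vectors in the 2 x 18 column-major layout used by the
# vectorized stochastic step below.
prep_rates <- function(rates, newborn_survival) {
  list(surv = as.vector(rates$survival),
       migpos = as.vector(pmax(rates$net_migration, 0)),
       migneg = as.vector(pmax(-rates$net_migration, 0)),
       fert = as.numeric(rates$fertility),
       male_share = rates$sex_ratio_at_birth / (1 + rates$sex_ratio_at_birth),
       sf1 = rates$survival["female", 1], sm1 = rates$survival["male", 1],
       newborn_survival = newborn_survival)
}

# column-major cell index of (female, band): 2*(band-1)+1; fertile bands 4..10
.FERTILE_CELLS <- 2L * (.FERTILE_IDX - 1L) + 1L

# One stochastic step on a length-36 column-major count vector. Draw order is
# identical to project_step(), so the two produce the same result from the
# same RNG state.
step_stochastic_vec <- function(v, rp) {
  survivors <- rbinom(36L, v, rp$surv)
  add <- rpois(36L, rp$migpos * survivors)
  rem <- rbinom(36L, survivors, rp$migneg)
  after <- survivors + add - rem
  new <- c(0L, 0L, after[1:34])
  new[35:36] <- new[35:36] + after[35:36]
  births <- rpois(1L, sum(rp$fert * new[.FERTILE_CELLS]))
  b_m <- rbinom(1L, births, rp$male_share)
  b_f <- births - b_m
  if (rp$newborn_survival) {
    b_f <- rbinom(1L, b_f, rp$sf1)
    b_m <- rbinom(1L, b_m, rp$sm1)
  }
  new[1L] <- b_f
  new[2L] <- b_m
  new
}

#' Project every mesh forward over several steps
#'
#' Applies [project_step()] independently per mesh per step. In stochastic
#' mode each (mesh, step, sample) triple is seeded from its own derived
#' substream, so projecting meshes together or separately, or in any order,
#' gives identical results.
#'
#' @param meshes a mesh table.
#' @param rates a `paam_rates` object (or a list of one per step for
#'   time-varying rates).
#' @param config a `paam_projection_config`.
#' @param sample_index Monte Carlo sampling index (enters the substream key).
#' @return list of `n_steps + 1` mesh tables; element 1 is the input.
#' @export
project_series <- function(meshes, rates, config = projection_config(),
                           sample_index = 1L) {
  stopifnot(inherits(config, "paam_projection_config"))
  stochastic <- config$mode == "stochastic"
  validate_meshes(meshes, integral = stochastic)
  rate_for <- function(step) {
    if (inherits(rates, "paam_rates")) rates
    else rates[[min(step, length(rates))]]
  }
  out <- vector("list", config$n_steps + 1L)
  out[[1L]] <- meshes
  if (config$n_steps == 0L) return(out)
  # populations as length-36 column-major vectors (female/male interleaved)
  fm <- as.matrix(meshes[, pop_cols()])
  interleave <- as.vector(rbind(1:18, 19:36))  # pop_cols -> column-major
  pops <- lapply(seq_len(nrow(fm)), function(i) fm[i, interleave])
  cur <- meshes
  for (step in seq_len(config$n_steps)) {
    r <- rate_for(step)
    rp <- prep_rates(r, config$newborn_survival)
    for (i in seq_along(pops)) {
      if (stochastic) {
        set.seed(derive_seed(config$seed, .STAGE$project, sample_index,
                             step, meshes$mesh_id[i]))
        pops[[i]] <- step_stochastic_vec(pops[[i]], rp)
      } else {
        m <- matrix(pops[[i]], 2, 18, dimnames = list(.SEXES, .AGE_BANDS))
        pops[[i]] <- as.vector(project_step(m, r, config))
      }
    }
    pm <- do.call(rbind, pops)[, interleave_inverse(), drop = FALSE]
    colnames(pm) <- pop_cols()
    cur[, pop_cols()] <- pm
    out[[step + 1L]] <- cur
  }
  out
}

# inverse permutation: column-major (f,m interleaved) -> pop_cols layout
interleave_inverse <- function() {
  interleave <- as.vector(rbind(1:18, 19:36))
  order(interleave)
}

#' Flatten a projection series to long format
#'
#' @param series list of mesh tables from [project_series()].
#' @param start_year calendar year of the first element.
#' @param step_years years per step.
#' @param sample_index sampling index recorded in the output.
#' @return `data.frame` with columns `mesh_id`, `year`, `sex`, `age_band`,
#'   `count`, `sample_index` — the CSV interchange layout.
#' @export
population_long <- function(series, start_year = 2010, step_years = 5,
                            sample_index = 1L) {
  pieces <- lapply(seq_along(series), function(k) {
    meshes <- series[[k]]
    grid <- expand.grid(mesh_id = meshes$mesh_id, sex = .SEXES,
                        age_band = .AGE_BANDS, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    pm <- as.matrix(meshes[, pop_cols()])
    # pop_cols order: female bands 1..18, then male bands 19..36
    grid$count <- pm[cbind(match(grid$mesh_id, meshes$mesh_id),
                           (match(grid$sex, .SEXES) - 1L) * 18L +
                             match(grid$age_band, .AGE_BANDS))]
    grid$year <- start_year + (k - 1L) * step_years
    grid$sample_index <- sample_index
    grid[, c("mesh_id", "year", "sex", "age_band", "count", "sample_index")]
  })
  do.call(rbind, pieces)
}
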