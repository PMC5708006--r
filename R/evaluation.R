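# Orchestration: repeat (project population -> sample patients -> allocate)
# over years and Monte Carlo samplings for one scenario, aggregate means and
# standard deviations over samplings, and compare scenarios.

#' Run one scenario over years and repeated samplings
#'
#' For each of the scenario's `n_samples` samplings: project every mesh's
#' population over the year grid (independently re-projected per sampling),
#' draw the daily inpatient census per mesh, and allocate patients to beds
#' within their Patient Access Areas. Travel times, PAAs and capacities are
#' computed once. Aggregates are the mean and standard deviation over
#' samplings of total patients, over-demand and over-supply per year, plus
#' per-mesh mean over-demand and per-hospital mean vacancy. Everything is
#' reproducible from the scenario's seed.
#'
#' @param region a `paam_region` (from [generate_region()] or
#'   [read_region()]).
#' @param scenario a `paam_scenario`.
#' @param n_steps number of 5-year projection steps (default 6: a
#'   seven-point, 30-year horizon).
#' @param start_year calendar label of the first year point.
#' @param strategy allocation strategy, see [allocate()].
#' @param reuse_projection if TRUE, one population projection (sampling 1)
#'   is shared by all samplings — a variance-reduction option; by default
#'   the population is re-projected independently in every sampling.
#' @param travel_mode `"network"` or `"direct"`, see [build_travel_matrix()].
#' @return an object of class `paam_run`.
#' @export
run_scenario <- function(region, scenario, n_steps = 6L, start_year = 2010,
                         strategy = "size_first", reuse_projection = FALSE,
                         travel_mode = "network") {
  stopifnot(inherits(scenario, "paam_scenario"))
  meshes <- region$meshes
  hospitals <- region$hospitals
  if (is.null(meshes) || nrow(meshes) == 0)
    stop("region has no meshes", call. = FALSE)
  validate_meshes(meshes)
  validate_hospitals(hospitals)
  rates <- region$rates
  years <- start_year + 5L * (0:n_steps)

  tm <- build_travel_matrix(meshes, hospitals, region$network,
                            mode = travel_mode)
  paa <- compute_paa(tm, scenario$paa_threshold_minutes)
  caps <- setNames(
    available_beds(hospitals$total_beds, scenario$utilization_rate,
                   hospitals$in_region, scenario$external_bed_fraction),
    hospitals$hospital_id)

  n_years <- n_steps + 1L
  nm <- nrow(meshes)
  nh <- nrow(hospitals)
  tot_pat <- matrix(0, scenario$n_samples, n_years)
  tot_od <- matrix(0, scenario$n_samples, n_years)
  tot_os <- matrix(0, scenario$n_samples, n_years)
  mesh_od <- matrix(0, n_years, nm, dimnames = list(years, meshes$mesh_id))
  hosp_vac <- matrix(0, n_years, nh,
                     dimnames = list(years, hospitals$hospital_id))

  pcfg <- projection_config(n_steps = n_steps, mode = "stochastic",
                            seed = scenario$seed)
  R_ad <- scenario$inpatient_rate_reduction
  D_ad <- scenario$alos_reduction

  for (s in seq_len(scenario$n_samples)) {
    proj_sample <- if (reuse_projection) 1L else s
    series <- project_series(meshes, rates, pcfg,
                             sample_index = proj_sample)
    for (k in seq_len(n_years)) {
      my <- series[[k]]
      pm <- as.matrix(my[, pop_cols()])
      padj <- adjusted_inpatient_prob(rates, R_ad, D_ad)
      w <- c(padj["female", ], padj["male", ])
      patients <- setNames(integer(nm), my$mesh_id)
      for (i in seq_len(nm)) {
        set.seed(derive_seed(scenario$seed, .STAGE$incidence, s, k,
                             my$mesh_id[i]))
        patients[i] <- sum(rbinom(36L, as.integer(pm[i, ]), w))
      }
      set.seed(derive_seed(scenario$seed, .STAGE$allocate, s, k))
      res <- allocate(patients, paa, hospitals, tm, scenario,
                      strategy = strategy, capacities = caps)
      tot_pat[s, k] <- res$n_patients
      tot_od[s, k] <- sum(res$unallocated)
      tot_os[s, k] <- sum(res$remaining)
      mesh_od[k, ] <- mesh_od[k, ] + res$unallocated[meshes$mesh_id]
      hosp_vac[k, ] <- hosp_vac[k, ] + res$remaining[hospitals$hospital_id]
    }
  }

  ns <- scenario$n_samples
  col_sd <- function(m) if (nrow(m) > 1) apply(m, 2, sd) else rep(NA_real_, ncol(m))
  totals <- data.frame(
    year = years,
    patients_mean = colMeans(tot_pat), patients_sd = col_sd(tot_pat),
    overdemand_mean = colMeans(tot_od), overdemand_sd = col_sd(tot_od),
    oversupply_mean = colMeans(tot_os), oversupply_sd = col_sd(tot_os)
  )
  totals$allocated_mean <- totals$patients_mean - totals$overdemand_mean

  structure(
    list(scenario = scenario, years = years, n_samples = ns,
         totals = totals,
         mesh_overdemand = mesh_od / ns,
         hospital_vacancy = hosp_vac / ns,
         capacity_total = sum(caps),
         capacities = caps,
         strategy = strategy,
         first_overdemand_year = first_positive_year(years,
                                                     totals$overdemand_mean)),
    class = "paam_run"
  )
}

first_positive_year <- function(years, values) {
  i <- which(values > 0)
  if (length(i)) years[min(i)] else Inf
}

#' @export
print.paam_run <- function(x, digits = 1, ...) {
  cat(sprintf("Scenario '%s' (%d samplings, capacity %d beds)\n",
              x$scenario$name, x$n_samples, x$capacity_total))
  tab <- x$totals
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  if (is.finite(x$first_overdemand_year))
    cat(sprintf("First year with mean over-demand: %d\n",
                as.integer(x$first_overdemand_year)))
  else cat("No over-demand in any year\n")
  invisible(x)
}

#' @export
summary.paam_run <- function(object, n_top = 5, ...) {
  print(object, ...)
  final <- object$mesh_overdemand[nrow(object$mesh_overdemand), ]
  top <- sort(final[final > 0], decreasing = TRUE)
  if (length(top)) {
    cat(sprintf("\nTop over-demand meshes in %d (mean patients/day):\n",
                max(object$years)))
    print(round(head(top, n_top), 2))
  }
  invisible(object)
}

#' @export
plot.paam_run <- function(x, ...) {
  tab <- x$totals
  ylim <- range(0, tab$patients_mean, x$capacity_total)
  plot(tab$year, tab$patients_mean, type = "b", pch = 16, ylim = ylim,
       xlab = "year", ylab = "patients per day",
       main = x$scenario$name, ...)
  abline(h = x$capacity_total, lty = 2)
  lines(tab$year, tab$overdemand_mean, type = "b", pch = 1, col = 2)
  legend("topleft", bty = "n",
         legend = c("demand (mean)", "available beds", "over-demand (mean)"),
         lty = c(1, 2, 1), pch = c(16, NA, 1), col = c(1, 1, 2))
  invisible(x)
}

#' Run and align several scenarios on one region
#'
#' @param region a `paam_region`.
#' @param scenarios list of at least two `paam_scenario` objects with unique
#'   names (default: the three standard scenarios).
#' @param ... passed to [run_scenario()].
#' @return an object of class `paam_comparison`: the individual runs, a
#'   per-year table of scenario mean over-demand (and patients and
#'   over-supply), and each scenario's first year with positive mean
#'   over-demand (`Inf` if none).
#' @export
compare_scenarios <- function(region, scenarios = default_scenarios(), ...) {
  if (length(scenarios) < 2)
    stop("need at least two scenarios to compare", call. = FALSE)
  nms <- vapply(scenarios, function(s) s$name, character(1))
  if (anyDuplicated(nms)) stop("scenario names must be unique", call. = FALSE)
  runs <- lapply(scenarios, function(s) run_scenario(region, s, ...))
  names(runs) <- nms
  years <- runs[[1]]$years
  tab <- data.frame(year = years)
  for (nm in nms) {
    tab[[paste0("overdemand.", nm)]] <- runs[[nm]]$totals$overdemand_mean
    tab[[paste0("patients.", nm)]] <- runs[[nm]]$totals$patients_mean
    tab[[paste0("oversupply.", nm)]] <- runs[[nm]]$totals$oversupply_mean
  }
  structure(
    list(runs = runs, table = tab,
         first_overdemand = vapply(runs, function(r) r$first_overdemand_year,
                                   numeric(1))),
    class = "paam_comparison"
  )
}

#' @export
print.paam_comparison <- function(x, digits = 1, ...) {
  cat(sprintf("Scenario comparison (%d scenarios, %d year points)\n",
              length(x$runs), nrow(x$table)))
  od <- x$table[, c("year", grep("^overdemand\\.", names(x$table),
                                 value = TRUE))]
  od[-1] <- lapply(od[-1], round, digits)
  print(od, row.names = FALSE)
  cat("First year with mean over-demand:\n")
  print(x$first_overdemand)
  invisible(x)
}

#' @export
plot.paam_comparison <- function(x, ...) {
  od <- as.matrix(x$table[, grep("^overdemand\\.", names(x$table))])
  matplot(x$table$year, od, type = "b", pch = 16, lty = 1,
          xlab = "year", ylab = "mean over-demand (patients/day)", ...)
  legend("topleft", bty = "n", col = seq_len(ncol(od)), lty = 1, pch = 16,
         legend = sub("^overdemand\\.", "", colnames(od)))
  invisible(x)
}

#' Export a per-mesh over-demand choropleth layer
#'
#' Writes one GeoJSON Polygon per mesh carrying the mean over-demand, ready
#' for choropleth rendering in any GIS.
#'
#' @param overdemand named numeric vector of mean over-demand per mesh id,
#'   or a `paam_run` (then `year` selects the row of its per-mesh means).
#' @param meshes the region's mesh table.
#' @param path output `.geojson` path.
#' @param year year point to export when `overdemand` is a `paam_run`
#'   (default: the final year).
#' @export
export_overdemand_map <- function(overdemand, meshes, path, year = NULL) {
  if (inherits(overdemand, "paam_run")) {
    yrs <- overdemand$years
    year <- year %||% max(yrs)
    if (!year %in% yrs) stop("year not in the run's year grid", call. = FALSE)
    overdemand <- overdemand$mesh_overdemand[as.character(year), ]
  }
  if (is.null(names(overdemand)) ||
      !setequal(names(overdemand), meshes$mesh_id))
    stop("over-demand values must be named by the region's mesh ids",
         call. = FALSE)
  write_meshes_geojson(
    meshes, path,
    properties = list(overdemand = as.numeric(overdemand[meshes$mesh_id])))
}
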