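# Patient-to-bed allocation. All patients from all meshes are shuffled into
# one random order; each patient in turn takes a bed at the best-ranked
# hospital of their mesh's PAA that still has capacity. The default ranking
# prefers larger size classes first and shorter travel times second (ties by
# hospital id), reflecting the tendency of patients to choose large,
# well-equipped hospitals as close to home as possible. A patient with no
# free bed anywhere in their PAA counts toward the mesh's over-demand.

#' Allocate sampled patients to hospital beds
#'
#' @param patients named integer vector: daily inpatient count per mesh id
#'   (e.g. from [sample_inpatients()] on a mesh table).
#' @param paa a `paam_paa` from [compute_paa()]; every mesh with patients
#'   must be indexed.
#' @param hospitals a hospital table.
#' @param travel_matrix mesh-by-hospital minutes from
#'   [build_travel_matrix()], used for the time-priority ranking.
#' @param scenario a `paam_scenario`; supplies the utilization rate and
#'   external-bed cap (ignored when `capacities` is given).
#' @param strategy hospital ranking: `"size_first"` (size class descending,
#'   then minutes ascending — the default), `"time_first"` (minutes
#'   ascending, then size class descending), or `"huff"` (each patient draws
#'   one hospital among those with free beds with probability proportional
#'   to `beds^alpha / minutes^beta`, a gravity-model alternative).
#' @param capacities optional named integer vector of available beds per
#'   hospital, overriding [available_beds()] from the scenario.
#' @param huff_alpha,huff_beta gravity exponents for `strategy = "huff"`
#'   (attractiveness on beds, decay on travel time; minutes are floored at 1
#'   to keep co-located pairs finite).
#' @return an object of class `paam_allocation`: `allocated` and `remaining`
#'   per hospital, `unallocated` (over-demand) per mesh, `available`
#'   capacities, and the patient total. The identities
#'   `allocated + remaining == available` and
#'   `sum(allocated) + sum(unallocated) == sum(patients)` always hold.
#'
#'   Randomness (the global patient order, and per-patient draws under
#'   `"huff"`) uses the current RNG state; seed before calling for
#'   reproducibility.
#' @export
allocate <- function(patients, paa, hospitals, travel_matrix,
                     scenario = NULL,
                     strategy = c("size_first", "time_first", "huff"),
                     capacities = NULL, huff_alpha = 1, huff_beta = 2) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(paa, "paam_paa"))
  validate_hospitals(hospitals)
  if (is.null(names(patients)) || anyNA(patients) || any(patients < 0) ||
      any(patients != round(patients)))
    stop("patients must be a named vector of non-negative integer counts",
         call. = FALSE)
  missing_mesh <- setdiff(names(patients)[patients > 0], names(paa$by_mesh))
  if (length(missing_mesh))
    stop("meshes absent from the PAA index: ",
         paste(head(missing_mesh, 3), collapse = ", "), call. = FALSE)
  hid <- hospitals$hospital_id
  if (is.null(capacities)) {
    if (is.null(scenario)) stop("supply either scenario or capacities",
                                call. = FALSE)
    capacities <- setNames(
      available_beds(hospitals$total_beds, scenario$utilization_rate,
                     hospitals$in_region, scenario$external_bed_fraction),
      hid)
  }
  capacities <- capacities[hid]
  if (anyNA(capacities)) stop("capacities must cover every hospital",
                              call. = FALSE)

  size_rank <- as.integer(hospitals$size_class)  # 1 small .. 3 large
  active <- names(patients)[patients > 0]
  # per-mesh candidate ranking, computed once
  cand <- lapply(active, function(m) {
    h <- intersect(paa$by_mesh[[m]], hid)
    if (!length(h)) return(integer(0))
    j <- match(h, hid)
    mins <- travel_matrix[m, h]
    ord <- switch(strategy,
                  size_first = order(-size_rank[j], mins, hid[j]),
                  time_first = order(mins, -size_rank[j], hid[j]),
                  huff = seq_along(j))
    j[ord]
  })
  names(cand) <- active

  cap <- as.integer(capacities)
  alloc <- integer(length(hid))
  unalloc <- setNames(integer(length(patients)), names(patients))

  order_ids <- rep(active, patients[active])
  if (length(order_ids)) order_ids <- order_ids[sample.int(length(order_ids))]

  if (strategy == "huff") {
    weights <- lapply(active, function(m) {
      j <- cand[[m]]
      if (!length(j)) return(numeric(0))
      hospitals$total_beds[j]^huff_alpha /
        pmax(travel_matrix[m, hid[j]], 1)^huff_beta
    })
    names(weights) <- active
    for (m in order_ids) {
      j <- cand[[m]]
      open <- j[cap[j] > 0L]
      if (!length(open)) {
        unalloc[m] <- unalloc[m] + 1L
        next
      }
      w <- weights[[m]][match(open, j)]
      pick <- if (length(open) == 1L) open else
        open[sample.int(length(open), 1L, prob = w)]
      cap[pick] <- cap[pick] - 1L
      alloc[pick] <- alloc[pick] + 1L
    }
  } else {
    ptr <- setNames(rep(1L, length(active)), active)
    for (m in order_ids) {
      j <- cand[[m]]
      k <- ptr[m]
      while (k <= length(j) && cap[j[k]] == 0L) k <- k + 1L
      ptr[m] <- k
      if (k > length(j)) {
        unalloc[m] <- unalloc[m] + 1L
      } else {
        h <- j[k]
        cap[h] <- cap[h] - 1L
        alloc[h] <- alloc[h] + 1L
      }
    }
  }

  structure(
    list(allocated = setNames(alloc, hid),
         remaining = setNames(cap, hid),
         available = setNames(as.integer(capacities), hid),
         unallocated = unalloc,
         n_patients = sum(patients),
         strategy = strategy),
    class = "paam_allocation"
  )
}

#' @export
print.paam_allocation <- function(x, ...) {
  cat(sprintf(
    "Allocation (%s): %d patients -> %d allocated, %d over-demand; %d of %d beds vacant\n",
    x$strategy, x$n_patients, sum(x$allocated), sum(x$unallocated),
    sum(x$remaining), sum(x$available)))
  invisible(x)
}
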