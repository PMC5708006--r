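# Synthetic region generator: a fully controllable stand-in for census mesh
# populations, a hospital registry, demographic/inpatient rate tables, and a
# road network, so that every pipeline stage runs and is testable without
# any external data.

#' Specify a synthetic region
#'
#' @param nx,ny grid dimensions (meshes).
#' @param total_population total head count, distributed over meshes,
#'   sexes and age bands by one multinomial draw (so the grand total is
#'   exact).
#' @param mesh_size_m mesh edge length in meters (default 500).
#' @param age_pyramid length-18 vector of age-band fractions summing to 1
#'   (applied to both sexes).
#' @param sex_split fraction female.
#' @param n_hospitals number of hospitals to place.
#' @param bed_distribution list with `weights` (named fractions over
#'   `small`/`medium`/`large` summing to 1) and `ranges` (named list of
#'   `c(min, max)` bed counts per class, consistent with the size bands of
#'   [classify_hospital_size()]).
#' @param hospital_placement `"population_weighted"` (hospitals gravitate to
#'   populous meshes, as real facilities do) or `"uniform"`.
#' @param network_speed_kmh travel speed on road edges (default 40).
#' @param density_decay controls how strongly population concentrates in the
#'   grid centre (Gaussian kernel sd as a fraction of the grid extent);
#'   larger is flatter.
#' @param out_region_fraction probability a hospital is flagged
#'   out-of-region (subject to the external-bed cap).
#' @param edge_removal_fraction fraction of road edges severed at random, to
#'   create access-poor pockets.
#' @param rates optional `paam_rates` to embed; defaults to
#'   [default_rate_tables()].
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `paam_region_spec`.
#' @export
region_spec <- function(nx, ny, total_population,
                        n_hospitals = max(1L, round(nx * ny / 40)),
                        mesh_size_m = 500,
                        age_pyramid = default_age_pyramid(),
                        sex_split = 0.513,
                        bed_distribution = default_bed_distribution(),
                        hospital_placement = c("population_weighted",
                                               "uniform"),
                        network_speed_kmh = 40,
                        density_decay = 0.35,
                        out_region_fraction = 0,
                        edge_removal_fraction = 0,
                        rates = NULL,
                        seed = 1L) {
  hospital_placement <- match.arg(hospital_placement)
  if (nx < 1 || ny < 1) stop("grid must have at least one mesh", call. = FALSE)
  if (total_population < 0) stop("total_population must be >= 0", call. = FALSE)
  if (n_hospitals < 1) stop("need at least one hospital", call. = FALSE)
  if (length(age_pyramid) != 18 || any(age_pyramid < 0) ||
      abs(sum(age_pyramid) - 1) > 1e-9)
    stop("age_pyramid must be 18 non-negative fractions summing to 1",
         call. = FALSE)
  if (sex_split < 0 || sex_split > 1)
    stop("sex_split must be in [0, 1]", call. = FALSE)
  w <- bed_distribution$weights
  rg <- bed_distribution$ranges
  if (is.null(w) || is.null(rg) ||
      !setequal(names(w), c("small", "medium", "large")) ||
      abs(sum(w) - 1) > 1e-9 || any(w < 0))
    stop("bed_distribution$weights must be fractions over small/medium/large summing to 1",
         call. = FALSE)
  for (cls in names(rg)) {
    r <- rg[[cls]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 1)
      stop("bad bed range for class ", cls, call. = FALSE)
    if (any(as.character(classify_hospital_size(round(r))) != cls))
      stop("bed range for class ", cls,
           " is inconsistent with the size classification", call. = FALSE)
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny),
         mesh_size_m = mesh_size_m,
         total_population = as.integer(total_population),
         age_pyramid = age_pyramid / sum(age_pyramid),
         sex_split = sex_split,
         n_hospitals = as.integer(n_hospitals),
         bed_distribution = bed_distribution,
         hospital_placement = hospital_placement,
         network_speed_kmh = network_speed_kmh,
         density_decay = density_decay,
         out_region_fraction = out_region_fraction,
         edge_removal_fraction = edge_removal_fraction,
         rates = rates,
         seed = as.integer(seed)),
    class = "paam_region_spec"
  )
}

#' Default age pyramid
#'
#' An aged-population pyramid (thin child bands, a late-middle-age bulge,
#' about 23% aged 65+), normalized to sum to 1.
#'
#' @return length-18 vector of fractions.
#' @export
default_age_pyramid <- function() {
  p <- c(0.042, 0.043, 0.045, 0.048, 0.051, 0.057, 0.063, 0.072,
         0.064, 0.060, 0.060, 0.065, 0.078, 0.062, 0.055, 0.047,
         0.034, 0.034)
  p / sum(p)
}

#' Default hospital bed-count mixture
#'
#' Roughly half small facilities, with a mean around 190 beds per hospital
#' (comparable to national hospital registries).
#'
#' @return list with `weights` and per-class `ranges`.
#' @export
default_bed_distribution <- function() {
  list(weights = c(small = 0.45, medium = 0.45, large = 0.10),
       ranges = list(small = c(20, 100), medium = c(101, 399),
                     large = c(400, 700)))
}

# deterministic mesh weights: urban-core Gaussian plus a uniform floor
mesh_density_weights <- function(nx, ny, decay) {
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  s <- decay * max(nx, ny)
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  w <- exp(-((g$col - cx)^2 + (g$row - cy)^2) / (2 * s^2)) + 0.1
  w / sum(w)
}

# hospitals gravitate to populous meshes (or are spread uniformly)
place_hospitals <- function(meshes, n_hospitals, placement, bed_distribution,
                            out_region_fraction, seed) {
  set.seed(derive_seed(seed, .STAGE$synth_hosp))
  totals <- rowSums(as.matrix(meshes[, pop_cols()]))
  prob <- if (placement == "population_weighted" && sum(totals) > 0)
    totals else rep(1, nrow(meshes))
  at <- sample.int(nrow(meshes), n_hospitals, replace = TRUE, prob = prob)
  w <- bed_distribution$weights
  cls <- sample(names(w), n_hospitals, replace = TRUE, prob = w)
  beds <- vapply(cls, function(cl) {
    r <- round(bed_distribution$ranges[[cl]])
    if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
  }, numeric(1))
  in_region <- runif(n_hospitals) >= out_region_fraction
  hospital_table(sprintf("h%03d", seq_len(n_hospitals)),
                 meshes$x[at], meshes$y[at], beds, in_region)
}

#' Generate a complete synthetic region
#'
#' Builds, reproducibly from the spec's seed: an `nx` x `ny` mesh grid whose
#' populations are one multinomial draw over mesh x sex x age band (grand
#' total exact, meshes weighted toward an urban core); hospitals placed per
#' the placement rule with bed counts from the class mixture; the default
#' (or supplied) rate tables; and a 4-connected grid road network over the
#' mesh centroids whose edge minutes equal edge length divided by the
#' network speed.
#'
#' @param spec a `paam_region_spec`.
#' @return an object of class `paam_region`: list with `meshes`,
#'   `hospitals`, `rates`, `network` and the `spec`.
#' @examples
#' region <- generate_region(region_spec(nx = 3, ny = 3,
#'                                       total_population = 2000,
#'                                       n_hospitals = 2, seed = 42))
#' population_total(region$meshes)
#' @export
generate_region <- function(spec) {
  stopifnot(inherits(spec, "paam_region_spec"))
  nx <- spec$nx; ny <- spec$ny; sz <- spec$mesh_size_m
  g <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  ids <- sprintf("m%03d_%03d", g$row, g$col)
  xs <- (g$col - 0.5) * sz
  ys <- (g$row - 0.5) * sz

  # one multinomial draw over mesh x sex x band conserves the grand total
  set.seed(derive_seed(spec$seed, .STAGE$synth_pop))
  mesh_w <- mesh_density_weights(nx, ny, spec$density_decay)
  cell_prob <- as.vector(outer(
    mesh_w, c(spec$sex_split * spec$age_pyramid,
              (1 - spec$sex_split) * spec$age_pyramid)))
  counts <- as.vector(stats::rmultinom(1, spec$total_population, cell_prob))
  pm <- matrix(counts, nrow = nx * ny, ncol = 36,
               dimnames = list(NULL, pop_cols()))
  meshes <- mesh_table(ids, xs, ys, mesh_size_m = sz)
  meshes[, pop_cols()] <- pm

  hospitals <- place_hospitals(meshes, spec$n_hospitals,
                               spec$hospital_placement,
                               spec$bed_distribution,
                               spec$out_region_fraction, spec$seed)

  rates <- spec$rates %||% default_rate_tables()

  # 4-connected grid road network over mesh centroids
  node_id <- paste0("n_", ids)
  right <- which(g$col < nx)
  up <- which(g$row < ny)
  a <- c(node_id[right], node_id[up])
  b <- c(node_id[right + 1L], node_id[up + nx])
  minutes <- rep((sz / 1000) / spec$network_speed_kmh * 60, length(a))
  edges <- data.frame(node_a = a, node_b = b, minutes = minutes,
                      stringsAsFactors = FALSE)
  if (spec$edge_removal_fraction > 0 && nrow(edges) > 0) {
    set.seed(derive_seed(spec$seed, .STAGE$synth_net))
    keep <- runif(nrow(edges)) >= spec$edge_removal_fraction
    edges <- edges[keep, , drop = FALSE]
  }
  network <- road_network(
    data.frame(node_id = node_id, x = xs, y = ys, stringsAsFactors = FALSE),
    edges)

  structure(list(meshes = meshes, hospitals = hospitals, rates = rates,
                 network = network, spec = spec),
            class = "paam_region")
}

#' @export
print.paam_region <- function(x, ...) {
  cat(sprintf(
    "Region: %d meshes, %s people, %d hospitals (%s beds)\n",
    nrow(x$meshes),
    format(population_total(x$meshes), big.mark = ","),
    nrow(x$hospitals),
    format(sum(x$hospitals$total_beds), big.mark = ",")))
  invisible(x)
}

#' A compact metropolitan-style demonstration region
#'
#' A 20 x 20 grid (10 km square) of 500-m meshes holding 50,000 people with
#' an aged pyramid, and 10 small hospitals of 30-60 beds each (about 9 beds
#' per 1,000 population in expectation — within the per-capita bed supply
#' of developed-country metropolises), so that baseline daily demand sits
#' just below available capacity and population aging pushes it over within
#' the simulation horizon. With 10 facilities serving 50,000 people,
#' per-capita realism forces all of them to be small; an all-small registry
#' also keeps total capacity stable across seeds, which a rare large-
#' hospital draw would swamp.
#'
#' @param seed integer seed.
#' @return a `paam_region_spec`.
#' @export
demo_region_spec <- function(seed = 1L) {
  region_spec(
    nx = 20, ny = 20, total_population = 50000, n_hospitals = 10,
    bed_distribution = list(
      weights = c(small = 1, medium = 0, large = 0),
      ranges = list(small = c(30, 60), medium = c(101, 399),
                    large = c(400, 700))),
    seed = seed
  )
}

#' Write or read a region as its component files
#'
#' Files in `dir`: `meshes.csv`, `hospitals.csv`, `rates.csv`,
#' `network_nodes.csv`, `network_edges.csv`.
#'
#' @param region a `paam_region` (or a list with the same elements).
#' @param dir directory path.
#' @return `read_region()` returns a `paam_region` (without a spec).
#' @export
write_region <- function(region, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_meshes(region$meshes, file.path(dir, "meshes.csv"))
  write_hospitals(region$hospitals, file.path(dir, "hospitals.csv"))
  write_rate_tables(region$rates, file.path(dir, "rates.csv"))
  write_network(region$network, file.path(dir, "network_nodes.csv"),
                file.path(dir, "network_edges.csv"))
  invisible(dir)
}

#' @rdname write_region
#' @export
read_region <- function(dir) {
  need <- c("meshes.csv", "hospitals.csv", "rates.csv",
            "network_nodes.csv", "network_edges.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("region directory is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  structure(
    list(meshes = read_meshes(file.path(dir, "meshes.csv")),
         hospitals = read_hospitals(file.path(dir, "hospitals.csv")),
         rates = read_rate_tables(file.path(dir, "rates.csv")),
         network = read_network(file.path(dir, "network_nodes.csv"),
                                file.path(dir, "network_edges.csv")),
         spec = NULL),
    class = "paam_region"
  )
}
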