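# Plain-text interchange: CSV for meshes, hospitals, rate tables, networks
# and travel matrices; GeoJSON for mesh polygons. Readers validate the type
# invariants so that write-then-read is the identity on valid data and
# invalid files fail with a specific message.

#' Read and write mesh tables as CSV
#'
#' Columns: `mesh_id`, `x`, `y`, then 36 population columns
#' `pop_f_0_4` ... `pop_m_85p`.
#'
#' @param path CSV file path.
#' @param mesh_size_m cell size attribute to attach on read.
#' @return `read_meshes()` returns a validated mesh table.
#' @export
read_meshes <- function(path, mesh_size_m = 500) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$mesh_id <- as.character(df$mesh_id)
  validate_meshes(df, integral = TRUE)
  df <- df[, c("mesh_id", "x", "y", pop_cols())]
  attr(df, "mesh_size_m") <- mesh_size_m
  df
}

#' @param meshes a mesh table.
#' @rdname read_meshes
#' @export
write_meshes <- function(meshes, path) {
  validate_meshes(meshes, integral = TRUE)
  write.csv(meshes[, c("mesh_id", "x", "y", pop_cols())], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write hospital registries as CSV
#'
#' Columns: `hospital_id`, `x`, `y`, `total_beds`, `in_region`. The size
#' class is derived on read, never stored.
#'
#' @param path CSV file path.
#' @return `read_hospitals()` returns a validated hospital table.
#' @export
read_hospitals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("hospital_id", "x", "y", "total_beds", "in_region")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("hospital file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  hospital_table(df$hospital_id, df$x, df$y, df$total_beds,
                 as.logical(df$in_region))
}

#' @param hospitals a hospital table.
#' @rdname read_hospitals
#' @export
write_hospitals <- function(hospitals, path) {
  validate_hospitals(hospitals)
  write.csv(hospitals[, c("hospital_id", "x", "y", "total_beds", "in_region")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write rate tables as CSV
#'
#' One row per sex x age band with columns `sex`, `age_band`, `survival`,
#' `net_migration`, `inpatient_rate`, `fertility` (populated only for female
#' bands 15-19 .. 45-49) and `sex_ratio_at_birth` (repeated).
#'
#' @param path CSV file path.
#' @return `read_rate_tables()` returns a `paam_rates` object.
#' @export
read_rate_tables <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age_band", "survival", "net_migration",
            "inpatient_rate", "fertility", "sex_ratio_at_birth")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("rate file is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  pick <- function(col) {
    m <- matrix(NA_real_, 2, 18, dimnames = list(.SEXES, .AGE_BANDS))
    idx <- cbind(match(df$sex, .SEXES), match(df$age_band, .AGE_BANDS))
    if (anyNA(idx)) stop("unknown sex or age_band in rate file", call. = FALSE)
    m[idx] <- df[[col]]
    if (anyNA(m)) stop("rate file does not cover every sex x band for ",
                       col, call. = FALSE)
    m
  }
  fert_rows <- df$sex == "female" & df$age_band %in% .AGE_BANDS[.FERTILE_IDX]
  fert <- df$fertility[fert_rows][match(.AGE_BANDS[.FERTILE_IDX],
                                        df$age_band[fert_rows])]
  rate_tables(
    fertility = fert,
    sex_ratio_at_birth = df$sex_ratio_at_birth[1],
    survival = pick("survival"),
    net_migration = pick("net_migration"),
    inpatient_rate = pick("inpatient_rate")
  )
}

#' @param rates a `paam_rates` object.
#' @rdname read_rate_tables
#' @export
write_rate_tables <- function(rates, path) {
  stopifnot(inherits(rates, "paam_rates"))
  df <- expand.grid(age_band = .AGE_BANDS, sex = .SEXES,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df <- df[, c("sex", "age_band")]
  idx <- cbind(match(df$sex, .SEXES), match(df$age_band, .AGE_BANDS))
  df$survival <- rates$survival[idx]
  df$net_migration <- rates$net_migration[idx]
  df$inpatient_rate <- rates$inpatient_rate[idx]
  df$fertility <- NA_real_
  fr <- df$sex == "female" & df$age_band %in% names(rates$fertility)
  df$fertility[fr] <- rates$fertility[df$age_band[fr]]
  df$sex_ratio_at_birth <- rates$sex_ratio_at_birth
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write mesh polygons as GeoJSON
#'
#' Each mesh becomes a square Polygon feature (side `mesh_size_m`, centred on
#' the centroid) with the mesh id, total population, and optionally a named
#' vector of extra per-mesh properties (e.g. mean over-demand).
#'
#' @param meshes a mesh table.
#' @param path output `.geojson` path.
#' @param properties optional named list of per-mesh property vectors, each
#'   aligned with `meshes$mesh_id`.
#' @param mesh_size_m cell size; defaults to the table's attribute or 500.
#' @export
write_meshes_geojson <- function(meshes, path, properties = NULL,
                                 mesh_size_m = NULL) {
  validate_meshes(meshes, integral = FALSE)
  if (is.null(mesh_size_m))
    mesh_size_m <- attr(meshes, "mesh_size_m") %||% 500
  h <- mesh_size_m / 2
  features <- lapply(seq_len(nrow(meshes)), function(i) {
    x <- meshes$x[i]; y <- meshes$y[i]
    ring <- list(c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
                 c(x - h, y + h), c(x - h, y - h))
    props <- list(mesh_id = meshes$mesh_id[i],
                  total_population = sum(meshes[i, pop_cols()]))
    for (nm in names(properties)) props[[nm]] <- properties[[nm]][i]
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-mesh properties back from an exported GeoJSON
#'
#' @param path a `.geojson` written by [write_meshes_geojson()] or
#'   [export_overdemand_map()].
#' @return `data.frame` of the feature properties, one row per mesh.
#' @export
read_meshes_geojson <- function(path) {
  fc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  props <- lapply(fc$features, function(f) as.data.frame(f$properties))
  do.call(rbind, props)
}

#' Read and write road networks as CSV pairs
#'
#' Nodes: `node_id`, `x`, `y`. Edges: `node_a`, `node_b`, `minutes`
#' (undirected, positive travel minutes).
#'
#' @param nodes_path,edges_path CSV file paths.
#' @return `read_network()` returns a `paam_network`.
#' @export
read_network <- function(nodes_path, edges_path) {
  nodes <- read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- read.csv(edges_path, stringsAsFactors = FALSE)
  road_network(nodes, edges)
}

#' @param network a `paam_network`.
#' @rdname read_network
#' @export
write_network <- function(network, nodes_path, edges_path) {
  stopifnot(inherits(network, "paam_network"))
  write.csv(network$nodes, nodes_path, row.names = FALSE, quote = FALSE)
  write.csv(network$edges, edges_path, row.names = FALSE, quote = FALSE)
  invisible(c(nodes_path, edges_path))
}

#' Read and write mesh-by-hospital travel-time matrices as CSV
#'
#' Rows are meshes (first column `mesh_id`), remaining columns one per
#' hospital id; entries are minutes, with unreachable pairs stored as `Inf`.
#'
#' @param path CSV file path.
#' @return `read_travel_matrix()` returns a numeric matrix with mesh ids as
#'   row names and hospital ids as column names.
#' @export
read_travel_matrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (any(is.na(m)) || any(m < 0))
    stop("travel times must be non-negative (Inf for unreachable)",
         call. = FALSE)
  m
}

#' @param matrix mesh-by-hospital matrix of minutes.
#' @rdname read_travel_matrix
#' @export
write_travel_matrix <- function(matrix, path) {
  df <- data.frame(mesh_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
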