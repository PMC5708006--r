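# Core domain vocabulary: 5-year age bands, the sex x age population matrix,
# and the mesh table that carries one such population per 500-m grid cell.

.AGE_BANDS <- c(
  "0-4", "5-9", "10-14", "15-19", "20-24", "25-29", "30-34", "35-39",
  "40-44", "45-49", "50-54", "55-59", "60-64", "65-69", "70-74",
  "75-79", "80-84", "85+"
)
.SEXES <- c("female", "male")
# indices of the reproductive bands 15-19 .. 45-49
.FERTILE_IDX <- 4:10

#' Five-year age bands used throughout the model
#'
#' Eighteen bands from 0-4 to the absorbing top band 85+.
#'
#' @return character vector of band labels.
#' @export
age_bands <- function() .AGE_BANDS

# column suffixes for mesh tables: "0_4", ..., "85p"
band_suffix <- function() gsub("-", "_", sub("\\+$", "p", .AGE_BANDS))

# population column names in mesh tables, female bands then male bands
pop_cols <- function() {
  c(paste0("pop_f_", band_suffix()), paste0("pop_m_", band_suffix()))
}

#' Construct an age-by-sex population matrix
#'
#' The unit of demand bookkeeping: a 2 x 18 matrix of counts, rows
#' `female`/`male`, columns the 18 five-year age bands.
#'
#' @param counts numeric matrix (2 x 18), or a single value recycled.
#'   Counts must be non-negative; integrality is required by the stochastic
#'   operations but not by this constructor (the deterministic expected-value
#'   projection produces real-valued populations).
#' @return a named 2 x 18 matrix.
#' @examples
#' p <- population(0)
#' p["female", "30-34"] <- 120
#' population_total(p)
#' @export
population <- function(counts = 0) {
  m <- matrix(as.numeric(counts), nrow = 2, ncol = 18,
              dimnames = list(.SEXES, .AGE_BANDS))
  validate_population(m, integral = FALSE)
  m
}

validate_population <- function(p, integral = TRUE) {
  if (!is.matrix(p) || !identical(dim(p), c(2L, 18L)))
    stop("population must be a 2 x 18 matrix (sex x age band)", call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)))
    stop("population contains missing or non-finite counts", call. = FALSE)
  if (any(p < 0))
    stop("population counts must be non-negative", call. = FALSE)
  if (integral && any(p != round(p)))
    stop("population counts must be integral", call. = FALSE)
  invisible(p)
}

#' Total population of an age-by-sex matrix or a mesh table
#'
#' @param x a population matrix from [population()], or a mesh table.
#' @return total head count.
#' @export
population_total <- function(x) {
  if (is.data.frame(x)) sum(as.matrix(x[, pop_cols()])) else sum(x)
}

#' Assemble a mesh table
#'
#' A mesh is a square grid cell (500 m by default) identified by `mesh_id`,
#' located by its centroid in a planar projected CRS (meters), and carrying
#' an age-by-sex population. The table stores one row per mesh with the
#' population spread over `pop_f_*`/`pop_m_*` columns, matching the CSV
#' interchange format.
#'
#' @param mesh_id unique character ids.
#' @param x,y centroid coordinates in meters.
#' @param populations list of 2 x 18 population matrices, one per mesh, or
#'   NULL for all-zero populations.
#' @param mesh_size_m cell edge length in meters (stored as an attribute).
#' @return a `data.frame` with columns `mesh_id`, `x`, `y` and 36 population
#'   columns.
#' @export
mesh_table <- function(mesh_id, x, y, populations = NULL, mesh_size_m = 500) {
  mesh_id <- as.character(mesh_id)
  if (anyDuplicated(mesh_id)) stop("duplicate mesh ids", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("mesh centroids must be finite", call. = FALSE)
  n <- length(mesh_id)
  pm <- matrix(0, n, 36, dimnames = list(NULL, pop_cols()))
  if (!is.null(populations)) {
    stopifnot(length(populations) == n)
    for (i in seq_len(n)) {
      validate_population(populations[[i]], integral = FALSE)
      pm[i, ] <- c(populations[[i]]["female", ], populations[[i]]["male", ])
    }
  }
  out <- data.frame(mesh_id = mesh_id, x = as.numeric(x), y = as.numeric(y),
                    pm, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "mesh_size_m") <- mesh_size_m
  out
}

validate_meshes <- function(meshes, integral = TRUE) {
  need <- c("mesh_id", "x", "y", pop_cols())
  missing <- setdiff(need, names(meshes))
  if (length(missing))
    stop("mesh table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(meshes$mesh_id))
    stop("duplicate mesh ids", call. = FALSE)
  if (any(!is.finite(meshes$x)) || any(!is.finite(meshes$y)))
    stop("mesh centroids must be finite", call. = FALSE)
  pm <- as.matrix(meshes[, pop_cols()])
  if (anyNA(pm) || any(pm < 0))
    stop("mesh populations must be non-negative and complete", call. = FALSE)
  if (integral && any(pm != round(pm)))
    stop("mesh populations must be integral", call. = FALSE)
  invisible(meshes)
}

#' Extract one mesh's population as a 2 x 18 matrix
#'
#' @param meshes a mesh table.
#' @param mesh_id id of the mesh to extract.
#' @return a 2 x 18 population matrix.
#' @export
mesh_population <- function(meshes, mesh_id) {
  i <- match(mesh_id, meshes$mesh_id)
  if (is.na(i)) stop("unknown mesh id: ", mesh_id, call. = FALSE)
  row_to_population(as.numeric(meshes[i, pop_cols()]))
}

row_to_population <- function(v) {
  m <- rbind(female = v[1:18], male = v[19:36])
  colnames(m) <- .AGE_BANDS
  m
}

population_to_row <- function(p) c(p["female", ], p["male", ])

#' Replace the populations of a mesh table
#'
#' @param meshes a mesh table.
#' @param populations list of 2 x 18 matrices in mesh table order.
#' @return the updated mesh table.
#' @export
set_mesh_populations <- function(meshes, populations) {
  stopifnot(length(populations) == nrow(meshes))
  pm <- t(vapply(populations, population_to_row, numeric(36)))
  colnames(pm) <- pop_cols()
  meshes[, pop_cols()] <- pm
  meshes
}
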