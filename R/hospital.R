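# Hospitals: the unit of supply. Size classes follow the convention used in
# Japanese hospital statistics; capacity available for allocation is the bed
# count discounted by the utilization rate, and further capped for
# out-of-region facilities.

#' Classify hospitals by bed count
#'
#' Small scale is up to 100 beds, medium 101-399, large 400 or more beds
#' (400 itself counts as large).
#'
#' @param total_beds integer vector of bed counts, each >= 1.
#' @return ordered factor with levels `small < medium < large`.
#' @examples
#' classify_hospital_size(c(1, 100, 250, 400))
#' @export
classify_hospital_size <- function(total_beds) {
  if (length(total_beds) == 0 || anyNA(total_beds) ||
      any(total_beds < 1) || any(total_beds != round(total_beds)))
    stop("total_beds must be positive integers", call. = FALSE)
  cls <- ifelse(total_beds <= 100, "small",
                ifelse(total_beds < 400, "medium", "large"))
  factor(cls, levels = c("small", "medium", "large"), ordered = TRUE)
}

#' Beds available for allocation
#'
#' Not every licensed bed can take a simulated patient: capacity is the bed
#' count times the bed utilization rate, floored so it is never overstated.
#' Hospitals outside the study region accept patients in at most a fraction
#' `external_bed_fraction` of those available beds (20% by default).
#'
#' @param total_beds integer vector of bed counts.
#' @param utilization_rate fraction of beds usable, in (0, 1].
#' @param in_region logical vector; FALSE applies the external-bed cap.
#' @param external_bed_fraction cap fraction for out-of-region hospitals,
#'   in [0, 1].
#' @return integer vector of available beds.
#' @examples
#' available_beds(c(100, 60, 50), utilization_rate = 0.8)  # sums to 168
#' available_beds(100, 0.8, in_region = FALSE)             # 16
#' @export
available_beds <- function(total_beds, utilization_rate,
                           in_region = TRUE, external_bed_fraction = 0.2) {
  if (length(total_beds) == 0 || anyNA(total_beds) ||
      any(total_beds < 1) || any(total_beds != round(total_beds)))
    stop("total_beds must be positive integers", call. = FALSE)
  if (!is.numeric(utilization_rate) || length(utilization_rate) != 1 ||
      is.na(utilization_rate) ||
      utilization_rate <= 0 || utilization_rate > 1)
    stop("utilization_rate must be in (0, 1]", call. = FALSE)
  if (!is.numeric(external_bed_fraction) || length(external_bed_fraction) != 1 ||
      is.na(external_bed_fraction) ||
      external_bed_fraction < 0 || external_bed_fraction > 1)
    stop("external_bed_fraction must be in [0, 1]", call. = FALSE)
  frac <- ifelse(rep_len(in_region, length(total_beds)), 1, external_bed_fraction)
  as.integer(floor(total_beds * utilization_rate * frac))
}

#' Assemble a hospital table
#'
#' @param hospital_id unique character ids.
#' @param x,y location in meters (planar projected CRS).
#' @param total_beds integer bed counts, each >= 1.
#' @param in_region logical; FALSE marks facilities outside the study region,
#'   subject to the external-bed cap in [available_beds()].
#' @return `data.frame` with a derived `size_class` column.
#' @export
hospital_table <- function(hospital_id, x, y, total_beds, in_region = TRUE) {
  hospital_id <- as.character(hospital_id)
  if (anyDuplicated(hospital_id)) stop("duplicate hospital ids", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("hospital locations must be finite", call. = FALSE)
  data.frame(
    hospital_id = hospital_id, x = as.numeric(x), y = as.numeric(y),
    total_beds = as.integer(total_beds),
    in_region = rep_len(as.logical(in_region), length(hospital_id)),
    size_class = classify_hospital_size(total_beds),
    stringsAsFactors = FALSE
  )
}

validate_hospitals <- function(hospitals) {
  need <- c("hospital_id", "x", "y", "total_beds", "in_region")
  missing <- setdiff(need, names(hospitals))
  if (length(missing))
    stop("hospital table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(hospitals$hospital_id))
    stop("duplicate hospital ids", call. = FALSE)
  classify_hospital_size(hospitals$total_beds)  # validates bed counts
  if (anyNA(hospitals$in_region))
    stop("in_region must be TRUE/FALSE", call. = FALSE)
  invisible(hospitals)
}
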