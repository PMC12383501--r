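#' Read raw catch records from a delimited file
#'
#' Ingests CATDIS/T2CE-style tabular catch data. The `schema` argument maps
#' the canonical field names used throughout the package onto the column
#' names actually present in the file, so files from different extractions
#' can be read without renaming columns by hand.
#'
#' Rows failing validation (negative catch, impossible coordinates, year
#' outside the study window) are reported with their line numbers; the read
#' aborts rather than silently dropping data.
#'
#' @param path path to a delimited text file.
#' @param schema named character vector mapping canonical names
#'   (`year`, `species_code`, `gear`, `flag`, `lat`, `lon`, `catch_tonnes`,
#'   optionally `category_kind`) to file column names. Defaults to the
#'   identity mapping.
#' @param sep field separator (default `,`).
#' @param study_window integer length-2 vector of first and last admissible
#'   year, or NULL to accept all years.
#' @return a data.frame of catch records with canonical column names; the
#'   `category_kind` column is `"single-species"` or `"species-group"`.
#' @export
read_catch_records <- function(path, schema = NULL, sep = ",",
                               study_window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  canonical <- c("year", "species_code", "gear", "flag", "lat", "lon",
                 "catch_tonnes")
  if (is.null(schema)) schema <- stats::setNames(canonical, canonical)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(unname(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: mapped column(s) absent from file: ",
         paste(missing_cols, collapse = ", "))
  }
  need <- setdiff(canonical, names(schema))
  if (length(need) > 0) {
    stop("schema error: no mapping for required field(s): ",
         paste(need, collapse = ", "))
  }
  rec <- stats::setNames(raw[unname(schema)], names(schema))
  if (!"category_kind" %in% names(rec)) {
    rec$category_kind <- ifelse(grepl("spp|SPP|\\*", rec$species_code),
                                "species-group", "single-species")
  }
  rec$year <- as.integer(rec$year)
  rec$lat <- as.numeric(rec$lat)
  rec$lon <- as.numeric(rec$lon)
  rec$catch_tonnes <- as.numeric(rec$catch_tonnes)

  line_no <- seq_len(nrow(rec)) + 1L  # +1 for the header line
  bad <- character(0)
  flag_rows <- function(cond, what) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      bad <<- c(bad, sprintf("%s at line(s) %s", what,
                             paste(line_no[cond], collapse = ", ")))
    }
  }
  flag_rows(rec$catch_tonnes < 0, "negative catch")
  flag_rows(rec$lat < -90 | rec$lat > 90, "latitude outside [-90, 90]")
  flag_rows(rec$lon < -180 | rec$lon > 180, "longitude outside [-180, 180]")
  if (!is.null(study_window)) {
    flag_rows(rec$year < study_window[1] | rec$year > study_window[2],
              "year outside study window")
  }
  if (length(bad) > 0) {
    stop("validation error:\n  ", paste(bad, collapse = "\n  "))
  }
  rec
}

#' Assign a record to a study region
#'
#' The study area spans latitudes 0 to 60 S and is divided laterally at
#' 20 W into a western (SWAO) and an eastern (SEAO) sector. Conventions are
#' half-open: the equator itself falls outside the study area and the 20 W
#' meridian belongs to SEAO.
#'
#' @param lat latitude in degrees, negative south. Vectorised.
#' @param lon longitude in degrees, negative west. Vectorised.
#' @return character vector with values `"SWAO"`, `"SEAO"` or `"OUT"`.
#' @examples
#' assign_region(-30, -40) # "SWAO"
#' assign_region(-30, 10)  # "SEAO"
#' @export
assign_region <- function(lat, lon) {
  if (anyNA(lat) || anyNA(lon)) stop("coordinates must be non-missing")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]")
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]")
  in_band <- lat >= -60 & lat < 0
  ifelse(!in_band, "OUT", ifelse(lon < -20, "SWAO", "SEAO"))
}

#' Restrict records to retained single-species categories
#'
#' Group-level catch categories (e.g. genus-level lumping) cannot be given a
#' single thermal preference and are removed before any MTC computation,
#' keeping only the retained single-species codes. The fraction of total
#' biomass kept is reported; a warning is emitted when it drops below 95%,
#' the coverage the retained species are expected to attain.
#'
#' @param records data.frame from [read_catch_records()].
#' @param retained_species character vector of species codes to keep.
#' @param coverage_warn warn when retained biomass falls below this fraction
#'   of the total (default 0.95).
#' @return list with `records` (the filtered data.frame) and
#'   `coverage_fraction` (retained biomass / total biomass).
#' @export
filter_single_species <- function(records, retained_species,
                                  coverage_warn = 0.95) {
  if (nrow(records) == 0) stop("empty record list")
  if (length(retained_species) == 0) {
    stop("configuration error: empty retained species list")
  }
  kind <- records$category_kind
  if (is.null(kind)) kind <- rep("single-species", nrow(records))
  keep <- records$species_code %in% retained_species &
    kind == "single-species"
  total <- sum(records$catch_tonnes)
  coverage <- if (total > 0) sum(records$catch_tonnes[keep]) / total else 1
  if (coverage < coverage_warn) {
    warning(sprintf(
      "retained species cover only %.1f%% of reported biomass (< %.0f%%)",
      100 * coverage, 100 * coverage_warn
    ))
  }
  list(records = records[keep, , drop = FALSE], coverage_fraction = coverage)
}

#' Aggregate catch records into a year-by-species matrix
#'
#' Sums `catch_tonnes` over all records of a given year and species falling
#' in `region`; combinations never observed get 0. Species whose column is
#' entirely zero after aggregation are dropped (they carry no information
#' and would break row-wise relative-abundance transforms), with a message.
#'
#' @param records data.frame of validated catch records.
#' @param region `"SWAO"`, `"SEAO"`, or `"ALL"` to pool the whole study area.
#' @return a [catch_matrix()].
#' @export
aggregate_matrix <- function(records, region = c("SWAO", "SEAO", "ALL")) {
  region <- match.arg(region)
  reg <- assign_region(records$lat, records$lon)
  keep <- if (region == "ALL") reg != "OUT" else reg == region
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records fall in region ", region)
  years <- sort(unique(rec$year))
  species <- sort(unique(rec$species_code))
  m <- tapply(rec$catch_tonnes,
              list(factor(rec$year, levels = years),
                   factor(rec$species_code, levels = species)),
              sum, default = 0)
  empty <- colSums(m) == 0
  if (any(empty)) {
    message("dropping all-zero species column(s): ",
            paste(species[empty], collapse = ", "))
    m <- m[, !empty, drop = FALSE]
    species <- species[!empty]
  }
  catch_matrix(m, years = years, species = species)
}
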