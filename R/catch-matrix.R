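#' Year-by-species catch matrix
#'
#' Construct a validated years x species biomass matrix, the central data
#' container of the package. Rows are calendar years (strictly increasing),
#' columns are species codes (unique), and cells hold non-negative catch
#' biomass in metric tons.
#'
#' @param biomass numeric matrix (years x species) of non-negative tonnes.
#' @param years integer vector of calendar years, one per row.
#' @param species character vector of species codes, one per column.
#' @return a numeric matrix of class `catch_matrix` with year rownames and
#'   species colnames.
#' @examples
#' m <- catch_matrix(matrix(1:4, 2), years = 2000:2001, species = c("A", "B"))
#' @export
catch_matrix <- function(biomass, years = NULL, species = NULL) {
  biomass <- as.matrix(biomass)
  storage.mode(biomass) <- "double"
  if (is.null(years)) years <- as.integer(rownames(biomass))
  if (is.null(species)) species <- colnames(biomass)
  if (is.null(years) || anyNA(years)) {
    stop("`years` must be supplied or present as integer rownames")
  }
  if (is.null(species)) stop("`species` must be supplied or present as colnames")
  years <- as.integer(years)
  species <- as.character(species)
  if (length(years) != nrow(biomass)) stop("length(years) != nrow(biomass)")
  if (length(species) != ncol(biomass)) stop("length(species) != ncol(biomass)")
  if (anyDuplicated(species)) stop("species codes must be unique")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  if (anyNA(biomass) || any(biomass < 0)) {
    stop("biomass cells must be non-negative and non-missing")
  }
  dimnames(biomass) <- list(year = as.character(years), species = species)
  class(biomass) <- c("catch_matrix", class(biomass))
  biomass
}

#' @export
print.catch_matrix <- function(x, ...) {
  cat(sprintf(
    "catch_matrix: %d years (%s-%s) x %d species; total %.1f t\n",
    nrow(x), rownames(x)[1], rownames(x)[nrow(x)], ncol(x), sum(x)
  ))
  invisible(x)
}

#' @rdname catch_matrix
#' @param x object to test or coerce.
#' @export
is_catch_matrix <- function(x) inherits(x, "catch_matrix")

cm_years <- function(x) as.integer(rownames(x))

#' Read / write a catch matrix as CSV
#'
#' The on-disk layout is one row per year: first column `year`, remaining
#' columns one per species code.
#'
#' @param x a [catch_matrix()].
#' @param path file path.
#' @return `read_catch_matrix` returns a [catch_matrix()];
#'   `write_catch_matrix` returns `path` invisibly.
#' @export
write_catch_matrix <- function(x, path) {
  df <- data.frame(year = cm_years(x), unclass(x), check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catch_matrix
#' @export
read_catch_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"year" %in% names(df)) stop("catch matrix CSV must have a `year` column")
  catch_matrix(as.matrix(df[setdiff(names(df), "year")]),
               years = df$year,
               species = setdiff(names(df), "year"))
}
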