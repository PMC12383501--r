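#' Year-indexed numeric series
#'
#' A thin container for annual series (MTC, SST, Brazil Current transport,
#' warm-biomass fraction, anomalies): a numeric vector named by strictly
#' increasing calendar years, with an optional units attribute. Missing
#' years inside the span are permitted only as explicit `NA` values.
#'
#' @param years integer vector of calendar years.
#' @param values numeric vector, same length; `NA` marks a missing year.
#' @param units optional units string (e.g. `"degC"`, `"Sv"`).
#' @return numeric vector of class `annual_series`.
#' @export
annual_series <- function(years, values, units = NULL) {
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) stop("years and values differ in length")
  if (is.unsorted(years, strictly = TRUE)) stop("years must be strictly increasing")
  structure(stats::setNames(values, years),
            units = units, class = "annual_series")
}

#' @export
print.annual_series <- function(x, ...) {
  u <- attr(x, "units")
  cat(sprintf("annual_series [%s-%s]%s\n", names(x)[1], names(x)[length(x)],
              if (is.null(u)) "" else paste0(" (", u, ")")))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

series_years <- function(x) as.integer(names(x))

#' @export
`[.annual_series` <- function(x, i, ...) {
  out <- NextMethod()
  structure(out, units = attr(x, "units"), class = "annual_series")
}

#' Express a series as anomalies about its long-term mean
#'
#' Subtracts the mean of the non-missing values, so series measured in
#' different units (degrees, Sverdrups, proportions) become comparable
#' deviations. Idempotent: the anomaly of an anomaly is itself.
#'
#' @param series an [annual_series()] or named numeric vector.
#' @return an [annual_series()] with mean zero over non-missing values.
#' @export
to_anomaly <- function(series) {
  v <- as.numeric(series)
  if (sum(!is.na(v)) < 2) stop("need at least 2 non-missing values")
  annual_series(names(series), v - mean(v, na.rm = TRUE),
                units = attr(series, "units"))
}

#' Read / write an annual series as CSV
#'
#' Layout: columns `year`, `value`.
#'
#' @param x an [annual_series()].
#' @param path file path.
#' @export
write_annual_series <- function(x, path) {
  utils::write.csv(data.frame(year = series_years(x), value = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annual_series
#' @export
read_annual_series <- function(path) {
  df <- utils::read.csv(path)
  annual_series(df$year, df$value)
}
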