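#' Classify species into warm- and cold-water affinity groups
#'
#' The classification threshold is the arithmetic mean of the supplied
#' preferred temperatures, recomputed from whatever table is given rather
#' than fixed; with the 29-species South Atlantic pelagic table this mean is
#' 24.03 degrees C. A species is "warm" only when its preference is strictly
#' above the threshold; a preference exactly at the threshold counts as
#' "cold".
#'
#' @param preferences named numeric vector: species code -> preferred
#'   temperature in degrees C, or a data.frame with columns `species_code`
#'   and `t_pref_c`.
#' @return a `thermal_table`: data.frame with columns `species_code`,
#'   `t_pref_c`, `affinity` (`"warm"`/`"cold"`), and attribute `threshold`.
#' @examples
#' classify_affinity(c(A = 20, B = 28))
#' @export
classify_affinity <- function(preferences) {
  if (is.data.frame(preferences)) {
    preferences <- stats::setNames(preferences$t_pref_c,
                                   preferences$species_code)
  }
  if (length(preferences) < 2) stop("need at least 2 species")
  if (anyNA(preferences) || any(!is.finite(preferences))) {
    stop("all temperature preferences must be finite")
  }
  if (is.null(names(preferences)) || any(names(preferences) == "")) {
    stop("preferences must be named by species code")
  }
  threshold <- mean(preferences)
  tab <- data.frame(
    species_code = names(preferences),
    t_pref_c = as.numeric(preferences),
    affinity = ifelse(preferences > threshold, "warm", "cold"),
    stringsAsFactors = FALSE
  )
  structure(tab, threshold = threshold,
            class = c("thermal_table", "data.frame"))
}

#' @export
print.thermal_table <- function(x, ...) {
  cat(sprintf("thermal_table: %d species, threshold %.2f degC (%d warm / %d cold)\n",
              nrow(x), attr(x, "threshold"),
              sum(x$affinity == "warm"), sum(x$affinity == "cold")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read / write a thermal-preference table as CSV
#'
#' Layout: columns `species_code`, `t_pref_c`.
#'
#' @param x a `thermal_table` from [classify_affinity()].
#' @param path file path.
#' @export
write_thermal_table <- function(x, path) {
  utils::write.csv(x[c("species_code", "t_pref_c")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_thermal_table
#' @export
read_thermal_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  classify_affinity(stats::setNames(df$t_pref_c, df$species_code))
}

prefs_for_matrix <- function(matrix, table) {
  idx <- match(colnames(matrix), table$species_code)
  if (anyNA(idx)) {
    stop("species lacking a thermal preference: ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  }
  stats::setNames(table$t_pref_c[idx], colnames(matrix))
}

#' Mean Temperature of the Catch
#'
#' For each year y, the catch-weighted mean of species preferred
#' temperatures: MTC_y = sum_i T_i C_iy / sum_i C_iy, with T_i the preferred
#' temperature of species i and C_iy its catch biomass. The statistic rises
#' when warm-affinity species come to dominate the catch. Years with zero
#' total catch are returned as `NA` (flagged missing, never 0).
#'
#' @param matrix a [catch_matrix()].
#' @param table a `thermal_table` covering every species in `matrix`.
#' @return an [annual_series()] in degrees C, bounded by the range of the
#'   species preferences.
#' @examples
#' m <- catch_matrix(rbind(c(1, 3), c(2, 2)), 2000:2001, c("A", "B"))
#' compute_mtc(m, classify_affinity(c(A = 20, B = 30)))
#' @export
compute_mtc <- function(matrix, table) {
  t_pref <- prefs_for_matrix(matrix, table)
  totals <- rowSums(matrix)
  mtc <- as.numeric(matrix %*% t_pref) / totals
  mtc[totals == 0] <- NA_real_
  annual_series(cm_years(matrix), mtc, units = "degC")
}

#' Warm-affinity share of the catch
#'
#' Annual fraction of catch biomass contributed by warm-classified species,
#' together with a secondary species-count variant (fraction of species
#' present in the year's catch that are warm-classified) and the
#' whole-series warm:cold biomass ratio. Zero-catch years are `NA`.
#'
#' @inheritParams compute_mtc
#' @return list with `biomass_fraction` and `count_fraction`
#'   ([annual_series()] of proportions) and `overall_ratio`
#'   (warm biomass / cold biomass across all years; `Inf` if no cold catch).
#' @export
warm_fraction_series <- function(matrix, table) {
  t_pref <- prefs_for_matrix(matrix, table)  # validates coverage
  warm <- table$affinity[match(colnames(matrix), table$species_code)] == "warm"
  totals <- rowSums(matrix)
  warm_biomass <- rowSums(matrix[, warm, drop = FALSE])
  frac <- warm_biomass / totals
  frac[totals == 0] <- NA_real_
  present <- matrix > 0
  n_present <- rowSums(present)
  cnt <- rowSums(present[, warm, drop = FALSE]) / n_present
  cnt[n_present == 0] <- NA_real_
  years <- cm_years(matrix)
  list(
    biomass_fraction = annual_series(years, frac, units = "proportion"),
    count_fraction = annual_series(years, cnt, units = "proportion"),
    overall_ratio = sum(warm_biomass) / sum(totals - warm_biomass)
  )
}
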