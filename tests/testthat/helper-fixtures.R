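# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the tests themselves write.

# A tiny well-formed catch-record table (SWAO unless stated otherwise).
toy_records <- function() {
  data.frame(
    year = c(2000L, 2000L, 2001L),
    species_code = c("YFT", "ALB", "YFT"),
    gear = "LL", flag = "BRA",
    lat = -30, lon = -40,
    catch_tonnes = c(10, 5, 20),
    stringsAsFactors = FALSE
  )
}

write_records_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Random small non-negative matrix with year rownames / species colnames.
random_biomass <- function(n_years, n_species, seed) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_years * n_species, rate = 0.01),
              n_years, n_species,
              dimnames = list(seq(2000, length.out = n_years),
                              sprintf("SP%02d", seq_len(n_species))))
  m
}

# Piecewise-constant community: len[i] years of profile prof[[i]] (no noise).
regime_matrix <- function(lens, profiles, start_year = 1978) {
  rows <- do.call(rbind, mapply(function(l, p) {
    matrix(rep(p, each = l), nrow = l)
  }, lens, profiles, SIMPLIFY = FALSE))
  rownames(rows) <- seq(start_year, length.out = nrow(rows))
  colnames(rows) <- sprintf("SP%02d", seq_len(ncol(rows)))
  rows
}

# Exhaustive-search oracle: optimal contiguous partition of rows into
# `n_groups` blocks minimising total within-group SS. Returns the optimal
# year thresholds (midpoints). Independent of the tree code path.
brute_force_partition <- function(Y, years, n_groups) {
  n <- nrow(Y)
  ss_block <- function(i, j) {
    sub <- Y[i:j, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  cuts <- utils::combn(n - 1, n_groups - 1)
  best <- NULL
  for (c_i in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, c_i], n)
    ss <- sum(vapply(seq_len(n_groups), function(g) {
      ss_block(bounds[g] + 1, bounds[g + 1])
    }, numeric(1)))
    if (is.null(best) || ss < best$ss - 1e-12) {
      best <- list(ss = ss, cuts = cuts[, c_i])
    }
  }
  list(ss = best$ss,
       thresholds = (years[best$cuts] + years[best$cuts + 1]) / 2)
}

# Hand-rolled MTC oracle: explicit per-year loop over species.
mtc_by_hand <- function(m, prefs) {
  vapply(seq_len(nrow(m)), function(y) {
    num <- 0; den <- 0
    for (s in seq_len(ncol(m))) {
      num <- num + prefs[colnames(m)[s]] * m[y, s]
      den <- den + m[y, s]
    }
    num / den
  }, numeric(1))
}
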