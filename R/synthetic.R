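#' Scenario parameters for the synthetic catch generator
#'
#' Defaults describe a stylised South Atlantic pelagic fishery: a 41-year
#' series (1978-2018) of 29 species whose thermal preferences span roughly
#' 10-29 degrees C with 16 of 29 species on the warm side of the table mean,
#' annual totals near 300,000 t growing about 1.6% per year, biomass
#' dominated by a few taxa (geometric rank-abundance), log-normal
#' multiplicative catch noise, an SST series warming at 0.008 degC/yr, and a
#' Brazil Current transport series strengthening at 0.366 Sv/yr.
#'
#' Years are indexed centred at the series midpoint inside the generator, so
#' `total_catch_base`, `sst_base` and `bct_base` are midpoint values and
#' intercepts stay well conditioned.
#'
#' @param n_years number of years (>= 5).
#' @param start_year first calendar year.
#' @param n_species number of species (>= 3).
#' @param warm_fraction target fraction of species strictly above the
#'   thermal table's own mean.
#' @param thermal_range length-2 numeric, degC range of preferences.
#' @param baseline_share per-species expected biomass share at the series
#'   midpoint (recycled/normalised); default geometric with ratio 0.5, so a
#'   handful of taxa dominate.
#' @param share_trend per-species linear trend in log-biomass share per year
#'   (scalar recycled).
#' @param total_catch_base annual total catch (t) at the series midpoint.
#' @param total_catch_trend multiplicative trend of annual totals per year.
#' @param noise_sd standard deviation of log-normal catch noise.
#' @param sst_base,sst_slope,sst_noise_sd SST midpoint (degC), trend
#'   (degC/yr) and noise sd (degC).
#' @param bct_base,bct_slope,bct_noise_sd Brazil Current transport midpoint
#'   (Sv), trend (Sv/yr) and noise sd (Sv).
#' @param seed integer master seed; expanded into independent per-component
#'   substreams so adding one component does not shift the others.
#' @return a list of class `scenario_params`.
#' @export
scenario_params <- function(n_years = 41L, start_year = 1978L,
                            n_species = 29L, warm_fraction = 16 / 29,
                            thermal_range = c(10, 29),
                            baseline_share = NULL, share_trend = 0,
                            total_catch_base = 3e5,
                            total_catch_trend = 1.016,
                            noise_sd = 0.1,
                            sst_base = 23.7, sst_slope = 0.008,
                            sst_noise_sd = 0.1,
                            bct_base = -22, bct_slope = 0.366,
                            bct_noise_sd = 4,
                            seed = 1L) {
  if (n_years < 5) stop("n_years must be >= 5")
  if (n_species < 3) stop("n_species must be >= 3")
  if (noise_sd < 0 || sst_noise_sd < 0 || bct_noise_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  if (warm_fraction < 0 || warm_fraction > 1) {
    stop("warm_fraction must be in [0, 1]")
  }
  if (diff(thermal_range) <= 0) stop("thermal_range must be increasing")
  if (is.null(baseline_share)) baseline_share <- 0.5^(seq_len(n_species) - 1)
  baseline_share <- rep_len(baseline_share, n_species)
  if (any(baseline_share < 0)) stop("baseline shares must be >= 0")
  baseline_share <- baseline_share / sum(baseline_share)
  share_trend <- rep_len(share_trend, n_species)
  structure(list(
    n_years = as.integer(n_years), start_year = as.integer(start_year),
    n_species = as.integer(n_species), warm_fraction = warm_fraction,
    thermal_range = thermal_range, baseline_share = baseline_share,
    share_trend = share_trend, total_catch_base = total_catch_base,
    total_catch_trend = total_catch_trend, noise_sd = noise_sd,
    sst_base = sst_base, sst_slope = sst_slope, sst_noise_sd = sst_noise_sd,
    bct_base = bct_base, bct_slope = bct_slope, bct_noise_sd = bct_noise_sd,
    seed = as.integer(seed)
  ), class = "scenario_params")
}

# Deterministic per-component substream seed derived from the master seed,
# kept below 2^31. Component names hash independently so adding a component
# never shifts another component's stream.
substream_seed <- function(seed, component) {
  h <- 0
  for (k in utf8ToInt(component)) h <- (h * 131 + k) %% 1048573
  as.integer((as.numeric(seed) * 1048573 + h) %% .Machine$integer.max)
}

centered_years <- function(params) {
  y <- seq_len(params$n_years) - 1
  y - mean(y)
}

#' Generate a species thermal-preference table
#'
#' Preferences are drawn uniformly over `thermal_range`; draws are repeated
#' (deterministically, under the scenario substream) until the number of
#' species strictly above the table's own mean matches
#' `round(warm_fraction * n_species)`. With `symmetric = TRUE` preferences
#' are instead spaced evenly across the range (no randomness).
#'
#' @param params a [scenario_params()].
#' @param symmetric logical; evenly spaced deterministic preferences.
#' @param max_attempts rejection-sampling cap before a parameter error.
#' @return a `thermal_table` (see [classify_affinity()]).
#' @export
generate_thermal_table <- function(params, symmetric = FALSE,
                                   max_attempts = 5000L) {
  n <- params$n_species
  codes <- sprintf("SP%02d", seq_len(n))
  if (symmetric) {
    prefs <- seq(params$thermal_range[1], params$thermal_range[2],
                 length.out = n)
    return(classify_affinity(stats::setNames(prefs, codes)))
  }
  n_warm <- round(params$warm_fraction * n)
  if (n_warm >= n || (n_warm == 0 && params$warm_fraction > 0)) {
    stop("parameter error: warm_fraction ", params$warm_fraction,
         " infeasible for ", n, " species (strictly-above-mean rule)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(params$seed, "thermal"))
  for (i in seq_len(max_attempts)) {
    prefs <- stats::runif(n, params$thermal_range[1], params$thermal_range[2])
    if (sum(prefs > mean(prefs)) == n_warm) {
      return(classify_affinity(stats::setNames(prefs, codes)))
    }
  }
  stop("parameter error: could not realise warm_fraction ",
       params$warm_fraction, " in ", max_attempts, " attempts")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Noise-free expected biomass (t) for every year x species cell.
expected_biomass <- function(params) {
  yc <- centered_years(params)
  log_share <- outer(yc, params$share_trend) +
    rep(log(pmax(params$baseline_share, 1e-300)), each = params$n_years)
  shares <- exp(log_share)
  shares <- shares / rowSums(shares)
  totals <- params$total_catch_base * params$total_catch_trend^yc
  shares * totals
}

# Noise-free MTC path implied by the share model: the deterministic skeleton
# the planted-slope calibration and recovery tests reason about.
mtc_path_noiseless <- function(params, table) {
  mu <- expected_biomass(params)
  t_pref <- table$t_pref_c
  as.numeric(mu %*% t_pref / rowSums(mu))
}

#' Generate a synthetic year-by-species catch matrix
#'
#' Cell (y, s) = total_y * share_s(y) * exp(eps), eps ~ N(0, noise_sd^2)
#' i.i.d., where share_s(y) is proportional to
#' `baseline_share_s * exp(share_trend_s * yc)` (yc the centred year index)
#' and total_y follows the multiplicative total-catch trend. Log-normal
#' noise keeps every cell non-negative without truncation.
#'
#' @param params a [scenario_params()].
#' @param table a `thermal_table` with `n_species` rows (used for species
#'   codes; pass the table the scenario generated).
#' @return a [catch_matrix()].
#' @export
generate_catch_matrix <- function(params, table) {
  if (nrow(table) != params$n_species) {
    stop("thermal table size does not match n_species")
  }
  mu <- expected_biomass(params)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(params$seed, "catch"))
  eps <- matrix(stats::rnorm(length(mu), 0, params$noise_sd), nrow(mu))
  years <- params$start_year + seq_len(params$n_years) - 1L
  catch_matrix(mu * exp(eps), years = years, species = table$species_code)
}

#' Generate synthetic environmental series
#'
#' SST (degC, upper-ocean annual mean) and Brazil Current transport (Sv) as
#' linear trends about their midpoint values plus Gaussian noise.
#'
#' @param params a [scenario_params()].
#' @return list with [annual_series()] elements `sst` and `bct`.
#' @export
generate_env_series <- function(params) {
  yc <- centered_years(params)
  years <- params$start_year + seq_len(params$n_years) - 1L
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(substream_seed(params$seed, "sst"))
  sst <- params$sst_base + params$sst_slope * yc +
    stats::rnorm(params$n_years, 0, params$sst_noise_sd)
  set.seed(substream_seed(params$seed, "bct"))
  bct <- params$bct_base + params$bct_slope * yc +
    stats::rnorm(params$n_years, 0, params$bct_noise_sd)
  list(sst = annual_series(years, sst, units = "degC"),
       bct = annual_series(years, bct, units = "Sv"))
}

#' Null scenario: no trends anywhere
#'
#' All share, total-catch and environmental trends are zeroed, giving an
#' exchangeable-by-year world for type-I-error and permutation-uniformity
#' checks.
#'
#' @param params a [scenario_params()]; trend fields are overridden.
#' @return list with `params`, `table`, `catch`, `sst`, `bct`.
#' @export
null_scenario <- function(params = scenario_params()) {
  params$share_trend <- rep(0, params$n_species)
  params$total_catch_trend <- 1
  params$sst_slope <- 0
  params$bct_slope <- 0
  table <- generate_thermal_table(params)
  list(params = params,
       table = table,
       catch = generate_catch_matrix(params, table),
       sst = generate_env_series(params)$sst,
       bct = generate_env_series(params)$bct)
}

#' Tropicalization scenario with a planted MTC slope
#'
#' Plants a linear shift of biomass share from cold- to warm-affinity
#' species: warm species get log-share trend `+g`, cold species `-g`, with
#' `g` calibrated (on the noise-free skeleton, by root finding) so the OLS
#' slope of the noise-free MTC path equals `planted_mtc_slope`.
#'
#' @param params a [scenario_params()].
#' @param planted_mtc_slope target MTC trend in degC/yr (default 0.012, the
#'   magnitude observed in the western South Atlantic).
#' @return list with `params` (calibrated), `table`, `catch`, `sst`, `bct`,
#'   and `planted` (the planted slope and calibrated g).
#' @export
tropicalization_scenario <- function(params = scenario_params(),
                                     planted_mtc_slope = 0.012) {
  table <- generate_thermal_table(params)
  direction <- ifelse(table$affinity == "warm", 1, -1)
  yc <- centered_years(params)
  slope_for <- function(g) {
    p <- params
    p$share_trend <- g * direction
    path <- mtc_path_noiseless(p, table)
    stats::cov(yc, path) / stats::var(yc)
  }
  g <- stats::uniroot(function(g) slope_for(g) - planted_mtc_slope,
                      c(0, 1), tol = 1e-12)$root
  params$share_trend <- g * direction
  list(params = params,
       table = table,
       catch = generate_catch_matrix(params, table),
       sst = generate_env_series(params)$sst,
       bct = generate_env_series(params)$bct,
       planted = list(mtc_slope = planted_mtc_slope, g = g))
}
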