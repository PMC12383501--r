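#' Linear trend of an annual series
#'
#' Ordinary least squares of value on calendar year, the baseline trend
#' model for MTC, SST and transport series. Inference on the slope uses the
#' usual two-sided t test; no autocorrelation correction is applied.
#'
#' @param series an [annual_series()] or year-named numeric vector.
#' @return list of class `trend_fit`: `slope` (units/yr), `intercept`,
#'   `slope_se`, `p_value`, `r2`, `adj_r2`, `aic`, `bic`, `residuals`,
#'   `fitted`, `n`, `years`, and the underlying `model`. For a constant
#'   series `r2` is reported as 0 and `p_value` as 1.
#' @export
fit_linear_trend <- function(series) {
  yr <- as.numeric(names(series))
  v <- as.numeric(series)
  ok <- !is.na(v)
  if (sum(ok) < 3) stop("need at least 3 non-missing points")
  yr <- yr[ok]; v <- v[ok]
  if (stats::var(yr) == 0) stop("zero variance in year")
  fit <- stats::lm(v ~ yr)
  sm <- summary(fit)
  tss <- sum((v - mean(v))^2)
  if (tss == 0) {
    r2 <- 0; adj <- 0; p <- 1; se <- 0
  } else {
    r2 <- sm$r.squared
    adj <- sm$adj.r.squared
    se <- sm$coefficients["yr", "Std. Error"]
    p <- sm$coefficients["yr", "Pr(>|t|)"]
  }
  structure(list(
    slope = unname(stats::coef(fit)["yr"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    slope_se = se, p_value = p, r2 = r2, adj_r2 = adj,
    aic = stats::AIC(fit), bic = stats::BIC(fit),
    residuals = unname(stats::residuals(fit)),
    fitted = unname(stats::fitted(fit)),
    n = length(v), years = yr, model = fit
  ), class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "trend_fit: slope %.5g /yr (SE %.3g, p = %.3g), r2 = %.3f, adj r2 = %.3f, AIC = %.2f, n = %d\n",
    x$slope, x$slope_se, x$p_value, x$r2, x$adj_r2, x$aic, x$n
  ))
  invisible(x)
}

# Cubic regression spline basis + curvature penalty on the observed years.
cr_basis <- function(yr, k) {
  sm <- mgcv::smoothCon(mgcv::s(year, k = k, bs = "cr"),
                        data = data.frame(year = yr),
                        absorb.cons = FALSE)[[1]]
  list(X = sm$X, S = sm$S[[1]], sm = sm)
}

penalized_fit <- function(X, S, y, lambda) {
  A <- crossprod(X) + lambda * S
  R <- chol(A)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  fitted <- as.numeric(X %*% beta)
  # edf = tr(X (X'X + lambda S)^-1 X')
  XAinv <- t(backsolve(R, forwardsolve(t(R), t(X))))
  edf <- sum(XAinv * X)
  list(beta = beta, fitted = fitted, edf = edf,
       rss = sum((y - fitted)^2))
}

gaussian_ic <- function(rss, n, edf) {
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  c(aic = -2 * ll + 2 * (edf + 1), bic = -2 * ll + log(n) * (edf + 1))
}

#' Penalized cubic-spline trend
#'
#' Fits a cubic regression spline of dimension `k` (default 5 basis
#' functions, knots at year quantiles) with a second-derivative curvature
#' penalty. The smoothing parameter lambda is chosen by generalized
#' cross-validation (GCV) over a log grid refined by golden-section search;
#' a fixed `lambda` can be supplied instead. The penalty null space is the
#' set of straight lines, so lambda -> Inf recovers the OLS line and
#' lambda = 0 the unpenalized regression on the basis.
#'
#' @param series an [annual_series()] or year-named numeric vector.
#' @param k basis dimension (default 5).
#' @param lambda optional fixed smoothing parameter (>= 0); `NULL` selects
#'   by GCV.
#' @param lambda_grid log10-lambda grid searched before refinement.
#' @return list of class `spline_fit`: `k`, `lambda`, `edf` (effective
#'   degrees of freedom, trace of the smoother matrix), `fitted`, `gcv`,
#'   `aic`, `bic`, `r2`, `adj_r2`, `residuals`, `years`, `n`.
#' @export
fit_spline_trend <- function(series, k = 5, lambda = NULL,
                             lambda_grid = seq(-8, 10, by = 0.25)) {
  yr <- as.numeric(names(series))
  v <- as.numeric(series)
  ok <- !is.na(v)
  yr <- yr[ok]; v <- v[ok]
  n <- length(v)
  if (n < k + 2) stop("need at least k + 2 = ", k + 2, " points")
  bas <- cr_basis(yr, k)
  gcv_of <- function(lam) {
    f <- penalized_fit(bas$X, bas$S, v, lam)
    n * f$rss / (n - f$edf)^2
  }
  if (is.null(lambda)) {
    scores <- vapply(10^lambda_grid, gcv_of, numeric(1))
    i <- which.min(scores)
    lo <- lambda_grid[max(1, i - 1)]
    hi <- lambda_grid[min(length(lambda_grid), i + 1)]
    lambda <- 10^stats::optimize(function(r) gcv_of(10^r),
                                 c(lo, hi), tol = 1e-8)$minimum
    if (gcv_of(10^lambda_grid[i]) < gcv_of(lambda)) {
      lambda <- 10^lambda_grid[i]
    }
  }
  if (lambda < 0) stop("lambda must be >= 0")
  f <- penalized_fit(bas$X, bas$S, v, lambda)
  ic <- gaussian_ic(f$rss, n, f$edf)
  tss <- sum((v - mean(v))^2)
  r2 <- if (tss == 0) 0 else 1 - f$rss / tss
  adj <- if (tss == 0) 0 else 1 - (f$rss / (n - f$edf)) / (tss / (n - 1))
  structure(list(
    k = k, lambda = lambda, edf = f$edf, fitted = f$fitted,
    gcv = n * f$rss / (n - f$edf)^2,
    aic = unname(ic["aic"]), bic = unname(ic["bic"]),
    r2 = r2, adj_r2 = adj,
    residuals = v - f$fitted, years = yr, n = n, basis = bas
  ), class = "spline_fit")
}

#' @export
print.spline_fit <- function(x, ...) {
  cat(sprintf(
    "spline_fit: k = %d, lambda = %.4g, edf = %.2f, GCV = %.4g, AIC = %.2f\n",
    x$k, x$lambda, x$edf, x$gcv, x$aic
  ))
  invisible(x)
}

#' Compare linear and spline trend structures
#'
#' Reports adjusted R-squared, AIC and BIC deltas plus simple residual
#' diagnostics for both fits. The linear structure is retained unless the
#' spline wins on all three criteria simultaneously; when criteria
#' disagree, parsimony and cross-study comparability favour the line.
#'
#' @param lin a `trend_fit`.
#' @param spl a `spline_fit` on the same data.
#' @return list of class `model_choice`: `selected` (`"linear"` or
#'   `"spline"`), `delta` (spline minus linear for adj_r2, AIC, BIC),
#'   `criteria` (logical, per-criterion spline wins), `diagnostics`.
#' @export
choose_trend_model <- function(lin, spl) {
  y_lin <- lin$fitted + lin$residuals
  y_spl <- spl$fitted + spl$residuals
  if (lin$n != spl$n || !isTRUE(all.equal(lin$years, spl$years)) ||
      !isTRUE(all.equal(y_lin, y_spl, tolerance = 1e-8))) {
    stop("fits are not on the same data")
  }
  wins <- c(adj_r2 = spl$adj_r2 > lin$adj_r2,
            aic = spl$aic < lin$aic,
            bic = spl$bic < lin$bic)
  shapiro_p <- function(r) {
    if (length(r) >= 3 && stats::sd(r) > 0) stats::shapiro.test(r)$p.value else NA_real_
  }
  structure(list(
    selected = if (all(wins)) "spline" else "linear",
    delta = c(adj_r2 = spl$adj_r2 - lin$adj_r2,
              aic = spl$aic - lin$aic,
              bic = spl$bic - lin$bic),
    criteria = wins,
    diagnostics = list(
      linear_resid_normality_p = shapiro_p(lin$residuals),
      spline_resid_normality_p = shapiro_p(spl$residuals)
    )
  ), class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat("model choice:", x$selected, "\n")
  cat(sprintf("  delta adj r2 = %+.4f, delta AIC = %+.2f, delta BIC = %+.2f\n",
              x$delta["adj_r2"], x$delta["aic"], x$delta["bic"]))
  invisible(x)
}

#' ANCOVA comparison of two trend slopes
#'
#' Pools two annual series into value ~ year * group and tests slope
#' equality through the interaction term, the standard comparison of
#' regional trends.
#'
#' @param series_a,series_b [annual_series()] objects (e.g. the two regional
#'   MTC series).
#' @param labels length-2 character group labels.
#' @return list of class `ancova_result`: `slope_difference` (b minus a),
#'   `interaction_p`, `slopes`, and the pooled `model`.
#' @export
compare_slopes_ancova <- function(series_a, series_b,
                                  labels = c("A", "B")) {
  mk <- function(s, g) {
    v <- as.numeric(s)
    data.frame(year = as.numeric(names(s)), value = v, group = g)[!is.na(v), ]
  }
  df <- rbind(mk(series_a, labels[1]), mk(series_b, labels[2]))
  df$group <- factor(df$group, levels = labels)
  if (any(table(df$group) < 3)) stop("each group needs at least 3 points")
  fit <- stats::lm(value ~ year * group, data = df)
  cf <- summary(fit)$coefficients
  int_row <- grep(":", rownames(cf))
  slope_a <- unname(stats::coef(fit)["year"])
  slope_diff <- unname(stats::coef(fit)[int_row])
  structure(list(
    slope_difference = slope_diff,
    interaction_p = unname(cf[int_row, "Pr(>|t|)"]),
    slopes = stats::setNames(c(slope_a, slope_a + slope_diff), labels),
    model = fit
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA: slopes %s = %.5g, %s = %.5g; difference %.5g (interaction p = %.4g)\n",
              names(x$slopes)[1], x$slopes[1], names(x$slopes)[2], x$slopes[2],
              x$slope_difference, x$interaction_p))
  invisible(x)
}

#' Leave-one-species-out sensitivity of the MTC trend
#'
#' Recomputes the MTC series with each species excluded in turn, refits the
#' linear trend, and reports the slope, its p-value, and the signed percent
#' change relative to the full-assemblage slope,
#' 100 * (slope_without - slope_full) / |slope_full|, so that sign flips
#' exceed -100%. Rows whose |change| exceeds `flag_threshold` percent are
#' flagged. A species whose removal leaves some year with zero catch is
#' reported as unavailable (NA row).
#'
#' @param matrix a [catch_matrix()].
#' @param table a `thermal_table`.
#' @param flag_threshold percent change above which a row is flagged
#'   (default 5, the conventional reporting cut).
#' @return data.frame of class `sensitivity_table` with columns
#'   `species_code`, `affinity`, `slope_without`, `p_without`,
#'   `slope_change_pct`, `flagged`, `available`; the full-model `trend_fit`
#'   is attached as attribute `full_fit`.
#' @export
sensitivity_loo <- function(matrix, table, flag_threshold = 5) {
  if (ncol(matrix) < 3) stop("need at least 3 species")
  full <- fit_linear_trend(compute_mtc(matrix, table))
  aff <- table$affinity[match(colnames(matrix), table$species_code)]
  rows <- lapply(seq_len(ncol(matrix)), function(j) {
    sub <- matrix[, -j, drop = FALSE]
    if (any(rowSums(sub) == 0)) {
      return(data.frame(species_code = colnames(matrix)[j], affinity = aff[j],
                        slope_without = NA_real_, p_without = NA_real_,
                        slope_change_pct = NA_real_, flagged = NA,
                        available = FALSE))
    }
    cm <- catch_matrix(sub, years = cm_years(matrix),
                       species = colnames(sub))
    fit <- fit_linear_trend(compute_mtc(cm, table))
    chg <- if (full$slope == 0) NA_real_ else
      100 * (fit$slope - full$slope) / abs(full$slope)
    data.frame(species_code = colnames(matrix)[j], affinity = aff[j],
               slope_without = fit$slope, p_without = fit$p_value,
               slope_change_pct = chg,
               flagged = !is.na(chg) && abs(chg) > flag_threshold,
               available = TRUE)
  })
  out <- do.call(rbind, rows)
  structure(out, full_fit = full,
            class = c("sensitivity_table", "data.frame"))
}

#' Time-lagged linear driver models
#'
#' Regresses the response on the driver lagged by 0..`max_lag` years
#' (response year y paired with driver year y - lag) and reports each fit
#' plus three separate selection criteria: minimum AIC, maximum R-squared,
#' and slope significance at `alpha`. By default each lag uses its own
#' maximal year overlap; `common_sample = TRUE` restricts every lag to the
#' years usable at all lags so AIC values compare models on identical data.
#'
#' @param response,driver [annual_series()] objects (may cover different
#'   year spans; alignment is by calendar year).
#' @param max_lag largest lag in years (default 4).
#' @param common_sample logical; force one common aligned sample.
#' @param alpha significance level for the slope criterion (default 0.05).
#' @param driver_name label recorded in the output.
#' @return list of class `lag_fits`: `fits` (data.frame with columns
#'   `driver`, `lag`, `n`, `slope`, `slope_se`, `p_value`, `r2`, `aic`),
#'   `selection` (list `min_aic`, `max_r2`, `significant`), `common_sample`.
#' @export
fit_lagged <- function(response, driver, max_lag = 4,
                       common_sample = FALSE, alpha = 0.05,
                       driver_name = deparse(substitute(driver))) {
  ry <- series_years(response); dy <- series_years(driver)
  rv <- as.numeric(response); dv <- as.numeric(driver)
  usable_years <- function(lag) {
    y <- intersect(ry[!is.na(rv)], dy[!is.na(dv)] + lag)
    sort(y)
  }
  lags <- 0:max_lag
  if (common_sample) {
    common <- Reduce(intersect, lapply(lags, usable_years))
  }
  rows <- list(); kept <- integer(0)
  for (lag in lags) {
    yrs <- if (common_sample) common else usable_years(lag)
    if (length(yrs) < 3) {
      message("lag ", lag, " skipped: only ", length(yrs), " aligned years")
      next
    }
    y <- rv[match(yrs, ry)]
    x <- dv[match(yrs - lag, dy)]
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    rows[[length(rows) + 1]] <- data.frame(
      driver = driver_name, lag = lag, n = length(yrs),
      slope = unname(stats::coef(fit)["x"]),
      slope_se = sm$coefficients["x", "Std. Error"],
      p_value = sm$coefficients["x", "Pr(>|t|)"],
      r2 = sm$r.squared, aic = stats::AIC(fit)
    )
    kept <- c(kept, lag)
  }
  if (length(rows) == 0) stop("insufficient overlap at every lag")
  fits <- do.call(rbind, rows)
  structure(list(
    fits = fits,
    selection = list(
      min_aic = fits$lag[which.min(fits$aic)],
      max_r2 = fits$lag[which.max(fits$r2)],
      significant = fits$lag[fits$p_value < alpha]
    ),
    common_sample = common_sample
  ), class = "lag_fits")
}

#' @export
print.lag_fits <- function(x, ...) {
  print(x$fits, row.names = FALSE)
  cat(sprintf("selection: min AIC at lag %d; max r2 at lag %d; significant: %s\n",
              x$selection$min_aic, x$selection$max_r2,
              if (length(x$selection$significant) == 0) "none"
              else paste(x$selection$significant, collapse = ", ")))
  invisible(x)
}
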