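test_that("fit_linear_trend handles exact, constant and degenerate input", {
  yrs <- 2000:2009
  exact <- fit_linear_trend(annual_series(yrs, 2 * yrs + 1))
  expect_equal(exact$slope, 2, tolerance = 1e-12)
  expect_equal(exact$r2, 1, tolerance = 1e-12)

  flat <- fit_linear_trend(annual_series(yrs, rep(3, 10)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0)
  expect_equal(flat$p_value, 1)

  expect_error(fit_linear_trend(annual_series(2000:2001, c(1, 2))),
               "at least 3")
})

test_that("fit_linear_trend matches the closed-form OLS slope", {
  set.seed(8)
  yrs <- 2001:2010
  v <- 0.3 * yrs + rnorm(10)
  fit <- fit_linear_trend(annual_series(yrs, v))
  slope_hand <- sum((yrs - mean(yrs)) * (v - mean(v))) / sum((yrs - mean(yrs))^2)
  expect_equal(fit$slope, slope_hand, tolerance = 1e-10)
  expect_equal(fit$intercept, mean(v) - slope_hand * mean(yrs),
               tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-9)
  expect_lte(fit$adj_r2, fit$r2)
})

test_that("OLS slope is invariant to additive shifts (anomalies)", {
  set.seed(21)
  yrs <- 1990:2010
  v <- rnorm(21)
  s <- annual_series(yrs, v)
  f1 <- fit_linear_trend(s)
  f2 <- fit_linear_trend(to_anomaly(s))
  expect_equal(f1$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-9)
})

test_that("spline limits: infinite penalty gives the OLS line, zero gives the basis fit", {
  set.seed(3)
  yrs <- 1978:2018
  v <- 0.01 * (yrs - 1998) + rnorm(41, sd = 0.1)
  s <- annual_series(yrs, v)
  lin <- fit_linear_trend(s)
  heavy <- fit_spline_trend(s, k = 5, lambda = 1e9)
  expect_lt(max(abs(heavy$fitted - lin$fitted)), 1e-6)
  expect_equal(heavy$edf, 2, tolerance = 1e-5)

  free <- fit_spline_trend(s, k = 5, lambda = 0)
  X <- free$basis$X
  ols_basis <- stats::lm.fit(X, v)$fitted.values
  expect_equal(free$fitted, as.numeric(ols_basis), tolerance = 1e-8)
  expect_equal(free$edf, 5, tolerance = 1e-8)

  # straight-line data are reproduced for any lambda (penalty null space)
  line <- annual_series(yrs, 2 + 0.05 * yrs)
  for (lam in c(0, 1, 1e6)) {
    f <- fit_spline_trend(line, lambda = lam)
    expect_lt(max(abs(f$fitted - as.numeric(line))), 1e-6)
  }

  expect_error(fit_spline_trend(annual_series(2000:2004, rnorm(5)), k = 5),
               "at least")
})

test_that("GCV-selected lambda matches a dense grid search", {
  set.seed(14)
  yrs <- 1978:2018
  v <- sin((yrs - 1978) / 4) + 0.02 * (yrs - 1998) + rnorm(41, sd = 0.2)
  s <- annual_series(yrs, v)
  fit <- fit_spline_trend(s, k = 5)
  grid <- 10^seq(-8, 10, by = 0.02)
  gcv_grid <- vapply(grid, function(l) fit_spline_trend(s, k = 5, lambda = l)$gcv,
                     numeric(1))
  expect_lte(fit$gcv, min(gcv_grid) + 1e-10)
  expect_true(fit$edf >= 2 && fit$edf <= 5)
})

test_that("choose_trend_model retains the line unless the spline wins everywhere", {
  set.seed(5)
  yrs <- 1978:2018
  lin_truth <- annual_series(yrs, 0.01 * yrs + rnorm(41, sd = 0.05))
  lin <- fit_linear_trend(lin_truth)
  spl <- fit_spline_trend(lin_truth)
  expect_equal(choose_trend_model(lin, spl)$selected, "linear")

  # strong step change: the spline wins on every criterion
  step <- annual_series(yrs, ifelse(yrs < 1998, 0, 5) + rnorm(41, sd = 0.1))
  lin2 <- fit_linear_trend(step)
  spl2 <- fit_spline_trend(step)
  ch2 <- choose_trend_model(lin2, spl2)
  expect_true(all(ch2$criteria))
  expect_equal(ch2$selected, "spline")

  # disagreement keeps the line even if the spline wins AIC
  fake_spl <- spl
  fake_spl$aic <- lin$aic - 1
  fake_spl$bic <- lin$bic + 1
  fake_spl$adj_r2 <- lin$adj_r2 + 0.01
  expect_equal(choose_trend_model(lin, fake_spl)$selected, "linear")

  expect_error(choose_trend_model(lin, fit_spline_trend(step)), "same data")
})

test_that("ANCOVA detects equal and unequal slopes", {
  set.seed(9)
  yrs <- 2000:2015
  v <- 0.5 * yrs + rnorm(16)
  same <- compare_slopes_ancova(annual_series(yrs, v), annual_series(yrs, v))
  expect_equal(same$slope_difference, 0, tolerance = 1e-10)
  expect_equal(same$interaction_p, 1, tolerance = 1e-8)

  a <- annual_series(yrs, 1 * yrs + rnorm(16, sd = 1e-6))
  b <- annual_series(yrs, 2 * yrs + rnorm(16, sd = 1e-6))
  diff <- compare_slopes_ancova(a, b, labels = c("SWAO", "SEAO"))
  expect_equal(diff$slope_difference, 1, tolerance = 1e-5)
  expect_lt(diff$interaction_p, 1e-10)
  expect_equal(unname(diff$slopes), c(1, 2), tolerance = 1e-5)

  expect_error(compare_slopes_ancova(annual_series(2000:2001, 1:2), a),
               "at least 3")
})

test_that("leave-one-species-out reproduces a from-scratch recomputation", {
  # cold species SP01 declines and drives the upward MTC trend; its removal
  # flips the fitted slope sign
  yrs <- 2000:2011
  m <- catch_matrix(cbind(SP01 = seq(100, 1, length.out = 12),
                          SP02 = rep(50, 12),
                          SP03 = c(rep(50, 6), rep(49, 6))),
                    yrs, c("SP01", "SP02", "SP03"))
  tb <- classify_affinity(c(SP01 = 12, SP02 = 26, SP03 = 28))
  sens <- sensitivity_loo(m, tb)
  full <- attr(sens, "full_fit")
  expect_gt(full$slope, 0)

  # direct oracle: recompute without SP01 from raw pieces
  sub <- m[, c("SP02", "SP03")]
  mtc_wo <- (26 * sub[, 1] + 28 * sub[, 2]) / rowSums(sub)
  oracle <- fit_linear_trend(annual_series(yrs, mtc_wo))
  row1 <- sens[sens$species_code == "SP01", ]
  expect_equal(row1$slope_without, oracle$slope, tolerance = 1e-12)
  expect_lt(row1$slope_without, 0)  # sign flip
  expect_lt(row1$slope_change_pct, -100)
  expect_true(row1$flagged)
})

test_that("removing an absent (all-zero) species changes the slope by 0%", {
  yrs <- 2000:2009
  set.seed(2)
  m <- catch_matrix(cbind(A = runif(10, 1, 2), B = runif(10, 1, 2), Z = 0),
                    yrs, c("A", "B", "Z"))
  tb <- classify_affinity(c(A = 20, B = 28, Z = 25))
  sens <- sensitivity_loo(m, tb)
  zrow <- sens[sens$species_code == "Z", ]
  expect_equal(zrow$slope_change_pct, 0, tolerance = 1e-9)
  expect_equal(zrow$slope_without, attr(sens, "full_fit")$slope,
               tolerance = 1e-12)
})

test_that("sensitivity flags unavailable rows and validates input", {
  yrs <- 2000:2004
  m <- catch_matrix(cbind(A = c(1, 1, 1, 1, 1), B = c(0, 1, 1, 1, 1),
                          C = c(0, 1, 1, 1, 1)),
                    yrs, c("A", "B", "C"))
  tb <- classify_affinity(c(A = 20, B = 28, C = 25))
  sens <- sensitivity_loo(m, tb)
  expect_false(sens$available[sens$species_code == "A"])  # year 2000 empties
  expect_true(all(sens$available[sens$species_code != "A"]))
  expect_error(sensitivity_loo(m[, 1:2], tb), "at least 3")
})

test_that("lagged models recover a pure lag-2 relationship", {
  set.seed(4)
  yrs <- 1978:2018
  x <- cumsum(rnorm(41))
  driver <- annual_series(yrs, x)
  resp_years <- yrs[yrs - 2 >= min(yrs)]
  response <- annual_series(resp_years, 3 + 2 * x[match(resp_years - 2, yrs)])
  lf <- fit_lagged(response, driver, max_lag = 4, driver_name = "SST")
  expect_equal(lf$selection$min_aic, 2)
  expect_equal(lf$selection$max_r2, 2)
  expect_true(2 %in% lf$selection$significant)
  lag2 <- lf$fits[lf$fits$lag == 2, ]
  expect_equal(lag2$r2, 1, tolerance = 1e-9)
  expect_equal(lag2$slope, 2, tolerance = 1e-6)
  # each lag uses its own maximal aligned overlap
  expect_equal(lf$fits$n, c(39, 39, 39, 38, 37))
})

test_that("lagged models respect anomalies, common samples and short overlap", {
  set.seed(6)
  yrs <- 2000:2020
  resp <- annual_series(yrs, rnorm(21))
  drv <- annual_series(yrs, rnorm(21))
  raw <- fit_lagged(resp, drv, max_lag = 2)
  anom <- fit_lagged(to_anomaly(resp), to_anomaly(drv), max_lag = 2)
  expect_equal(raw$fits$slope, anom$fits$slope, tolerance = 1e-10)

  common <- fit_lagged(resp, drv, max_lag = 4, common_sample = TRUE)
  expect_true(all(common$fits$n == 21 - 4))

  short <- annual_series(2000:2003, rnorm(4))
  expect_message(fit_lagged(short, drv, max_lag = 4), "skipped")
  expect_error(suppressMessages(
    fit_lagged(annual_series(2000:2002, rnorm(3)),
               annual_series(2010:2012, rnorm(3)))), "insufficient overlap")
})
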