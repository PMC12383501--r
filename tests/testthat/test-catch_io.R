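test_that("read_catch_records ingests well-formed files and applies the schema", {
  path <- write_records_csv(toy_records())
  rec <- read_catch_records(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$catch_tonnes, c(10, 5, 20))
  expect_true(all(rec$category_kind == "single-species"))

  # schema mapping onto renamed columns
  df <- toy_records()
  names(df)[names(df) == "catch_tonnes"] <- "qty_t"
  path2 <- write_records_csv(df)
  schema <- c(year = "year", species_code = "species_code", gear = "gear",
              flag = "flag", lat = "lat", lon = "lon", catch_tonnes = "qty_t")
  expect_equal(read_catch_records(path2, schema)$catch_tonnes, c(10, 5, 20))

  # group categories pass through untouched; filtering happens later
  df2 <- toy_records()
  df2$species_code[2] <- "Thunnus spp"
  rec2 <- read_catch_records(write_records_csv(df2))
  expect_equal(rec2$category_kind[2], "species-group")
  expect_equal(nrow(rec2), 3)
})

test_that("read_catch_records rejects bad rows with line numbers and bad schemas", {
  df <- toy_records()
  df$catch_tonnes[2] <- -1
  expect_error(read_catch_records(write_records_csv(df)),
               "negative catch at line\\(s\\) 3")

  df <- toy_records()
  df$lat[1] <- 95
  expect_error(read_catch_records(write_records_csv(df)), "latitude")

  expect_error(
    read_catch_records(write_records_csv(toy_records()),
                       schema = c(year = "nope")),
    "schema error"
  )

  df <- toy_records()
  expect_error(
    read_catch_records(write_records_csv(df), study_window = c(2001, 2018)),
    "study window"
  )
})

test_that("assign_region implements the half-open study-area conventions", {
  expect_equal(assign_region(-30, -40), "SWAO")
  expect_equal(assign_region(-30, 10), "SEAO")
  expect_equal(assign_region(10, -40), "OUT")
  # boundaries: 20 W belongs to SEAO, the equator is outside, 60 S inside
  expect_equal(assign_region(-30, -20), "SEAO")
  expect_equal(assign_region(0, -40), "OUT")
  expect_equal(assign_region(-60, -40), "SWAO")
  expect_error(assign_region(NA, 0), "non-missing")
  expect_error(assign_region(0, 200), "longitude")
})

test_that("assign_region partitions the study band", {
  set.seed(11)
  lat <- runif(500, -60, -1e-9)
  lon <- runif(500, -180, 180)
  reg <- assign_region(lat, lon)
  expect_true(all(reg %in% c("SWAO", "SEAO")))
  expect_equal(reg == "SWAO", lon < -20)
})

test_that("filter_single_species computes coverage and warns below 95%", {
  df <- toy_records()
  out <- filter_single_species(df, c("YFT", "ALB"))
  expect_equal(out$coverage_fraction, 1)
  expect_equal(nrow(out$records), 3)

  df2 <- data.frame(year = 2000L, species_code = c("YFT", "Thunnus spp"),
                    gear = "LL", flag = "B", lat = -30, lon = -40,
                    catch_tonnes = c(95, 5),
                    category_kind = c("single-species", "species-group"))
  out2 <- expect_silent(filter_single_species(df2, "YFT"))
  expect_equal(out2$coverage_fraction, 0.95)
  expect_equal(nrow(out2$records), 1)

  df2$catch_tonnes <- c(90, 10)
  expect_warning(filter_single_species(df2, "YFT"), "90.0%")
  expect_error(filter_single_species(df2, character(0)), "configuration")
})

test_that("aggregate_matrix sums cells, excludes OUT, and conserves biomass", {
  df <- toy_records()
  df <- rbind(df, data.frame(year = 2000L, species_code = "YFT", gear = "PS",
                             flag = "X", lat = -31, lon = -41,
                             catch_tonnes = 5))
  df$category_kind <- "single-species"
  m <- aggregate_matrix(df, "SWAO")
  expect_equal(m["2000", "YFT"], 15)  # 10 + 5 over two records
  expect_equal(m["2000", "ALB"], 5)
  expect_equal(m["2001", "ALB"], 0)   # unobserved combination

  # record outside the study area is excluded
  df2 <- rbind(df, data.frame(year = 2001L, species_code = "YFT", gear = "LL",
                              flag = "X", lat = 10, lon = -40,
                              catch_tonnes = 999,
                              category_kind = "single-species"))
  expect_equal(sum(aggregate_matrix(df2, "SWAO")), sum(df$catch_tonnes))

  expect_error(aggregate_matrix(df, "SEAO"), "no records")
})

test_that("aggregate_matrix matches independent accumulation and is order-invariant", {
  set.seed(42)
  n <- 200
  df <- data.frame(
    year = sample(2000:2004, n, replace = TRUE),
    species_code = sample(c("A", "B", "C"), n, replace = TRUE),
    gear = "LL", flag = "X",
    lat = runif(n, -50, -10), lon = runif(n, -60, 20),
    catch_tonnes = round(runif(n, 0.1, 50), 3),
    category_kind = "single-species"
  )
  m <- aggregate_matrix(df, "SWAO")
  # independent accumulation over raw rows
  keep <- df$lon < -20
  for (y in rownames(m)) {
    expected <- sum(df$catch_tonnes[keep & df$year == as.integer(y)])
    expect_equal(unname(sum(m[y, ])), expected, tolerance = 1e-12)
  }
  m_perm <- aggregate_matrix(df[sample(n), ], "SWAO")
  expect_equal(unclass(m), unclass(m_perm))
})

test_that("aggregate_matrix drops all-zero species columns with a message", {
  df <- toy_records()
  df <- rbind(df, data.frame(year = 2000L, species_code = "ZZZ", gear = "LL",
                             flag = "X", lat = -30, lon = -40,
                             catch_tonnes = 0))
  df$category_kind <- "single-species"
  expect_message(m <- aggregate_matrix(df, "SWAO"), "ZZZ")
  expect_false("ZZZ" %in% colnames(m))
})

test_that("catch matrices and series round-trip through CSV", {
  m <- catch_matrix(random_biomass(5, 3, 1))
  path <- tempfile(fileext = ".csv")
  write_catch_matrix(m, path)
  expect_equal(unclass(read_catch_matrix(path)), unclass(m),
               tolerance = 1e-12)

  s <- annual_series(2000:2004, rnorm(5))
  path2 <- tempfile(fileext = ".csv")
  write_annual_series(s, path2)
  expect_equal(as.numeric(read_annual_series(path2)), as.numeric(s),
               tolerance = 1e-12)
})

test_that("catch_matrix enforces its invariants", {
  expect_error(catch_matrix(matrix(-1, 2, 2), 1:2, c("A", "B")), "non-negative")
  expect_error(catch_matrix(matrix(1, 2, 2), c(2, 1), c("A", "B")),
               "strictly increasing")
  expect_error(catch_matrix(matrix(1, 2, 2), 1:2, c("A", "A")), "unique")
})
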