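#' Load a pipeline configuration
#'
#' Configurations are structured text (YAML, or JSON — detected by
#' extension). Exactly one of the `simulate` block (synthetic scenario) or
#' the `inputs` block (paths to catch / thermal / SST / BCt CSV files) must
#' be present.
#'
#' @param path path to a YAML or JSON configuration file.
#' @return the configuration as a named list, validated.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  has_sim <- !is.null(cfg$simulate)
  has_inputs <- !is.null(cfg$inputs)
  if (has_sim == has_inputs) {
    stop("config must have exactly one of `simulate` or `inputs`")
  }
  if (is.null(cfg$output_dir)) stop("config needs `output_dir`")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  defaults <- list(spline_k = 5, cv_folds = 10, max_lag = 4, n_perm = 999,
                   mrt_max_size = 10, size_rule = "min",
                   lag_common_sample = FALSE)
  cfg$models <- utils::modifyList(defaults, as.list(cfg$models))
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

load_stage_inputs <- function(cfg, log) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    par_args <- as.list(sim$params)
    par_args$seed <- cfg$seed
    params <- do.call(scenario_params, par_args)
    kind <- if (is.null(sim$kind)) "tropicalization" else sim$kind
    bundle <- switch(kind,
      tropicalization = tropicalization_scenario(
        params,
        planted_mtc_slope = if (is.null(sim$planted_mtc_slope)) 0.012
                            else sim$planted_mtc_slope),
      null = null_scenario(params),
      stop("unknown simulate kind: ", kind)
    )
    log("simulated scenario kind=", kind, " seed=", cfg$seed)
    bundle
  } else {
    inp <- cfg$inputs
    catch <- if (!is.null(inp$catch_records)) {
      recs <- read_catch_records(inp$catch_records, schema = inp$schema,
                                 study_window = cfg$study_window)
      table0 <- read_thermal_table(inp$thermal)
      flt <- filter_single_species(recs, table0$species_code)
      log(sprintf("record filter coverage %.4f", flt$coverage_fraction))
      region <- if (is.null(cfg$region)) "ALL" else cfg$region
      aggregate_matrix(flt$records, region)
    } else {
      read_catch_matrix(inp$catch)
    }
    list(params = NULL, table = read_thermal_table(inp$thermal),
         catch = catch,
         sst = if (!is.null(inp$sst)) read_annual_series(inp$sst),
         bct = if (!is.null(inp$bct)) read_annual_series(inp$bct))
  }
}

trend_row <- function(label, series, fit) {
  v <- as.numeric(series)
  data.frame(series = label,
             range_min = min(v, na.rm = TRUE),
             range_max = max(v, na.rm = TRUE),
             slope_per_yr = fit$slope, p_value = fit$p_value,
             r2 = fit$r2, adj_r2 = fit$adj_r2)
}

#' Run the full tropicalization analysis pipeline
#'
#' Sequences catch ingestion (or simulation), thermal classification, MTC
#' and warm-fraction series, trend and lagged-driver models, leave-one-out
#' sensitivity, composition analysis (Hellinger transform, multivariate
#' regression tree, PCoA) and beta-diversity / TBI decompositions, writing
#' one CSV per result plus a JSON run manifest into `output_dir`. A rerun
#' with the same configuration and seed is bit-identical.
#'
#' @param config a configuration list (see [read_pipeline_config()]) or a
#'   path to a YAML/JSON configuration file.
#' @param stages character subset of
#'   `c("mtc", "trends", "sensitivity", "lags", "composition", "betadiv",
#'   "tbi")`; defaults to all.
#' @return invisibly, a list with every intermediate and final result.
#' @export
run_pipeline <- function(config,
                         stages = c("mtc", "trends", "sensitivity", "lags",
                                    "composition", "betadiv", "tbi")) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else validate_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  log <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  out_csv <- function(df, name) {
    utils::write.csv(df, file.path(cfg$output_dir, name), row.names = FALSE)
  }

  stage <- "input"
  res <- tryCatch({
    bundle <- load_stage_inputs(cfg, log)
    res <- bundle
    res$mtc <- NULL

    stage <- "mtc"
    if ("mtc" %in% stages) {
      res$mtc <- compute_mtc(bundle$catch, bundle$table)
      res$warm <- warm_fraction_series(bundle$catch, bundle$table)
      write_annual_series(res$mtc, file.path(cfg$output_dir, "mtc.csv"))
      write_annual_series(res$warm$biomass_fraction,
                          file.path(cfg$output_dir, "warm_fraction.csv"))
      write_annual_series(to_anomaly(res$mtc),
                          file.path(cfg$output_dir, "mtc_anomaly.csv"))
    }

    stage <- "trends"
    if (any(c("trends", "lags") %in% stages) && is.null(res$mtc)) {
      res$mtc <- compute_mtc(bundle$catch, bundle$table)
    }
    if ("trends" %in% stages) {
      rows <- list()
      res$trend_mtc <- fit_linear_trend(res$mtc)
      res$spline_mtc <- fit_spline_trend(res$mtc, k = cfg$models$spline_k)
      res$model_choice <- choose_trend_model(res$trend_mtc, res$spline_mtc)
      rows$mtc <- trend_row("MTC", res$mtc, res$trend_mtc)
      if (!is.null(bundle$sst)) {
        res$trend_sst <- fit_linear_trend(bundle$sst)
        rows$sst <- trend_row("SST", bundle$sst, res$trend_sst)
      }
      if (!is.null(bundle$bct)) {
        res$trend_bct <- fit_linear_trend(bundle$bct)
        rows$bct <- trend_row("BCt", bundle$bct, res$trend_bct)
      }
      out_csv(do.call(rbind, rows), "trend_table.csv")
    }

    stage <- "sensitivity"
    if ("sensitivity" %in% stages) {
      res$sensitivity <- sensitivity_loo(bundle$catch, bundle$table)
      out_csv(as.data.frame(res$sensitivity), "sensitivity_table.csv")
    }

    stage <- "lags"
    if ("lags" %in% stages) {
      lag_rows <- list()
      if (!is.null(bundle$sst)) {
        res$lags_sst <- fit_lagged(to_anomaly(res$mtc), to_anomaly(bundle$sst),
                                   max_lag = cfg$models$max_lag,
                                   common_sample = cfg$models$lag_common_sample,
                                   driver_name = "SST")
        lag_rows$sst <- res$lags_sst$fits
      }
      if (!is.null(bundle$bct)) {
        res$lags_bct <- fit_lagged(to_anomaly(res$mtc), to_anomaly(bundle$bct),
                                   max_lag = cfg$models$max_lag,
                                   common_sample = cfg$models$lag_common_sample,
                                   driver_name = "BCt")
        lag_rows$bct <- res$lags_bct$fits
      }
      if (length(lag_rows) > 0) out_csv(do.call(rbind, lag_rows), "lag_table.csv")
    }

    stage <- "composition"
    if ("composition" %in% stages) {
      res$hellinger <- hellinger_transform(bundle$catch)
      res$mrt <- fit_mrt(res$hellinger, max_size = cfg$models$mrt_max_size,
                         cv_folds = cfg$models$cv_folds,
                         size_rule = cfg$models$size_rule, seed = cfg$seed)
      res$pcoa <- pcoa(distance_matrix(res$hellinger, "hellinger"))
      out_csv(data.frame(year = names(res$mrt$groups),
                         group = res$mrt$groups), "groups.csv")
      out_csv(res$mrt$cv_table, "cv_error.csv")
      ord <- data.frame(year = rownames(res$pcoa$coordinates),
                        res$pcoa$coordinates, check.names = FALSE)
      out_csv(ord, "ordination.csv")
      out_csv(data.frame(axis = seq_along(res$pcoa$eigenvalues),
                         eigenvalue = res$pcoa$eigenvalues), "eigenvalues.csv")
    }

    stage <- "betadiv"
    if ("betadiv" %in% stages) {
      h <- if (is.null(res$hellinger)) hellinger_transform(bundle$catch)
           else res$hellinger
      res$beta <- beta_decompose(h)
      res$ycbd_test <- ycbd_permutation_test(h, n_perm = cfg$models$n_perm,
                                             seed = cfg$seed)
      out_csv(data.frame(species_code = names(res$beta$scbd),
                         scbd = res$beta$scbd), "beta_scbd.csv")
      out_csv(data.frame(year = names(res$beta$ycbd), ycbd = res$beta$ycbd,
                         p_value = res$ycbd_test$p_values), "beta_ycbd.csv")
    }

    stage <- "tbi"
    if ("tbi" %in% stages) {
      res$tbi <- tbi_pairwise(bundle$catch)
      res$tbi_test <- tbi_gain_loss_test(res$tbi)
      out_csv(tbi_long(res$tbi), "tbi_pairs.csv")
    }
    res
  }, error = function(e) {
    stop("pipeline stage `", stage, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })

  writeLines(warnings_log, file.path(cfg$output_dir, "warnings.txt"))
  manifest <- list(
    package = "mtctrends",
    package_version = as.character(utils::packageVersion("mtctrends")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "output_dir")],
    config_hash = config_hash(cfg[setdiff(names(cfg), "output_dir")]),
    stages = stages
  )
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Run both regions and compare their MTC trends
#'
#' Convenience wrapper mirroring the paired western/eastern presentation:
#' runs the pipeline once per region configuration and adds the ANCOVA
#' slope comparison of the two MTC series.
#'
#' @param config_a,config_b configurations (lists or paths) for the two
#'   regions.
#' @param labels length-2 region labels.
#' @param ... passed to [run_pipeline()].
#' @return list with `a`, `b` (the per-region bundles) and `ancova`.
#' @export
run_two_region_comparison <- function(config_a, config_b,
                                      labels = c("SWAO", "SEAO"), ...) {
  a <- run_pipeline(config_a, ...)
  b <- run_pipeline(config_b, ...)
  list(a = a, b = b,
       ancova = compare_slopes_ancova(a$mtc, b$mtc, labels = labels))
}

#' Write a simulated scenario to disk in the pipeline's input formats
#'
#' Emits the same CSV layouts the readers consume (catch matrix, thermal
#' table, SST and BCt series) plus a JSON manifest recording every
#' parameter and the seed.
#'
#' @param params a [scenario_params()].
#' @param dir output directory (created if needed).
#' @param kind `"tropicalization"` or `"null"`.
#' @param planted_mtc_slope planted MTC trend for the tropicalization kind.
#' @return invisibly, the scenario bundle.
#' @export
simulate_to_files <- function(params, dir, kind = c("tropicalization", "null"),
                              planted_mtc_slope = 0.012) {
  kind <- match.arg(kind)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- if (kind == "null") null_scenario(params)
            else tropicalization_scenario(params, planted_mtc_slope)
  write_catch_matrix(bundle$catch, file.path(dir, "catch.csv"))
  write_thermal_table(bundle$table, file.path(dir, "thermal.csv"))
  write_annual_series(bundle$sst, file.path(dir, "sst.csv"))
  write_annual_series(bundle$bct, file.path(dir, "bct.csv"))
  jsonlite::write_json(
    c(list(kind = kind), unclass(bundle$params)),
    file.path(dir, "scenario_manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(bundle)
}

#' Command-line entry point
#'
#' Dispatches `mtctrends <subcommand> <config> [output_dir]`. Subcommands:
#' `simulate` (write a synthetic scenario), `all` (full pipeline), or any
#' single stage name (`mtc`, `trends`, `sensitivity`, `lags`,
#' `composition`, `betadiv`, `tbi` — earlier stages a later one depends on
#' are run as needed). Invoke from a shell as
#' `Rscript -e 'mtctrends::mtc_cli()' <subcommand> <config>`.
#'
#' @param args character vector of arguments (default: the command line).
#' @return invisibly, the result bundle.
#' @export
mtc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 2) {
    stop("usage: <simulate|all|mtc|trends|sensitivity|lags|composition|",
         "betadiv|tbi> <config.yaml> [dir]")
  }
  sub <- args[1]
  cfg <- read_pipeline_config(args[2])
  if (length(args) >= 3) cfg$output_dir <- args[3]
  if (sub == "simulate") {
    sim <- cfg$simulate
    par_args <- as.list(sim$params); par_args$seed <- cfg$seed
    return(invisible(simulate_to_files(
      do.call(scenario_params, par_args), cfg$output_dir,
      kind = if (is.null(sim$kind)) "tropicalization" else sim$kind
    )))
  }
  deps <- list(
    all = c("mtc", "trends", "sensitivity", "lags", "composition",
            "betadiv", "tbi"),
    mtc = "mtc", trends = c("mtc", "trends"),
    sensitivity = "sensitivity", lags = c("mtc", "lags"),
    composition = "composition", betadiv = "betadiv", tbi = "tbi"
  )
  if (!sub %in% names(deps)) stop("unknown subcommand: ", sub)
  invisible(run_pipeline(cfg, stages = deps[[sub]]))
}
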