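#' Default demonstration pipeline configuration
#'
#' A fully synthetic run over the [demo_region()] (676 points) for three
#' years: temperature fields with Gaussian spatial structure whose
#' nugget/sill/range magnitudes match published annual-THI variograms for
#' Pernambuco (THI sill ~1.7, nugget ~0.13, range ~60 km), a gentle
#' eastward warming trend, and all three variogram families fitted and
#' cross-validated per year.
#'
#' @param years Years simulated (default `2010:2012`).
#' @param seed RNG seed.
#' @return A nested configuration list accepted by [run_all()].
#' @export
demo_config <- function(years = 2010:2012, seed = 1L) {
  list(
    seed = as.integer(seed),
    years = as.integer(years),
    region = "demo",
    synthetic = list(
      tmax = list(mean = 29, model = "gaussian", nugget = 0.11,
                  sill = 1.4, range_m = 60000, trend = c(0.01, 0)),
      tmin = list(mean = 24, model = "gaussian", nugget = 0.11,
                  sill = 1.4, range_m = 60000, trend = c(0.01, 0)),
      ws = list(mean = 2, model = "gaussian", nugget = 0.02,
                sill = 0.2, range_m = 60000, trend = c(0, 0))
    ),
    variogram = list(n_lags = 12,
                     families = c("spherical", "exponential", "gaussian")),
    kriging = list(cell_m = 4000),
    zoning = list(min_fraction = 1, cdf_thresholds = c(72, 74, 77))
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the [demo_config()] schema; an `input` key
#'   (CSV path) replaces the `synthetic` block for real exported data.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$years) || length(cfg$years) == 0)
    stop("config error: no years")
  if (is.null(cfg$seed)) stop("config error: no seed")
  fams <- cfg$variogram$families %||% c("spherical", "exponential", "gaussian")
  bad <- setdiff(fams, c("spherical", "exponential", "gaussian"))
  if (length(bad))
    stop("config error: unknown model family ", paste(bad, collapse = ", "))
  if (is.null(cfg$input) && is.null(cfg$synthetic))
    stop("config error: need either 'input' (CSV path) or 'synthetic' block")
  if (!is.null(cfg$input) && !file.exists(cfg$input))
    stop("input file not found: ", cfg$input)
  invisible(cfg)
}

as_field_params <- function(b) {
  field_params(mean = b$mean, model = b$model, nugget = b$nugget,
               sill = b$sill, range_m = b$range_m,
               trend = b$trend %||% c(0, 0))
}

#' Validate and clean a climate sample table
#'
#' Rejects rows violating the physical constraints (`tmax_c > tmin_c`,
#' `ws_ms >= 0`), reports duplicated `(point_id, year)` keys, and fails
#' hard when more than half the rows are rejected (a likely schema
#' mismatch rather than scattered bad rows).
#'
#' @param table Parsed climate data frame (see [simulate_climate_series()]
#'   for the schema).
#' @return List with `data` (cleaned), `issues` (data frame `row`,
#'   `problem`), `n_in`, `n_out`.
#' @export
validate_inputs <- function(table) {
  need <- c("point_id", "x_m", "y_m", "region", "year",
            "tmax_c", "tmin_c", "ws_ms")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  issues <- data.frame(row = integer(), problem = character(),
                       stringsAsFactors = FALSE)
  bad_t <- which(!(table$tmax_c > table$tmin_c))
  bad_w <- which(table$ws_ms < 0)
  key <- paste(table$point_id, table$year, sep = "\r")
  dup <- which(duplicated(key))
  if (length(bad_t)) issues <- rbind(issues, data.frame(
    row = bad_t, problem = "tmax_c <= tmin_c"))
  if (length(bad_w)) issues <- rbind(issues, data.frame(
    row = bad_w, problem = "ws_ms < 0"))
  if (length(dup)) issues <- rbind(issues, data.frame(
    row = dup, problem = "duplicate (point_id, year)"))
  drop <- sort(unique(c(bad_t, bad_w, dup)))
  if (length(drop) > nrow(table) / 2)
    stop("more than 50% of rows rejected (", length(drop), "/", nrow(table),
         "): likely schema mismatch")
  out <- if (length(drop)) table[-drop, , drop = FALSE] else table
  rownames(out) <- NULL
  list(data = out, issues = issues, n_in = nrow(table), n_out = nrow(out))
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Run the full zoning pipeline
#'
#' Orchestrates all stages: climate input (synthetic simulation or CSV),
#' validation, annual THI, descriptive statistics, per-year empirical
#' semivariograms with all configured model families fitted and
#' cross-validated, model selection, ordinary-kriging surfaces, breed
#' suitability zoning and regional cumulative distributions. All outputs
#' are written to `out_dir` as plain text and are byte-identical across
#' re-runs with the same configuration and seed (the log carries no
#' timestamps). Report tables are rounded at write time (2 decimals for
#' THI summaries, 6 for cross-validation and variogram parameters);
#' `thi.csv` keeps full precision.
#'
#' @param config Configuration list ([demo_config()] or [read_config()]).
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly. Files written: `climate.csv`, `thi.csv`,
#'   `table1.csv`, `boxplot.csv`, `variogram_fits.csv` (all families),
#'   `table2.csv` (cross-validation), `table3.csv` (selected model per
#'   year), `thi_<year>.asc` and `thi_<year>_sigma.asc`,
#'   `zoning_report.csv`, `cdf_report.csv`, `config.yaml`, `run.log`.
#' @export
run_all <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    msg <- paste0(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  years <- as.integer(config$years)
  fams <- config$variogram$families %||%
    c("spherical", "exponential", "gaussian")

  region <- stage("region", {
    if (identical(config$region %||% "demo", "demo")) demo_region()
    else stop("unknown region preset: ", config$region)
  })
  say("region: ", region$name, " with ", nrow(region$points), " points")

  climate <- stage("climate", {
    if (!is.null(config$input)) {
      utils::read.csv(config$input, stringsAsFactors = FALSE)
    } else {
      simulate_climate_series(
        region, years,
        as_field_params(config$synthetic$tmax),
        as_field_params(config$synthetic$tmin),
        as_field_params(config$synthetic$ws),
        seed = config$seed)
    }
  })
  chk <- stage("validate", validate_inputs(climate))
  say("climate: ", chk$n_in, " rows in, ", chk$n_out, " kept, ",
      nrow(chk$issues), " issue(s)")
  climate <- chk$data
  utils::write.csv(climate, file.path(out_dir, "climate.csv"),
                   row.names = FALSE)

  thi <- stage("thi", annual_thi(climate, years))
  utils::write.csv(thi, file.path(out_dir, "thi.csv"), row.names = FALSE)
  say("thi: ", nrow(thi), " point-year values, range ",
      paste(round(range(thi$thi), 2), collapse = " - "))

  tab1 <- stage("stats", do.call(rbind, lapply(years, function(yr)
    summary_stats(thi$thi[thi$year == yr], year = yr))))
  utils::write.csv(round_df(tab1, 2), file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  box <- stage("boxplot", do.call(rbind, lapply(years, function(yr) {
    b <- boxplot_summary(thi$thi[thi$year == yr], year = yr)
    data.frame(year = yr, min_whisker = b$min_whisker, q1 = b$q1,
               median = b$median, q3 = b$q3, max_whisker = b$max_whisker,
               n_outliers = length(b$outliers))
  })))
  utils::write.csv(round_df(box, 2), file.path(out_dir, "boxplot.csv"),
                   row.names = FALSE)

  fits <- list(); cvrows <- list(); selected <- list()
  for (yr in years) {
    syr <- thi[thi$year == yr, , drop = FALSE]
    emp <- stage("variogram", empirical_semivariogram(
      cbind(syr$x_m, syr$y_m), syr$thi,
      n_lags = config$variogram$n_lags %||% 12))
    yr_fits <- lapply(fams, function(f)
      stage("variogram", fit_variogram(emp, f)))
    names(yr_fits) <- fams
    for (f in fams) {
      vm <- yr_fits[[f]]
      fits[[paste(yr, f)]] <- data.frame(
        year = yr, model = f, nugget = vm$nugget_c0, sill = vm$sill_total,
        range_m = vm$range_a, dsd_pct = vm$dsd_pct,
        dsd_class = vm$dsd_class, fit_r2 = vm$fit_r2,
        stringsAsFactors = FALSE)
      loo <- stage("crossval", loo_predict(syr, vm))
      cvrows[[paste(yr, f)]] <- cv_statistics(
        loo$observed, loo$predicted, loo$sigma, year = yr, family = f)
    }
    sel <- stage("crossval",
                 select_model(do.call(rbind, cvrows[paste(yr, fams)])))
    selected[[as.character(yr)]] <- yr_fits[[sel$family]]
    say("year ", yr, ": ", sel$rationale)
  }
  fits_df <- do.call(rbind, fits)
  utils::write.csv(round_df(fits_df, 6),
                   file.path(out_dir, "variogram_fits.csv"),
                   row.names = FALSE)
  utils::write.csv(round_df(do.call(rbind, cvrows), 6),
                   file.path(out_dir, "table2.csv"), row.names = FALSE)
  tab3 <- do.call(rbind, lapply(names(selected), function(yr) {
    vm <- selected[[yr]]
    data.frame(year = as.integer(yr), model = vm$family,
               nugget = vm$nugget_c0, sill = vm$sill_total,
               range_m = vm$range_a, dsd_pct = vm$dsd_pct,
               dsd_class = vm$dsd_class, fit_r2 = vm$fit_r2,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(round_df(tab3, 6), file.path(out_dir, "table3.csv"),
                   row.names = FALSE)

  registry <- load_breed_registry()
  zon <- list()
  for (yr in years) {
    syr <- thi[thi$year == yr, , drop = FALSE]
    kr <- stage("kriging", predict_grid(
      syr, selected[[as.character(yr)]], region,
      cell_m = config$kriging$cell_m %||% 4000))
    write_esri_ascii(kr, file.path(out_dir, sprintf("thi_%d.asc", yr)))
    write_esri_ascii(kr, file.path(out_dir, sprintf("thi_%d_sigma.asc", yr)),
                     what = "sigma")
    sm <- stage("zoning", suitability_masks(
      kr, registry, min_fraction = config$zoning$min_fraction %||% 1))
    zon[[as.character(yr)]] <- cbind(year = yr, sm$summary)
    say("year ", yr, ": kriged ", sum(!is.na(kr$grid$pred)), " cells; ",
        sum(sm$summary$area_pct == 100), " breed(s) suitable statewide")
  }
  utils::write.csv(round_df(do.call(rbind, zon), 2),
                   file.path(out_dir, "zoning_report.csv"),
                   row.names = FALSE)

  thresholds <- config$zoning$cdf_thresholds %||% c(72, 74, 77)
  periods <- quadrennials(years)
  cdfrows <- list()
  for (rg in names(region$subregions)) for (pn in names(periods)) {
    cd <- regional_cdf(thi, rg, periods[[pn]])
    for (tt in thresholds)
      cdfrows[[paste(rg, pn, tt)]] <- data.frame(
        region = rg, period = pn, threshold = tt,
        fraction = cdf_at(cd, tt), stringsAsFactors = FALSE)
  }
  utils::write.csv(round_df(do.call(rbind, cdfrows), 4),
                   file.path(out_dir, "cdf_report.csv"), row.names = FALSE)

  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
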