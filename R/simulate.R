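#' Parameters of a stationary random field
#'
#' Bundles the mean, variogram family and variogram parameters used by
#' [simulate_gaussian_field()]. The covariance implied by a bounded
#' variogram model is `C(h) = sill - gamma(h)`, so `sill` is the total
#' variance (nugget included) and `nugget` the discontinuity at the origin.
#'
#' @param mean Field mean, in units of the variable.
#' @param model Variogram family: `"spherical"`, `"exponential"` or
#'   `"gaussian"`.
#' @param nugget Nugget variance (>= 0).
#' @param sill Total sill (>= nugget).
#' @param range_m Practical range in meters (> 0; `0` is accepted and means
#'   a pure-nugget, spatially uncorrelated field).
#' @param trend Optional linear spatial gradient `c(dx, dy)` in variable
#'   units per km, applied about the field centroid so the mean is
#'   preserved.
#' @return An object of class `field_params`.
#' @export
field_params <- function(mean, model = c("gaussian", "spherical", "exponential"),
                         nugget, sill, range_m, trend = c(0, 0)) {
  model <- match.arg(model)
  if (nugget < 0) stop("nugget must be >= 0")
  if (sill < nugget) stop("sill must be >= nugget")
  if (range_m < 0) stop("range_m must be >= 0")
  stopifnot(length(trend) == 2, is.numeric(trend))
  structure(list(mean = mean, model = model, nugget = nugget, sill = sill,
                 range_m = range_m, trend = as.numeric(trend)),
            class = "field_params")
}

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Covariance from a bounded variogram model; diag(h = 0) = sill.
cov_from_variogram <- function(h, params) {
  if (params$range_m == 0) {           # pure nugget
    return(ifelse(h == 0, params$sill, 0))
  }
  params$sill - model_semivariance(h, params$model, params$nugget,
                                   params$sill, params$range_m)
}

#' Simulate a stationary Gaussian random field on a region's lattice
#'
#' Draws one realisation of a Gaussian process whose semivariogram is the
#' requested model, by dense Cholesky factorization of the implied
#' covariance matrix over the region's grid points. A small diagonal
#' jitter (`1e-10 * sill`) keeps the factorization numerically positive
#' definite. Intended for desk-scale grids; a guard refuses more than
#' 5000 points.
#'
#' @param region A [make_region()] `region_spec`.
#' @param params A [field_params()] object.
#' @param seed Integer seed; the draw is a pure function of
#'   `(region, params, seed)`. `NULL` uses the current RNG stream.
#' @return Numeric vector of field values, one per `region$points` row.
#' @export
simulate_gaussian_field <- function(region, params, seed = NULL) {
  stopifnot(inherits(region, "region_spec"), inherits(params, "field_params"))
  pts <- region$points
  n <- nrow(pts)
  if (n > 5000)
    stop("grid has ", n, " points; dense simulation is guarded at 5000")
  draw <- function() {
    base <- rep(params$mean, n)
    if (any(params$trend != 0)) {
      base <- base +
        params$trend[1] * (pts$x_m - mean(pts$x_m)) / 1000 +
        params$trend[2] * (pts$y_m - mean(pts$y_m)) / 1000
    }
    if (params$sill == 0) return(base)
    D <- as.matrix(stats::dist(cbind(pts$x_m, pts$y_m)))
    C <- cov_from_variogram(D, params)
    diag(C) <- diag(C) + 1e-10 * params$sill
    R <- tryCatch(chol(C), error = function(e)
      stop("covariance matrix not positive definite after regularization (",
           conditionMessage(e), ")"))
    base + drop(crossprod(R, stats::rnorm(n)))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a multi-year gridded climate series
#'
#' Generates one row per grid point and year with maximum temperature,
#' minimum temperature and mean wind speed, each drawn as an independent
#' stationary Gaussian field (fields are redrawn independently per year;
#' no cross-variable or between-year covariance is imposed). Physical
#' constraints are enforced after the draw: wind speed is truncated at 0
#' and `tmin` is clipped to at most `tmax - 0.01` degC, so every row
#' satisfies `tmax_c > tmin_c` and `ws_ms >= 0`.
#'
#' @param region A `region_spec`.
#' @param years Integer vector of years (non-empty).
#' @param tmax_params,tmin_params,ws_params [field_params()] for the three
#'   variables; `tmax_params$mean` must exceed `tmin_params$mean` and
#'   `ws_params$mean` must be >= 0.
#' @param seed Integer seed; the whole table is a pure function of the
#'   configuration and the seed.
#' @return Data frame with columns `point_id`, `x_m`, `y_m`, `region`,
#'   `year`, `tmax_c`, `tmin_c`, `ws_ms`.
#' @export
simulate_climate_series <- function(region, years, tmax_params, tmin_params,
                                    ws_params, seed = 1L) {
  stopifnot(inherits(region, "region_spec"))
  if (length(years) == 0) stop("empty year list")
  if (anyDuplicated(years)) stop("duplicate years")
  if (tmax_params$mean <= tmin_params$mean)
    stop("tmax mean must exceed tmin mean")
  if (ws_params$mean < 0) stop("wind-speed mean must be >= 0")
  pts <- region$points
  with_seed(seed, {
    rows <- lapply(years, function(yr) {
      tmax <- simulate_gaussian_field(region, tmax_params)
      tmin <- simulate_gaussian_field(region, tmin_params)
      ws <- simulate_gaussian_field(region, ws_params)
      tmin <- pmin(tmin, tmax - 0.01)
      ws <- pmax(ws, 0)
      data.frame(point_id = pts$point_id, x_m = pts$x_m, y_m = pts$y_m,
                 region = pts$region, year = yr,
                 tmax_c = tmax, tmin_c = tmin, ws_ms = ws,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
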