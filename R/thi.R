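#' Mean air temperature from daily extremes
#'
#' The arithmetic mean of the maximum and minimum air temperature, the
#' standard convention for deriving mean air temperature from gridded
#' Tmax/Tmin products.
#'
#' @param tmax_c,tmin_c Numeric vectors, degC; `tmax_c > tmin_c` elementwise.
#' @return `(tmax_c + tmin_c) / 2`, degC.
#' @export
mean_air_temperature <- function(tmax_c, tmin_c) {
  bad <- which(tmax_c <= tmin_c)
  if (length(bad))
    stop("tmax_c <= tmin_c at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  (tmax_c + tmin_c) / 2
}

#' Temperature-humidity index from mean temperature and wind speed
#'
#' The wind-adjusted THI used for sheep heat-stress assessment:
#' `THI = (6.3952 + 0.08964 * Tair + 0.01018 * Ws)^2`. Despite the
#' index's name this form carries no humidity term; it is a quadratic in
#' mean air temperature with a small wind-speed adjustment, strictly
#' increasing in both arguments over the physical domain. Typical values
#' for Tair 20-32 degC and Ws 0-6 m/s span roughly 67-84; higher values
#' mean a more thermally stressful environment.
#'
#' @param tair_c Mean air temperature, degC.
#' @param ws_ms Mean wind speed, m/s (>= 0).
#' @return THI (dimensionless), unrounded.
#' @examples
#' compute_thi(28, 2)  # 79.664
#' @export
compute_thi <- function(tair_c, ws_ms) {
  if (any(ws_ms < 0)) stop("ws_ms must be >= 0")
  (6.3952 + 0.08964 * tair_c + 0.01018 * ws_ms)^2
}

#' Annual THI field from a climate table
#'
#' Computes one THI value per grid point and year from that point-year's
#' annual-mean temperatures and wind speed: the index is evaluated once on
#' the annual means (index-of-means), not averaged over months.
#'
#' @param samples Climate data frame with columns `point_id`, `x_m`,
#'   `y_m`, `region`, `year`, `tmax_c`, `tmin_c`, `ws_ms` (as produced by
#'   [simulate_climate_series()] or read from CSV).
#' @param years Optional integer vector restricting the output years;
#'   `NULL` keeps all. Requesting a year absent from the table is an error.
#' @return Data frame with columns `point_id`, `x_m`, `y_m`, `region`,
#'   `year`, `tair_c`, `thi`.
#' @export
annual_thi <- function(samples, years = NULL) {
  need <- c("point_id", "x_m", "y_m", "region", "year",
            "tmax_c", "tmin_c", "ws_ms")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!is.null(years)) {
    absent <- setdiff(years, unique(samples$year))
    if (length(absent))
      stop("year(s) absent from table: ", paste(absent, collapse = ", "))
    samples <- samples[samples$year %in% years, , drop = FALSE]
  }
  if (nrow(samples) == 0) stop("no samples")
  key <- paste(samples$point_id, samples$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- samples[duplicated(key), c("point_id", "year")][1, ]
    stop("duplicate (point_id, year): ", d$point_id, ", ", d$year)
  }
  tair <- mean_air_temperature(samples$tmax_c, samples$tmin_c)
  out <- data.frame(point_id = samples$point_id, x_m = samples$x_m,
                    y_m = samples$y_m, region = samples$region,
                    year = samples$year, tair_c = tair,
                    thi = compute_thi(tair, samples$ws_ms),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
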