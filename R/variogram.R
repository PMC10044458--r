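#' Empirical (experimental) semivariogram
#'
#' Binned method-of-moments estimator: for each lag bin the semivariance
#' is `sum((z_i - z_j)^2) / (2 N)` over the `N` point pairs whose
#' separation falls in the bin. Bins are right-closed intervals
#' `((k-1) w, k w]` of width `w = lag_width`; pairs at exactly zero
#' distance (duplicate coordinates) are excluded with a warning, since
#' the estimator is defined for h > 0 only.
#'
#' @param coords Two-column matrix or data frame of planar coordinates
#'   (meters), n >= 10 points.
#' @param values Numeric vector of the regionalized variable, one per point.
#' @param n_lags Number of lag bins (default 12).
#' @param lag_width Bin width in meters; default `max_dist / n_lags`.
#' @param max_dist Largest separation considered; default half the maximum
#'   pairwise distance.
#' @return Object of class `empirical_variogram`: a data frame with
#'   columns `lag_center_m` (mean pair separation within the bin, which
#'   places lattice data correctly; the nominal bin center for empty
#'   bins), `gamma` (`NA` for empty bins) and `pairs`, with attributes
#'   `lag_width`, `max_dist`, `n` and `var` (sample variance of
#'   `values`).
#' @export
empirical_semivariogram <- function(coords, values, n_lags = 12,
                                    lag_width = NULL, max_dist = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("coords must have two columns")
  n <- nrow(coords)
  if (n < 10) stop("need at least 10 points")
  if (length(values) != n) stop("values length must match coords")
  h <- as.vector(stats::dist(coords))
  dz2 <- as.vector(stats::dist(values))^2
  if (any(h == 0)) {
    warning("duplicate coordinates: ", sum(h == 0),
            " zero-distance pair(s) excluded")
    dz2 <- dz2[h > 0]
    h <- h[h > 0]
  }
  if (is.null(max_dist)) max_dist <- max(h) / 2
  if (is.null(lag_width)) {
    if (n_lags < 1) stop("n_lags must be >= 1")
    lag_width <- max_dist / n_lags
  } else {
    if (lag_width <= 0) stop("lag_width must be > 0")
    n_lags <- ceiling(max_dist / lag_width)
  }
  keep <- h <= n_lags * lag_width
  if (!any(keep)) stop("all pairs beyond max_dist: empty variogram")
  bin <- ceiling(h[keep] / lag_width)
  pairs <- tabulate(bin, nbins = n_lags)
  ssq <- vapply(seq_len(n_lags), function(k) sum(dz2[keep][bin == k]), 0)
  hsum <- vapply(seq_len(n_lags), function(k) sum(h[keep][bin == k]), 0)
  gamma <- ifelse(pairs > 0, ssq / (2 * pairs), NA_real_)
  # lag position = mean pair separation in the bin (the nominal center
  # misplaces lattice data whose pair distances cluster near bin edges);
  # empty bins fall back to the nominal center
  centers <- ifelse(pairs > 0, hsum / pmax(pairs, 1),
                    (seq_len(n_lags) - 0.5) * lag_width)
  out <- data.frame(lag_center_m = centers, gamma = gamma, pairs = pairs)
  structure(out, class = c("empirical_variogram", "data.frame"),
            lag_width = lag_width, max_dist = n_lags * lag_width,
            n = n, var = stats::var(values))
}

#' Theoretical semivariogram models
#'
#' The three classical bounded models, with the practical-range `-3`
#' scaling for the exponential and Gaussian families and `gamma(0) = 0`
#' exactly (the nugget is a jump as h -> 0+). Writing `C = sill - nugget`
#' for the partial sill:
#' \itemize{
#'   \item spherical: `nugget + C (1.5 h/a - 0.5 (h/a)^3)` for `h <= a`,
#'     `nugget + C` beyond the range `a`;
#'   \item exponential: `nugget + C (1 - exp(-3 h / a))`;
#'   \item gaussian: `nugget + C (1 - exp(-3 h^2 / a^2))`.
#' }
#' The spherical model attains its sill exactly at `h = a`; the other two
#' reach 95% of the partial sill there.
#'
#' @param h Distances in meters (>= 0), vectorized.
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget_c0 Nugget variance.
#' @param sill_total Total sill (`C0 + C`).
#' @param range_a Range in meters (> 0).
#' @return Semivariance at each `h`.
#' @export
model_semivariance <- function(h, family = c("spherical", "exponential", "gaussian"),
                               nugget_c0, sill_total, range_a) {
  family <- match.arg(family)
  if (any(h < 0)) stop("negative distance")
  if (nugget_c0 < 0 || sill_total < nugget_c0 || range_a <= 0)
    stop("invalid parameters: need 0 <= nugget <= sill and range > 0")
  C <- sill_total - nugget_c0
  g <- switch(family,
    spherical = {
      r <- pmin(h / range_a, 1)
      nugget_c0 + C * (1.5 * r - 0.5 * r^3)
    },
    exponential = nugget_c0 + C * (1 - exp(-3 * h / range_a)),
    gaussian = nugget_c0 + C * (1 - exp(-3 * h^2 / range_a^2))
  )
  g[h == 0] <- 0
  g
}

#' Degree of spatial dependence
#'
#' The nugget-to-sill ratio in percent, `100 * C0 / (C0 + C)`, classified
#' as strong spatial dependence below 25%, moderate from 25 to 75%
#' (inclusive) and weak above 75%.
#'
#' @param nugget_c0 Nugget variance (>= 0).
#' @param sill_total Total sill (> 0, >= nugget).
#' @return List with `dsd_pct` and `dsd_class`.
#' @examples
#' dsd(0.1585, 1.6217)  # ~9.77%, strong
#' @export
dsd <- function(nugget_c0, sill_total) {
  if (sill_total <= 0) stop("sill_total must be > 0")
  if (nugget_c0 < 0 || nugget_c0 > sill_total)
    stop("need 0 <= nugget_c0 <= sill_total")
  pct <- 100 * nugget_c0 / sill_total
  cls <- if (pct < 25) "strong" else if (pct <= 75) "moderate" else "weak"
  list(dsd_pct = pct, dsd_class = cls)
}

#' Construct a variogram model object directly
#'
#' For using externally supplied (e.g. published) parameters in kriging
#' without refitting.
#'
#' @inheritParams model_semivariance
#' @param fit_r2,fit_weighted_sse Optional fit diagnostics.
#' @return Object of class `variogram_model`.
#' @export
variogram_model <- function(family, nugget_c0, sill_total, range_a,
                            fit_r2 = NA_real_, fit_weighted_sse = NA_real_) {
  family <- match.arg(family, c("spherical", "exponential", "gaussian"))
  if (nugget_c0 < 0 || sill_total < nugget_c0 || range_a <= 0)
    stop("invalid parameters: need 0 <= nugget <= sill and range > 0")
  d <- dsd(nugget_c0, sill_total)
  structure(list(family = family, nugget_c0 = nugget_c0,
                 sill_total = sill_total, range_a = range_a,
                 dsd_pct = d$dsd_pct, dsd_class = d$dsd_class,
                 fit_r2 = fit_r2, fit_weighted_sse = fit_weighted_sse),
            class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("variogram_model: %s  nugget %.4g  sill %.4g  range %.0f m\n",
              x$family, x$nugget_c0, x$sill_total, x$range_a))
  cat(sprintf("  DSD %.2f%% (%s)", x$dsd_pct, x$dsd_class))
  if (!is.na(x$fit_r2)) cat(sprintf("  fit R2 %.3f", x$fit_r2))
  cat("\n")
  invisible(x)
}

#' Fit a variogram model to an empirical semivariogram
#'
#' Bounded weighted least squares with Cressie weights
#' `w_k = N(h_k) / gamma_model(h_k)^2`, parametrized as (nugget, partial
#' sill, range) so the constraint `0 <= nugget <= sill` holds by
#' construction. Three starts are tried (a method-of-moments start, a
#' near-flat start and a steep short-range start) and the best solution
#' by weighted SSE is kept. Near-exact ties between starts go to the
#' larger nugget: a flat empirical variogram is read as absence of
#' spatial structure (pure nugget, DSD ~100%), not as structure with a
#' sub-resolution range, so the partial sill collapses to ~0 and the
#' range pins at its lower bound (the shortest observed lag).
#'
#' @param emp An [empirical_semivariogram()] result.
#' @param family Model family to fit.
#' @return A `variogram_model` with fit diagnostics; `fit_r2` is the
#'   coefficient of determination of fitted vs empirical semivariances
#'   (unweighted).
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian")) {
  family <- match.arg(family)
  stopifnot(inherits(emp, "empirical_variogram"))
  ok <- !is.na(emp$gamma) & emp$pairs > 0
  h <- emp$lag_center_m[ok]
  g <- emp$gamma[ok]
  N <- emp$pairs[ok]
  if (length(h) < 4) stop("need at least 4 non-empty lag bins")
  gmax <- max(g)
  if (gmax == 0) return(variogram_model(family, 0, 1e-12, attr(emp, "lag_width"),
                                        fit_r2 = 1, fit_weighted_sse = 0))
  hmax <- max(h)
  a_lo <- min(h)   # ranges below the shortest lag are unobservable
  # optimize in scaled units (semivariances / gmax, distances / hmax) so
  # the nugget, partial sill and range move on comparable scales
  gam_of <- function(p) model_semivariance(h, family, p[1] * gmax,
                                           (p[1] + p[2]) * gmax, p[3] * hmax)
  weights_at <- function(p) N / pmax(gam_of(p), 1e-10 * gmax)^2
  # method-of-moments start
  sill0 <- mean(g[h >= 0.7 * hmax])
  nug0 <- max(min(g[1], sill0), 0)
  reach <- h[which(g >= nug0 + 0.95 * (sill0 - nug0))[1]]
  if (is.na(reach)) reach <- hmax / 2
  starts <- list(
    c(nug0 * 0.5 / gmax, max(sill0 - nug0 * 0.5, 0.05 * gmax) / gmax,
      reach / hmax),
    c(mean(g) * 0.9 / gmax, 0.1, 1),
    c(0, 1, 0.25))
  # the range is only identifiable inside the observed lag span; beyond
  # hmax the sill would be pure extrapolation
  lower <- c(0, 0, a_lo / hmax)
  upper <- c(2, 3, 1)
  # Cressie's iteratively reweighted WLS: weights are frozen at the
  # current model per solve (minimizing jointly over weights and
  # parameters would reward inflating the model semivariance)
  solve_from <- function(s) {
    p <- pmin(pmax(s, lower), upper)
    res <- NULL
    for (it in 1:10) {
      w <- weights_at(p)
      obj <- function(q) sum(w * (g - gam_of(q))^2)
      res <- tryCatch(
        stats::optim(p, obj, method = "L-BFGS-B", lower = lower,
                     upper = upper, control = list(maxit = 1000, factr = 1e4)),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      if (max(abs(res$par - p)) < 1e-8) { p <- res$par; break }
      p <- res$par
    }
    # report the SSE with weights evaluated at the solution itself
    list(par = p, value = sum(weights_at(p) * (g - gam_of(p))^2))
  }
  sols <- Filter(Negate(is.null), lapply(starts, solve_from))
  if (!length(sols)) stop("variogram fit failed for all starts (", family, ")")
  # best weighted SSE; among (near-)exact ties, a flat variogram is read
  # as absence of spatial structure, so the tie goes to the larger nugget
  vals <- vapply(sols, `[[`, 0, "value")
  tied <- vals <= min(vals) + 1e-8 * (1 + min(vals))
  nuggets <- vapply(sols, function(r) r$par[1], 0)
  best <- sols[[which(tied & nuggets == max(nuggets[tied]))[1]]]
  p <- best$par * c(gmax, gmax, hmax)
  m <- model_semivariance(h, family, p[1], p[1] + p[2], p[3])
  r2 <- 1 - sum((g - m)^2) / sum((g - mean(g))^2)
  variogram_model(family, p[1], p[1] + p[2], p[3],
                  fit_r2 = r2, fit_weighted_sse = best$value)
}
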