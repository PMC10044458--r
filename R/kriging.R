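# Semivariogram-form ordinary kriging. The augmented system is
#   [ Gamma  1 ] [w ]   [ gamma0 ]
#   [ 1'     0 ] [mu] = [ 1      ]
# with Gamma[i,j] = gamma(|x_i - x_j|) (zero diagonal: the whole nugget
# lives in gamma for h > 0) and kriging variance w' gamma0 + mu.

gamma_matrix <- function(locs, model) {
  D <- as.matrix(stats::dist(locs))
  G <- model_semivariance(D, model$family, model$nugget_c0,
                          model$sill_total, model$range_a)
  dim(G) <- dim(D)
  G
}

augmented_gamma <- function(locs, model) {
  n <- nrow(locs)
  G <- gamma_matrix(locs, model)
  rbind(cbind(G, 1), c(rep(1, n), 0))
}

gamma_to_targets <- function(locs, targets, model) {
  # (n x m) matrix of gamma(sample_i, target_j)
  D <- sqrt(outer(locs[, 1], targets[, 1], "-")^2 +
            outer(locs[, 2], targets[, 2], "-")^2)
  G <- model_semivariance(D, model$family, model$nugget_c0,
                          model$sill_total, model$range_a)
  dim(G) <- dim(D)
  G
}

#' Ordinary kriging weights and variance for one target location
#'
#' Solves the ordinary-kriging system built from model semivariances with
#' the unbiasedness constraint (weights sum to one); the Lagrange
#' multiplier and the kriging variance `sum(w * gamma0) + mu` are returned
#' alongside the prediction. A target coinciding with a sample location
#' (within 1e-9 m) bypasses the solve and returns that sample exactly,
#' with zero variance.
#'
#' @param sample_locs Two-column matrix of sample coordinates (meters),
#'   no duplicates.
#' @param sample_vals Sample values, one per location.
#' @param target Length-2 numeric target coordinate.
#' @param model A `variogram_model`.
#' @return List with `weights`, `lagrange`, `variance` (clipped at 0 with
#'   a warning if negative by round-off) and `prediction`.
#' @export
kriging_weights <- function(sample_locs, sample_vals, target, model) {
  sample_locs <- as.matrix(sample_locs)
  n <- nrow(sample_locs)
  stopifnot(n >= 1, length(sample_vals) == n, length(target) == 2,
            inherits(model, "variogram_model"))
  d0 <- sqrt((sample_locs[, 1] - target[1])^2 +
             (sample_locs[, 2] - target[2])^2)
  if (n > 1 && min(stats::dist(sample_locs)) < 1e-9)
    stop("duplicate sample coordinates; clean duplicates before kriging")
  hit <- which(d0 < 1e-9)
  if (length(hit)) {
    w <- rep(0, n); w[hit[1]] <- 1
    return(list(weights = w, lagrange = 0, variance = 0,
                prediction = sample_vals[hit[1]]))
  }
  A <- augmented_gamma(sample_locs, model)
  g0 <- model_semivariance(d0, model$family, model$nugget_c0,
                           model$sill_total, model$range_a)
  sol <- tryCatch(solve(A, c(g0, 1)), error = function(e)
    stop("singular kriging system (duplicate or degenerate sample ",
         "configuration?): ", conditionMessage(e)))
  w <- sol[seq_len(n)]
  mu <- sol[n + 1]
  v <- sum(w * g0) + mu
  if (v < 0) {
    if (v < -1e-8) warning("negative kriging variance ", v, " clipped to 0")
    v <- 0
  }
  list(weights = w, lagrange = mu, variance = v,
       prediction = sum(w * sample_vals))
}

#' Krige a surface over a region's cell lattice
#'
#' Ordinary kriging of point values onto a regular cell lattice clipped to
#' the region, returning the prediction and the kriging standard error per
#' cell. The default neighborhood is global (all samples enter every
#' prediction; one factorization serves all cells). A local neighborhood
#' `list(max_n =, radius_m =)` restricts each prediction to the nearest
#' `max_n` samples within `radius_m`; cells with fewer than 2 neighbors
#' are flagged no-data (`NA`).
#'
#' @param samples Data frame with columns `x_m`, `y_m` and the value
#'   column (default `"thi"`).
#' @param model A `variogram_model` fitted on the same variable.
#' @param region A `region_spec` defining the prediction window.
#' @param cell_m Cell size in meters (default 4000, matching the input
#'   lattice).
#' @param neighborhood `NULL` (global) or `list(max_n, radius_m)`.
#' @param value_col Name of the value column in `samples`.
#' @return Object of class `kriging_result`: list with `grid` (data frame
#'   `x_m`, `y_m`, `region`, `pred`, `sigma`), `model`, `cell_m`,
#'   `neighborhood` and `region_name`.
#' @export
predict_grid <- function(samples, model, region, cell_m = 4000,
                         neighborhood = NULL, value_col = "thi") {
  stopifnot(inherits(model, "variogram_model"),
            inherits(region, "region_spec"), cell_m > 0)
  if (!value_col %in% names(samples)) stop("no column '", value_col, "'")
  locs <- cbind(samples$x_m, samples$y_m)
  vals <- samples[[value_col]]
  n <- nrow(locs)
  if (n < 2) stop("need at least 2 samples")
  if (min(stats::dist(locs)) < 1e-9)
    stop("duplicate sample coordinates; clean duplicates before kriging")
  b <- region$bounds
  xs <- seq(b[1], b[2], by = cell_m)
  ys <- seq(b[3], b[4], by = cell_m)
  cells <- expand.grid(x_m = xs, y_m = ys, KEEP.OUT.ATTRS = FALSE)
  lab <- assign_subregion(cells$x_m, cells$y_m, region$subregions)
  cells <- cells[!is.na(lab), , drop = FALSE]
  lab <- lab[!is.na(lab)]
  m <- nrow(cells)
  if (m == 0) stop("no cells inside the region")
  tg <- as.matrix(cells)
  pred <- numeric(m); sig <- numeric(m)
  if (is.null(neighborhood)) {
    A <- augmented_gamma(locs, model)
    G0 <- rbind(gamma_to_targets(locs, tg, model), 1)
    W <- solve(A, G0)
    pred <- drop(crossprod(W[seq_len(n), , drop = FALSE], vals))
    v <- colSums(W[seq_len(n), , drop = FALSE] *
                   G0[seq_len(n), , drop = FALSE]) + W[n + 1, ]
    sig <- sqrt(pmax(v, 0))
  } else {
    max_n <- neighborhood$max_n %||% 24
    radius <- neighborhood$radius_m %||% model$range_a
    for (j in seq_len(m)) {
      d <- sqrt((locs[, 1] - tg[j, 1])^2 + (locs[, 2] - tg[j, 2])^2)
      near <- order(d)[seq_len(min(max_n, n))]
      near <- near[d[near] <= radius]
      if (length(near) < 2) { pred[j] <- NA; sig[j] <- NA; next }
      kw <- kriging_weights(locs[near, , drop = FALSE], vals[near],
                            tg[j, ], model)
      pred[j] <- kw$prediction
      sig[j] <- sqrt(kw$variance)
    }
    if (all(is.na(pred))) stop("neighborhood too small everywhere")
  }
  # exactness at sample locations: override round-off from the dense solve
  exact <- which(outer_min_dist(tg, locs) < 1e-9)
  if (length(exact)) {
    idx <- nearest_index(tg[exact, , drop = FALSE], locs)
    pred[exact] <- vals[idx]
    sig[exact] <- 0
  }
  structure(list(grid = data.frame(x_m = cells$x_m, y_m = cells$y_m,
                                   region = lab, pred = pred, sigma = sig,
                                   stringsAsFactors = FALSE),
                 model = model, cell_m = cell_m,
                 neighborhood = neighborhood, region_name = region$name),
            class = "kriging_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

outer_min_dist <- function(a, b) {
  # for each row of a, distance to the nearest row of b
  apply(a, 1, function(p) sqrt(min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2)))
}

nearest_index <- function(a, b) {
  apply(a, 1, function(p) which.min((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))
}

#' @export
print.kriging_result <- function(x, ...) {
  ok <- !is.na(x$grid$pred)
  cat("kriging_result:", sum(ok), "of", nrow(x$grid), "cells predicted (",
      x$cell_m, "m cells )\n")
  cat("  model:", x$model$family, " pred range:",
      paste(signif(range(x$grid$pred[ok]), 5), collapse = " - "), "\n")
  invisible(x)
}

#' Write a kriged surface as an ESRI ASCII grid
#'
#' Serialises the cell lattice of a [predict_grid()] result in `.asc`
#' format (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value` header, rows written north to south). Cells outside the
#' region carry the no-data sentinel.
#'
#' @param kr A `kriging_result`.
#' @param path Output file path.
#' @param what `"pred"` or `"sigma"`.
#' @param nodata No-data sentinel (default -9999).
#' @param digits Significant digits written (default 6).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(kr, path, what = c("pred", "sigma"),
                             nodata = -9999, digits = 6) {
  what <- match.arg(what)
  stopifnot(inherits(kr, "kriging_result"))
  g <- kr$grid
  xs <- sort(unique(g$x_m)); ys <- sort(unique(g$y_m))
  M <- matrix(NA_real_, length(ys), length(xs))
  M[cbind(match(g$y_m, ys), match(g$x_m, xs))] <- g[[what]]
  lines <- c(
    paste("ncols", length(xs)),
    paste("nrows", length(ys)),
    paste("xllcorner", format(min(xs) - kr$cell_m / 2, scientific = FALSE)),
    paste("yllcorner", format(min(ys) - kr$cell_m / 2, scientific = FALSE)),
    paste("cellsize", format(kr$cell_m, scientific = FALSE)),
    paste("NODATA_value", nodata))
  rows <- vapply(rev(seq_along(ys)), function(i) {
    v <- M[i, ]
    v_chr <- ifelse(is.na(v), as.character(nodata),
                    formatC(signif(v, digits), format = "fg", flag = "#"))
    paste(v_chr, collapse = " ")
  }, "")
  writeLines(c(lines, rows), path)
  invisible(path)
}
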