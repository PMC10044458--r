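# Shared fixtures and independent oracles for the test suite.

# Small single-subregion square region.
square_region <- function(side_m = 100000, spacing = 4000) {
  make_region("square", c(0, side_m, 0, side_m), grid_spacing = spacing)
}

# Random scattered sample configuration (no duplicate coordinates).
random_config <- function(n, seed, extent = 100) {
  set.seed(seed)
  repeat {
    locs <- cbind(runif(n, 0, extent), runif(n, 0, extent))
    if (n < 2 || min(dist(locs)) > 1e-6) break
  }
  list(locs = locs, vals = rnorm(n, 10, 2))
}

# Brute-force all-pairs binned semivariogram (independent of the
# package's dist()-based implementation): explicit double loop,
# right-closed bins ((k-1) w, k w].
brute_semivariogram <- function(locs, vals, lag_width, n_lags) {
  ssq <- numeric(n_lags)
  cnt <- integer(n_lags)
  n <- nrow(locs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    h <- sqrt(sum((locs[i, ] - locs[j, ])^2))
    if (h <= 0) next
    k <- ceiling(h / lag_width)
    if (k >= 1 && k <= n_lags) {
      ssq[k] <- ssq[k] + (vals[i] - vals[j])^2
      cnt[k] <- cnt[k] + 1L
    }
  }
  list(gamma = ifelse(cnt > 0, ssq / (2 * cnt), NA_real_), pairs = cnt)
}

# Independent ordinary-kriging solve: builds the augmented system with
# its own semivariance evaluation and solves it densely.
brute_ok <- function(locs, vals, target, family, nugget, sill, range_a) {
  gfun <- function(h) {
    C <- sill - nugget
    out <- switch(family,
      spherical = ifelse(h <= range_a,
                         nugget + C * (1.5 * h / range_a - 0.5 * (h / range_a)^3),
                         nugget + C),
      exponential = nugget + C * (1 - exp(-3 * h / range_a)),
      gaussian = nugget + C * (1 - exp(-3 * h^2 / range_a^2)))
    out[h == 0] <- 0
    out
  }
  n <- nrow(locs)
  A <- matrix(0, n + 1, n + 1)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, j] <- gfun(sqrt(sum((locs[i, ] - locs[j, ])^2)))
  A[n + 1, seq_len(n)] <- 1
  A[seq_len(n), n + 1] <- 1
  g0 <- vapply(seq_len(n),
               function(i) gfun(sqrt(sum((locs[i, ] - target)^2))), 0)
  sol <- solve(A, c(g0, 1))
  list(weights = sol[seq_len(n)], lagrange = sol[n + 1],
       variance = sum(sol[seq_len(n)] * g0) + sol[n + 1],
       prediction = sum(sol[seq_len(n)] * vals))
}

# THI field data frame from raw values on a region's lattice.
thi_frame <- function(region, values, year = 2010) {
  data.frame(point_id = region$points$point_id,
             x_m = region$points$x_m, y_m = region$points$y_m,
             region = region$points$region, year = year,
             tair_c = NA_real_, thi = values,
             stringsAsFactors = FALSE)
}
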