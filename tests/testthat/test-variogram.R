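test_that("binned estimator equals a hand-computed collinear example", {
  # points at x = 0, 1, 2 with z = 0, 1, 3 and unit lag bins:
  # gamma for |h| = 1 is (1 + 4)/(2*2), for |h| = 2 is 9/(2*1);
  # padded with far-away points to satisfy the n >= 10 precondition
  locs <- cbind(c(0, 1, 2, 100 + 7 * (1:7)), rep(0, 10))
  vals <- c(0, 1, 3, rep(0, 7))
  emp <- empirical_semivariogram(locs, vals, lag_width = 1, max_dist = 2.5)
  expect_equal(emp$gamma[emp$pairs == 2], 1.25)
  expect_equal(emp$gamma[1:2][emp$pairs[1:2] == 1], 4.5)
})

test_that("binned estimator equals brute-force all-pairs computation exactly", {
  for (seed in 1:20) {
    cfg <- random_config(sample(10:30, 1), seed)
    w <- runif(1, 5, 20)
    nl <- sample(4:10, 1)
    emp <- empirical_semivariogram(cfg$locs, cfg$vals, n_lags = nl,
                                   lag_width = w, max_dist = nl * w)
    oracle <- brute_semivariogram(cfg$locs, cfg$vals, w, nrow(emp))
    expect_identical(emp$pairs, oracle$pairs)
    expect_equal(emp$gamma, oracle$gamma, tolerance = 1e-12)
  }
})

test_that("constant fields and duplicate coordinates follow the conventions", {
  cfg <- random_config(15, 99)
  emp <- empirical_semivariogram(cfg$locs, rep(3, 15))
  expect_true(all(emp$gamma[emp$pairs > 0] == 0))
  locs_dup <- rbind(cfg$locs, cfg$locs[1, , drop = FALSE])
  expect_warning(
    emp2 <- empirical_semivariogram(locs_dup, c(cfg$vals, cfg$vals[1])),
    "zero-distance")
  expect_lte(sum(emp2$pairs), 16 * 15 / 2 - 1)
  expect_error(empirical_semivariogram(cfg$locs, cfg$vals, lag_width = 1e-9,
                                       max_dist = 1e-9), "empty variogram")
})

test_that("model semivariances match hand evaluations and stay bounded", {
  expect_equal(model_semivariance(10, "spherical", 0.1, 1.0, 10), 1.0)
  expect_equal(model_semivariance(50, "spherical", 0.1, 1.0, 10), 1.0)
  # published 2010 parameters evaluated at the range
  expect_equal(model_semivariance(59902, "gaussian", 0.1585, 1.6217, 59902),
               0.1585 + (1.6217 - 0.1585) * (1 - exp(-3)), tolerance = 1e-12)
  expect_equal(model_semivariance(59902, "gaussian", 0.1585, 1.6217, 59902),
               1.5488, tolerance = 1e-4)
  for (f in c("spherical", "exponential", "gaussian")) {
    expect_equal(model_semivariance(0, f, 0.3, 2, 40), 0)
    h <- seq(0, 200, by = 0.5)
    g <- model_semivariance(h, f, 0.3, 2, 40)
    expect_true(all(diff(g[-1]) >= -1e-12))       # monotone for h > 0
    expect_true(all(g <= 2 + 1e-12))              # bounded by the sill
    # practical-range property at h = a
    ga <- model_semivariance(40, f, 0.3, 2, 40)
    if (f == "spherical") expect_equal(ga, 2)
    else expect_equal(ga, 0.3 + (1 - exp(-3)) * 1.7, tolerance = 1e-12)
  }
  expect_error(model_semivariance(-1, "gaussian", 0, 1, 10), "negative")
  expect_error(model_semivariance(1, "gaussian", 0.5, 0.4, 10), "invalid")
})

test_that("DSD reproduces published nugget/sill pairs and classifies by 25/75", {
  expect_equal(dsd(0.1585, 1.6217)$dsd_pct, 9.77, tolerance = 0.005)
  expect_equal(dsd(0.1585, 1.6217)$dsd_class, "strong")
  expect_equal(dsd(0, 1)$dsd_pct, 0)
  expect_equal(dsd(0, 1)$dsd_class, "strong")
  expect_equal(dsd(0.8, 1)$dsd_pct, 80)
  expect_equal(dsd(0.8, 1)$dsd_class, "weak")
  expect_equal(dsd(0.25, 1)$dsd_class, "moderate")
  expect_equal(dsd(0.75, 1)$dsd_class, "moderate")
  expect_error(dsd(0.1, 0), "sill_total")
  # the full packaged reference table reproduces its own DSD column
  ref <- read.csv(system.file("extdata", "pe_thi_variogram_params.csv",
                              package = "thermozone"))
  for (i in seq_len(nrow(ref)))
    expect_equal(dsd(ref$nugget[i], ref$sill[i])$dsd_pct, ref$dsd_pct[i],
                 tolerance = 0.05 / ref$dsd_pct[i])
})

test_that("noise-free model semivariances are recovered to high accuracy", {
  h <- (1:12 - 0.5) * 10000
  for (f in c("spherical", "exponential", "gaussian")) {
    g <- model_semivariance(h, f, 0.2, 1.5, 60000)
    emp <- structure(data.frame(lag_center_m = h, gamma = g,
                                pairs = rep(500L, 12)),
                     class = c("empirical_variogram", "data.frame"),
                     lag_width = 10000, max_dist = 120000, n = 500, var = 1.5)
    fit <- fit_variogram(emp, f)
    expect_equal(fit$nugget_c0, 0.2, tolerance = 1e-3)
    expect_equal(fit$sill_total, 1.5, tolerance = 1e-3)
    expect_equal(fit$range_a, 60000, tolerance = 1e-3)
    expect_gt(fit$fit_r2, 0.9999)
  }
})

test_that("a flat (pure nugget) variogram collapses the partial sill", {
  h <- (1:10 - 0.5) * 5000
  emp <- structure(data.frame(lag_center_m = h, gamma = rep(0.8, 10),
                              pairs = rep(300L, 10)),
                   class = c("empirical_variogram", "data.frame"),
                   lag_width = 5000, max_dist = 50000, n = 300, var = 0.8)
  for (f in c("spherical", "exponential", "gaussian")) {
    fit <- fit_variogram(emp, f)
    expect_gt(fit$dsd_pct, 95)
    expect_equal(fit$nugget_c0, 0.8, tolerance = 0.05)
  }
})

test_that("fitting is invariant to point relabeling", {
  cfg <- random_config(40, 7, extent = 100000)
  perm <- sample(40)
  emp1 <- empirical_semivariogram(cfg$locs, cfg$vals, n_lags = 8)
  emp2 <- empirical_semivariogram(cfg$locs[perm, ], cfg$vals[perm], n_lags = 8)
  expect_equal(as.data.frame(emp1), as.data.frame(emp2), tolerance = 1e-12)
  f1 <- fit_variogram(emp1, "spherical")
  f2 <- fit_variogram(emp2, "spherical")
  expect_equal(f1$nugget_c0, f2$nugget_c0, tolerance = 1e-9)
  expect_equal(f1$range_a, f2$range_a, tolerance = 1e-6)
})

test_that("simulated fields round-trip their variogram parameters", {
  # moderate-size recovery check; the full 676-point 10-seed study runs
  # with the acceptance suite
  r <- square_region(100000, 5000)  # 441 points
  true <- c(nugget = 0.15, sill = 1.6, range = 40000)
  fits <- sapply(1:6, function(s) {
    z <- simulate_gaussian_field(
      r, field_params(0, "gaussian", true["nugget"], true["sill"],
                      true["range"]), seed = 100 + s)
    fit <- fit_variogram(
      empirical_semivariogram(cbind(r$points$x_m, r$points$y_m), z),
      "gaussian")
    c(fit$nugget_c0, fit$sill_total, fit$range_a)
  })
  avg <- rowMeans(fits)
  expect_lt(abs(avg[1] - true["nugget"]) / true["nugget"], 0.3)
  expect_lt(abs(avg[2] - true["sill"]) / true["sill"], 0.3)
  expect_lt(abs(avg[3] - true["range"]) / true["range"], 0.3)
})
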