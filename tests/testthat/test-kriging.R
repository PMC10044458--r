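vm_test <- variogram_model("spherical", 0.1, 1.2, 40)

test_that("degenerate and symmetric configurations give the expected weights", {
  # single sample: full weight, prediction equals the sample
  kw <- kriging_weights(cbind(10, 10), 5, c(0, 0), vm_test)
  expect_equal(kw$weights, 1)
  expect_equal(kw$prediction, 5)
  # two samples equidistant from the target split the weight evenly
  kw2 <- kriging_weights(rbind(c(-10, 0), c(10, 0)), c(2, 4), c(0, 0), vm_test)
  expect_equal(kw2$weights, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(kw2$prediction, 3)
  # target on a sample location returns it exactly
  kw3 <- kriging_weights(rbind(c(0, 0), c(10, 0), c(0, 10)), c(7, 1, 2),
                         c(0, 0), vm_test)
  expect_equal(kw3$prediction, 7)
  expect_equal(kw3$variance, 0)
  expect_error(kriging_weights(rbind(c(0, 0), c(0, 0)), c(1, 2), c(5, 5),
                               vm_test), "duplicate")
})

test_that("weights equal a dense brute-force solve of the augmented system", {
  fams <- c("spherical", "exponential", "gaussian")
  for (seed in 1:20) {
    n <- sample(4:50, 1)
    cfg <- random_config(n, 200 + seed)
    f <- fams[1 + seed %% 3]
    nug <- runif(1, 0, 0.5)
    sill <- nug + runif(1, 0.2, 2)
    a <- runif(1, 20, 80)
    vm <- variogram_model(f, nug, sill, a)
    target <- runif(2, 0, 100)
    kw <- kriging_weights(cfg$locs, cfg$vals, target, vm)
    oracle <- brute_ok(cfg$locs, cfg$vals, target, f, nug, sill, a)
    expect_equal(kw$weights, oracle$weights, tolerance = 1e-8)
    expect_equal(kw$prediction, oracle$prediction, tolerance = 1e-8)
    expect_equal(kw$variance, oracle$variance, tolerance = 1e-8)
    # unbiasedness to machine precision
    expect_lt(abs(sum(kw$weights) - 1), 1e-10)
    expect_gte(kw$variance, 0)
  }
})

test_that("surface prediction is exact at samples and reproduces constants", {
  r <- square_region(40000)  # 11 x 11
  set.seed(55)
  keep <- sort(sample(nrow(r$points), 40))
  sam <- data.frame(x_m = r$points$x_m[keep], y_m = r$points$y_m[keep],
                    thi = rnorm(40, 73, 1.5))
  kr <- predict_grid(sam, vm_test, r, cell_m = 4000)
  g <- kr$grid
  at_sample <- match(paste(sam$x_m, sam$y_m), paste(g$x_m, g$y_m))
  expect_equal(g$pred[at_sample], sam$thi, tolerance = 1e-8)
  expect_equal(g$sigma[at_sample], rep(0, 40))
  expect_true(all(g$sigma >= 0))
  # constant input reproduces the constant everywhere
  sam2 <- sam; sam2$thi <- rep(70, 40)
  kr2 <- predict_grid(sam2, vm_test, r, cell_m = 4000)
  expect_equal(kr2$grid$pred, rep(70, nrow(kr2$grid)), tolerance = 1e-8)
})

test_that("kriging standard error grows away from the samples", {
  r <- make_region("strip", c(0, 100000, 0, 8000), grid_spacing = 4000)
  sam <- data.frame(x_m = c(0, 4000, 8000, 4000),
                    y_m = c(4000, 0, 4000, 8000), thi = c(70, 71, 72, 73))
  vm <- variogram_model("gaussian", 0.1, 1.5, 30000)
  kr <- predict_grid(sam, vm, r, cell_m = 4000)
  g <- kr$grid
  near <- g$sigma[g$x_m == 4000 & g$y_m == 4000]   # surrounded by samples
  far <- g$sigma[g$x_m == 100000 & g$y_m == 4000]  # ~92 km away
  expect_gt(far, near)
})

test_that("local neighborhoods flag isolated cells as no-data", {
  r <- make_region("strip", c(0, 200000, 0, 4000), grid_spacing = 4000)
  sam <- data.frame(x_m = c(0, 4000, 8000), y_m = c(0, 4000, 0),
                    thi = c(70, 71, 72))
  vm <- variogram_model("gaussian", 0.1, 1.5, 30000)
  kr <- predict_grid(sam, vm, r, cell_m = 4000,
                     neighborhood = list(max_n = 8, radius_m = 20000))
  g <- kr$grid
  expect_true(anyNA(g$pred))                       # far cells flagged
  expect_false(anyNA(g$pred[g$x_m <= 8000]))       # near cells predicted
})

test_that("ESRI ASCII output round-trips header and values", {
  r <- square_region(16000)
  sam <- data.frame(x_m = c(0, 16000, 8000), y_m = c(0, 16000, 4000),
                    thi = c(70, 74, 72))
  kr <- predict_grid(sam, vm_test, r, cell_m = 8000)
  path <- tempfile(fileext = ".asc")
  on.exit(unlink(path))
  write_esri_ascii(kr, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ncols 3")
  expect_equal(lines[2], "nrows 3")
  expect_equal(lines[3], "xllcorner -4000")
  expect_equal(lines[5], "cellsize 8000")
  body <- do.call(rbind, lapply(lines[-(1:6)],
                                function(l) scan(text = l, quiet = TRUE)))
  expect_equal(body[3, 1], 70, tolerance = 1e-4)   # bottom row, first col
  expect_equal(body[1, 3], 74, tolerance = 1e-4)   # top row, last col
})
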