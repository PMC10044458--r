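test_that("packaged breed registry has the published structure and bounds", {
  reg <- load_breed_registry()
  expect_equal(nrow(reg), 21)
  expect_equal(sum(reg$cover == "hair"), 7)
  expect_equal(sum(reg$cover == "wool"), 14)
  expect_equal(max(reg$thi_limit), 81.93)
  expect_equal(reg$breed[which.max(reg$thi_limit)], "Rabo Largo")
  expect_equal(min(reg$thi_limit), 71.99)
  expect_equal(reg$breed[which.min(reg$thi_limit)], "Hampshire")
})

test_that("malformed registries are rejected with a line number", {
  p <- tempfile(fileext = ".csv")
  on.exit(unlink(p))
  writeLines(c("breed,cover,thi_limit", "A,hair,80", "A,wool,75"), p)
  expect_error(load_breed_registry(p), "duplicate breed 'A' at line 3")
  writeLines(c("breed,cover,thi_limit", "A,hair,80", "B,wool,notanumber"), p)
  expect_error(load_breed_registry(p), "line 3")
})

test_that("suitable breeds at worked THI values match a registry scan", {
  reg <- load_breed_registry()
  expect_equal(nrow(suitable_breeds(82)), 0)
  expect_equal(nrow(suitable_breeds(66)), 21)
  s75 <- suitable_breeds(75)
  expect_equal(nrow(s75), 9)
  expect_equal(s75$breed[1], "Rabo Largo")
  expect_equal(s75$breed[9], "SAMM")
  # boundary is inclusive
  expect_true("Hampshire" %in% suitable_breeds(71.99)$breed)
  # oracle: brute-force scan across a sweep, plus the nesting property
  prev <- NULL
  for (t in seq(66, 82, by = 0.25)) {
    cur <- suitable_breeds(t)$breed
    expect_equal(sort(cur), sort(reg$breed[reg$thi_limit >= t]))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

make_kr <- function(values, region) {
  sam <- data.frame(x_m = region$points$x_m, y_m = region$points$y_m,
                    thi = values)
  vm <- variogram_model("gaussian", 0.1, 1.5, 30000)
  predict_grid(sam, vm, region, cell_m = region$grid_spacing)
}

test_that("suitability masks follow the inclusive threshold rule", {
  r <- square_region(40000)
  reg <- load_breed_registry()
  kr <- make_kr(rep(70, nrow(r$points)), r)
  sm <- suitability_masks(kr, reg)
  expect_true(all(sm$summary$area_pct == 100))
  kr2 <- make_kr(rep(79, nrow(r$points)), r)
  sm2 <- suitability_masks(kr2, reg)
  expect_equal(sum(sm2$summary$area_pct == 100), 5)
  expect_equal(sum(sm2$summary$area_pct == 0), 16)
  # exact limit is suitable
  kr3 <- make_kr(rep(78.26, nrow(r$points)), r)
  expect_equal(
    suitability_masks(kr3, reg)$summary$area_pct[reg$breed == "Dorper"], 100)
})

test_that("per-subregion usability requires full coverage by default", {
  sub <- list(west = rect_poly(c(0, 20000, 0, 40000)),
              east = rect_poly(c(20000, 40000, 0, 40000)))
  r <- make_region("split", c(0, 40000, 0, 40000), sub)
  vals <- ifelse(r$points$region == "west", 73, 76)
  kr <- make_kr(vals, r)
  reg <- load_breed_registry()
  sm <- suitability_masks(kr, reg)
  suff <- sm$summary[sm$summary$breed == "Suffolk", ]     # limit 74.61
  expect_equal(suff$pct_west, 100)
  expect_equal(suff$pct_east, 0)
  expect_equal(suff$usable_regions, "west")
  rabo <- sm$summary[sm$summary$breed == "Rabo Largo", ]  # limit 81.93
  expect_match(rabo$usable_regions, "west")
  expect_match(rabo$usable_regions, "east")
})

test_that("regional CDFs match a sort-and-count oracle", {
  r <- square_region(40000)
  thi <- rbind(thi_frame(r, seq(70, 73, length.out = nrow(r$points)), 2010),
               thi_frame(r, seq(71, 74, length.out = nrow(r$points)), 2011))
  cd <- regional_cdf(thi, "square", 2010:2011)
  expect_equal(cd$n, 2 * nrow(r$points))
  vals <- thi$thi
  for (t in c(69, 70.5, 72, 74, 80)) {
    expect_equal(cdf_at(cd, t), mean(vals <= t))
    expect_equal(cdf_at(cd, t, inclusive = FALSE), mean(vals < t))
  }
  expect_equal(cdf_at(cd, 69), 0)
  expect_equal(cdf_at(cd, 80), 1)
  # four-point worked example: inclusive gives 0.75 at 72
  r4 <- thi_frame(r, rep(0, nrow(r$points)), 2010)
  r4 <- r4[1:4, ]; r4$thi <- c(70, 71, 72, 73)
  cd4 <- regional_cdf(r4, "square", 2010)
  expect_equal(cdf_at(cd4, 72), 0.75)
  expect_equal(cdf_at(cd4, 72, inclusive = FALSE), 0.5)
  expect_error(regional_cdf(thi, "nowhere", 2010), "unknown region")
  # determinism across identical periods
  expect_equal(cdf_at(regional_cdf(thi, "square", 2010), 72),
               cdf_at(regional_cdf(thi, "square", 2010), 72))
})

test_that("quadrennial defaults split 2010-2021 into three periods", {
  q <- quadrennials()
  expect_equal(names(q), c("2010-2013", "2014-2017", "2018-2021"))
  expect_equal(unname(lengths(q)), c(4L, 4L, 4L))
})
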