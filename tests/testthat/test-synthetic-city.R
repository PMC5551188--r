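test_that("city generation is deterministic and satisfies layer invariants", {
  a <- generate_city(extent_km = 8, seed = 42)
  b <- generate_city(extent_km = 8, seed = 42)
  expect_identical(a, b)

  city <- small_city()
  total <- Reduce(`+`, city$areal)
  for (nm in names(city$areal)) {
    expect_true(all(city$areal[[nm]] >= 0), info = nm)
    expect_true(all(city$areal[[nm]] <= 1), info = nm)
  }
  expect_true(all(total <= 1 + 1e-12))  # exhaustive per-cell scan
  expect_true(all(city$roads$aadt >= 0))
  expect_true(all(city$emitters$nox_tpy >= 0))
  expect_true(all(city$housing >= 0))
  expect_true(all(city$blocks$count >= 0))
})

test_that("invalid generation parameters are rejected", {
  expect_error(generate_city(extent_km = -1), "positive")
  expect_error(generate_city(lulc_cellsize = 0), "positive")
  # prediction grid points must coincide with LULC cell centers
  expect_error(generate_city(lulc_cellsize = 50, grid_cellsize = 200),
               "odd multiple")
})

test_that("zero-source truth is a constant background surface", {
  city <- line_city()
  terms <- default_truth_terms()
  terms$strength[] <- 0
  p <- truth_params(background = 8, seasonal = c(summer = 1, winter = 1.5),
                    terms = terms, noise_sd = 0)
  s <- simulate_no2_truth(city, p, "summer")
  w <- simulate_no2_truth(city, p, "winter")
  expect_true(all(s$values == 8))
  expect_true(all(w$values == 8 * 1.5))
  expect_error(simulate_no2_truth(city, p, "spring"))
})

test_that("single-source truth matches the closed-form kernel at hand-picked distances", {
  city <- line_city(extent = 4000, cellsize = 40, aadt = 120000)
  p <- freeway_only_params(strength = 5, decay = 300, background = 8)
  s <- simulate_no2_truth(city, p, "summer")
  # the freeway runs along x = 2000; aadt equals the reference volume, so
  # truth(x) = background + strength * exp(-|x - 2000| / 300)
  xs <- grid_x_centers(city$grid)
  row <- s$values[10, ]
  for (j in c(3, 7, 16)) {
    d <- abs(xs[j] - 2000)
    expect_equal(row[j], 8 + 5 * exp(-d / 300), tolerance = 1e-12)
  }
})

test_that("default summer and winter surfaces fall in the observed ranges", {
  city <- fixture("full_city", generate_city(seed = 1))
  p <- truth_params()
  s <- fixture("full_truth_s", simulate_no2_truth(city, p, "summer"))
  w <- fixture("full_truth_w", simulate_no2_truth(city, p, "winter"))
  expect_gte(min(s$values), 4)
  expect_lte(max(s$values), 23)
  expect_gte(min(w$values), 3)
  expect_lte(max(w$values), 29)
})

test_that("site observations reproduce the field-campaign structure", {
  city <- fixture("full_city", generate_city(seed = 1))
  p <- truth_params()
  s <- fixture("full_truth_s", simulate_no2_truth(city, p, "summer"))
  w <- fixture("full_truth_w", simulate_no2_truth(city, p, "winter"))

  obs <- sample_sites(city, s, w, seed = 3, params = p)
  expect_equal(nrow(obs), 174 + 82)
  summer_ids <- obs$site_id[obs$season == "summer"]
  winter_ids <- obs$site_id[obs$season == "winter"]
  expect_length(summer_ids, 174)
  expect_length(winter_ids, 82)
  expect_true(all(winter_ids %in% summer_ids))
  expect_true(all(obs$no2_ppb > 0))

  # calibration: seasonal site means near the campaign averages
  expect_equal(mean(obs$no2_ppb[obs$season == "summer"]), 11, tolerance = 2 / 11)
  expect_equal(mean(obs$no2_ppb[obs$season == "winter"]), 13, tolerance = 2 / 13)

  # determinism and the winter <= summer constraint
  expect_identical(obs, sample_sites(city, s, w, seed = 3, params = p))
  expect_error(sample_sites(city, s, w, n_summer = 10, n_winter = 20),
               "n_winter")
})

test_that("zero-noise observations equal the truth at site locations", {
  tr <- small_truth()
  obs <- sample_sites(small_city(), tr$summer, tr$winter, n_summer = 30,
                      n_winter = 10, noise_sd = 0, seed = 5)
  g <- small_city()$grid
  for (ss in c("summer", "winter")) {
    sub <- obs[obs$season == ss, ]
    truth <- if (ss == "summer") tr$summer else tr$winter
    looked <- lurf:::raster_at_points(truth$values, g, sub$x, sub$y)
    expect_equal(sub$no2_ppb, pmax(0.5, looked), tolerance = 1e-12)
  }
})

test_that("each generative term changes the truth only through its own kernel", {
  city <- small_city()
  p <- truth_params()
  s_all <- simulate_no2_truth(city, p, "summer")
  s_no_trees <- simulate_no2_truth(city, drop_truth_term(p, "trees"), "summer")
  # isolate the tree term directly: background-only minus background+trees
  only <- p
  only$terms$strength[only$terms$category != "trees"] <- 0
  s_only <- simulate_no2_truth(city, only, "summer")
  s_bg <- simulate_no2_truth(city, drop_truth_term(only, "trees"), "summer")
  expect_equal(s_all$values - s_no_trees$values,
               s_only$values - s_bg$values, tolerance = 1e-10)
})
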