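test_that("the feature table has the documented shape and column order", {
  f <- small_features()
  cats <- lulc_categories()$all
  expected <- c("location_id", "x", "y", "elevation",
                unlist(lapply(cats, feature_column, radius = default_radii())))
  expect_identical(colnames(f)[seq_along(expected)], expected)
  # 16 categories x 12 radii + x, y, elevation = 195 predictors
  expect_equal(length(expected) - 1, 195)
  expect_true(all(as.matrix(f[, -(1:4)]) >= 0))
})

test_that("buffer features are non-decreasing in radius for every category", {
  f <- small_features()
  for (ct in lulc_categories()$all) {
    m <- as.matrix(f[, feature_column(ct, default_radii())])
    expect_true(all(t(apply(m, 1, diff)) >= -1e-9), info = ct)
  }
})

test_that("areal features agree with a brute-force cell-center scan", {
  city <- small_city()
  lg <- city$lulc_grid
  set.seed(31)
  n <- 22
  locs <- data.frame(x = runif(n, 500, 7500), y = runif(n, 500, 7500))
  f <- extract_features(locs, city, radii = c(150, 400, 900),
                        categories = c("trees", "dev_med"))
  xs <- grid_x_centers(lg); ys <- grid_y_centers(lg)
  for (ct in c("trees", "dev_med")) {
    mat <- city$areal[[ct]]
    for (r in c(150, 400, 900)) {
      brute <- vapply(seq_len(n), function(i) {
        tot <- 0
        for (iy in seq_along(ys)) for (ix in seq_along(xs)) {
          if ((xs[ix] - locs$x[i])^2 + (ys[iy] - locs$y[i])^2 <= r^2)
            tot <- tot + mat[iy, ix]
        }
        tot * lg$cellsize^2
      }, numeric(1))
      got <- f[[feature_column(ct, r)]]
      expect_equal(got, brute, tolerance = 1e-9)
    }
  }
})

test_that("freeway VMT equals AADT times the chord length inside the buffer", {
  city <- line_city(extent = 4000, aadt = 10000)
  loc <- data.frame(x = 1800, y = 2000)
  f <- extract_features(loc, city, radii = 500,
                        categories = c("freeway", "vmt_freeway"))
  # vertical freeway at x = 2000, site 200 m away: chord = 2*sqrt(r^2-d^2)
  chord <- 2 * sqrt(500^2 - 200^2)
  expect_equal(f$freeway_r0500, chord, tolerance = 1e-9)
  expect_equal(f$vmt_freeway_r0500, 10000 * chord / 1609.344,
               tolerance = 1e-9)
  # densified oracle: cut the line into 1 m pieces and sum those inside
  yy <- seq(0.5, 3999.5, by = 1)
  inside <- (2000 - 1800)^2 + (yy - 2000)^2 <= 500^2
  expect_equal(f$freeway_r0500, sum(inside), tolerance = 2 / chord)
})

test_that("a location with no road within reach has all-zero road features", {
  city <- line_city(extent = 8000)
  # freeway at x = 4000; location at x = 500 is 3.5 km away
  f <- extract_features(data.frame(x = 500, y = 4000), city)
  road_cols <- unlist(lapply(c("freeway", "road_primary", "road_secondary",
                               "road_local", "rail", "vmt_freeway"),
                             feature_column, radius = default_radii()))
  expect_true(all(f[, road_cols] == 0))
})

test_that("trees can be assembled from separate forest-type layers", {
  city <- small_city()
  split_city <- city
  tr <- city$areal$trees
  split_city$areal$trees <- NULL
  split_city$areal$deciduous <- tr * 0.5
  split_city$areal$evergreen <- tr * 0.3
  split_city$areal$mixed <- tr * 0.2
  loc <- data.frame(x = c(2000, 5000), y = c(3000, 6000))
  a <- extract_features(loc, city, radii = 300, categories = "trees")
  b <- extract_features(loc, split_city, radii = 300, categories = "trees")
  expect_equal(a$trees_r0300, b$trees_r0300, tolerance = 1e-12)
})

test_that("invalid extraction inputs are rejected", {
  city <- small_city()
  expect_error(extract_features(data.frame(x = -10, y = 100), city),
               "outside")
  expect_error(extract_features(data.frame(x = 100, y = 100), city,
                                radii = c(-5)), "positive")
})

test_that("train/validation splits reproduce the campaign hold-outs", {
  tab <- data.frame(i = 1:174)
  sp <- split_train_validation(tab, seed = 4, n_validation = 42)
  expect_equal(nrow(sp$validation), 42)
  expect_equal(nrow(sp$train), 132)
  expect_setequal(c(sp$train$i, sp$validation$i), 1:174)

  sp2 <- split_train_validation(data.frame(i = 1:82), seed = 4,
                                n_validation = 20)
  expect_equal(nrow(sp2$validation), 20)
  expect_equal(nrow(sp2$train), 62)

  a <- split_train_validation(data.frame(i = 1:100), fraction = 0.25, seed = 9)
  b <- split_train_validation(data.frame(i = 1:100), fraction = 0.25, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a$validation), 25)

  expect_error(split_train_validation(data.frame(i = 1:5)), "at least 8")
  expect_error(split_train_validation(tab, fraction = 1.2), "fraction")
})
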