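# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small 8 x 8 km city: full layout at 40% scale, quick to extract from
small_city <- function() fixture("small_city", generate_city(extent_km = 8, seed = 42))

small_truth <- function() fixture("small_truth", {
  city <- small_city()
  p <- truth_params()
  list(params = p,
       summer = simulate_no2_truth(city, p, "summer"),
       winter = simulate_no2_truth(city, p, "winter"))
})

small_sites <- function() fixture("small_sites", {
  tr <- small_truth()
  sample_sites(small_city(), tr$summer, tr$winter, n_summer = 60,
               n_winter = 30, noise_sd = tr$params$noise_sd, seed = 7,
               params = tr$params)
})

small_features <- function() fixture("small_features", {
  s <- small_sites()
  ss <- s[s$season == "summer", ]
  f <- extract_features(
    data.frame(location_id = ss$site_id, x = ss$x, y = ss$y), small_city())
  f$no2_ppb <- ss$no2_ppb
  f
})

small_sel <- function() fixture("small_sel", {
  f <- small_features()
  fc <- setdiff(colnames(f), c("location_id", "no2_ppb"))
  phase1_select_buffers(f[, fc], f$no2_ppb, ntree = 150, seed = 3)
})

small_lurf <- function() fixture("small_lurf", {
  f <- small_features()
  fit_forest(f[, selected_columns(small_sel())], f$no2_ppb,
             ntree = 80, mtry = 5, seed = 1)
})

small_gf <- function() fixture("small_gf", {
  city <- small_city()
  extract_selected_features(lurf:::grid_points(city$grid), city, small_sel())
})

# a minimal hand-built city: one vertical freeway, nothing else, flat
# elevation; used for closed-form kernel and chord-geometry checks
line_city <- function(extent = 4000, cellsize = 40, aadt = 120000) {
  lg <- city_grid(0, 0, cellsize, extent / cellsize, extent / cellsize)
  pg <- city_grid(0, 0, 200, extent / 200, extent / 200)
  zero <- matrix(0, lg$ny, lg$nx)
  areal <- list(dev_high = zero, dev_low = zero, dev_med = zero,
                dev_open = zero, grassland = zero, pasture = zero,
                shrub = zero, trees = zero)
  structure(list(
    lulc_grid = lg, grid = pg, extent = grid_extent(lg),
    areal = areal,
    roads = data.frame(x0 = extent / 2, y0 = 0, x1 = extent / 2, y1 = extent,
                       class = "freeway", aadt = aadt),
    rail = data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0)),
    emitters = data.frame(x = numeric(0), y = numeric(0),
                          nox_tpy = numeric(0)),
    housing = zero, elevation = zero + 50,
    blocks = data.frame(block_id = "B1", xmin = 0, xmax = extent,
                        ymin = 0, ymax = extent, count = 1000),
    age_fractions = c(age_4_12 = 0.11), crs = "local planar meters",
    seed = 0), class = "city_dataset")
}

# truth params with a single freeway source term
freeway_only_params <- function(strength = 5, decay = 300, background = 8) {
  terms <- default_truth_terms()
  terms$strength[] <- 0
  terms$strength[terms$category == "freeway"] <- strength
  terms$decay[terms$category == "freeway"] <- decay
  truth_params(background = background, seasonal = c(summer = 1, winter = 1),
               noise_sd = 0, terms = terms)
}

# an additive "model" with known coefficients: predict = intercept +
# sum(coef * column); exact oracle for attribution additivity
toy_additive_model <- function(coefs, intercept = 10) {
  structure(list(coefs = coefs, intercept = intercept),
            class = "toy_additive_model")
}

predict.toy_additive_model <- function(object, newdata, ...) {
  out <- rep(object$intercept, nrow(newdata))
  for (nm in names(object$coefs)) out <- out + object$coefs[[nm]] * newdata[[nm]]
  out
}

# register the S3 method for the helper class inside the test session
registerS3method("predict", "toy_additive_model", predict.toy_additive_model)
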