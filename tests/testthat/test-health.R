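test_that("a polygon covering whole cells splits its count evenly", {
  g <- city_grid(0, 0, 100, 4, 4)
  blocks <- data.frame(block_id = "B1", xmin = 0, xmax = 200, ymin = 0,
                       ymax = 200, count = 400)
  pop <- allocate_population(blocks, g)
  expect_equal(pop$values[1:2, 1:2], matrix(100, 2, 2))
  expect_equal(sum(pop$values), 400, tolerance = 1e-9)
})

test_that("population allocation conserves totals and weights partial overlaps", {
  g <- city_grid(0, 0, 100, 6, 6)
  set.seed(13)
  blocks <- data.frame(
    block_id = sprintf("B%d", 1:5),
    xmin = c(0, 150, 320, 50, 400), xmax = c(150, 320, 600, 250, 580),
    ymin = c(0, 100, 0, 350, 380), ymax = c(120, 260, 180, 560, 600),
    count = c(120, 300, 80, 240, 60))
  pop <- allocate_population(blocks, g)
  expect_equal(sum(pop$values), sum(blocks$count), tolerance = 1e-6 * sum(blocks$count))

  # partial overlaps: check one cell against a fine-raster brute force
  cellsum <- function(b, ix, iy, step = 0.5) {
    xs <- seq((ix - 1) * 100 + step / 2, ix * 100, by = step)
    ys <- seq((iy - 1) * 100 + step / 2, iy * 100, by = step)
    inside <- outer(ys, xs, function(yy, xx)
      xx >= b$xmin & xx <= b$xmax & yy >= b$ymin & yy <= b$ymax)
    barea <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
    b$count * sum(inside) * step^2 / barea
  }
  contrib <- sum(vapply(1:5, function(i) cellsum(blocks[i, ], 2, 2),
                        numeric(1)))
  expect_equal(pop$values[2, 2], contrib, tolerance = 0.02 * max(1, contrib))

  expect_error(allocate_population(
    data.frame(xmin = 0, xmax = 1, ymin = 0, ymax = 1, count = -5), g),
    "negative")
})

test_that("arbitrary polygons are clipped correctly (triangle vs fine raster)", {
  g <- city_grid(0, 0, 100, 4, 4)
  tri <- list(list(id = "T1", x = c(50, 350, 50), y = c(50, 50, 350),
                   count = 900))
  pop <- allocate_population(tri, g)
  expect_equal(sum(pop$values), 900, tolerance = 1e-6 * 900)
  step <- 0.5
  xs <- seq(step / 2, 400, by = step); ys <- seq(step / 2, 400, by = step)
  for (cell in list(c(1, 1), c(2, 2), c(1, 3))) {
    ix <- cell[1]; iy <- cell[2]
    xr <- xs[xs > (ix - 1) * 100 & xs < ix * 100]
    yr <- ys[ys > (iy - 1) * 100 & ys < iy * 100]
    # inside the triangle x>=50, y>=50, x+y <= 400
    inside <- outer(yr, xr, function(yy, xx)
      xx >= 50 & yy >= 50 & (xx + yy) <= 400)
    brute <- 900 * sum(inside) * step^2 / (0.5 * 300 * 300)
    expect_equal(pop$values[iy, ix], brute, tolerance = 0.02 * max(1, brute))
  }
})

test_that("the log-linear impact function matches its closed form", {
  g <- city_grid(0, 0, 200, 2, 2)
  hif <- health_impact_function("asthma_exacerbation", "age_4_12",
                                beta = 0.01, baseline_incidence = 0.1)
  dC <- grid_surface(matrix(1, 2, 2), g)
  pop <- grid_surface(matrix(c(1000, 0, 0, 0), 2, 2), g)
  res <- apply_hif(hif, dC, pop)
  expect_equal(res$total_delta_cases, 0.1 * (1 - exp(-0.01)) * 1000,
               tolerance = 1e-9)
  # zero change -> zero impact
  res0 <- apply_hif(hif, grid_surface(matrix(0, 2, 2), g), pop)
  expect_equal(res0$total_delta_cases, 0)
  expect_true(all(res0$cell_delta$values == 0))
  # zero population -> zero impact regardless of dC
  expect_true(all(res$cell_delta$values[pop$values == 0] == 0))
})

test_that("small signals are first-order linear and signs follow beta * dC", {
  g <- city_grid(0, 0, 200, 3, 3)
  hif <- health_impact_function("cough", "age_7_14", beta = 0.005,
                                baseline_incidence = 0.2)
  set.seed(15)
  dC <- grid_surface(matrix(runif(9, -2e-4, 2e-4), 3, 3), g)
  pop <- grid_surface(matrix(runif(9, 100, 1000), 3, 3), g)
  res <- apply_hif(hif, dC, pop)
  lin <- 0.2 * hif$beta * dC$values * pop$values
  expect_equal(res$cell_delta$values, lin, tolerance = 1e-3)
  expect_true(all(sign(res$cell_delta$values) == sign(dC$values * hif$beta)))
  # monotonicity: larger |dC| gives larger |dy|
  d2 <- grid_surface(dC$values * 2, g)
  r2 <- apply_hif(hif, d2, pop)
  expect_true(all(abs(r2$cell_delta$values) >= abs(res$cell_delta$values)))
  # rate arithmetic recomputed independently
  expect_equal(res$rate_per_100k,
               1e5 * sum(res$cell_delta$values) / sum(pop$values),
               tolerance = 1e-12)
  expect_error(apply_hif(hif, dC, grid_surface(matrix(1, 2, 2),
                                               city_grid(0, 0, 200, 2, 2))),
               "geometry")
})

test_that("the worst-quintile mask selects the top fifth of cells", {
  g <- city_grid(0, 0, 100, 10, 10)
  vals <- matrix(sample(1:100), 10, 10)
  s <- grid_surface(vals, g)
  m <- worst_quintile_mask(s)
  expect_equal(sum(m), 20)
  expect_gte(min(vals[m]), max(vals[!m]))

  const <- grid_surface(matrix(5, 10, 10), g)
  expect_warning(mc <- worst_quintile_mask(const), "constant")
  expect_true(all(mc))
  expect_error(worst_quintile_mask(grid_surface(matrix(1:4, 2, 2),
                                                city_grid(0, 0, 100, 2, 2))),
               "at least 5")
})

test_that("city population rasters conserve the block totals by age band", {
  city <- small_city()
  pop <- city_population(city)
  expect_equal(sum(pop$total$values), sum(city$blocks$count),
               tolerance = 1e-6 * sum(city$blocks$count))
  for (band in names(city$age_fractions)) {
    expect_equal(sum(pop[[band]]$values),
                 city$age_fractions[[band]] * sum(pop$total$values),
                 tolerance = 1e-9 * sum(pop$total$values))
  }
})
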