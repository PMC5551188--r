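# build a compact feature table with known structure for selection tests:
# three buffered categories (one all-zero) plus the point features
toy_selection_table <- function(n = 60, seed = 2) {
  set.seed(seed)
  radii <- default_radii()
  tab <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                    elevation = runif(n, 0, 100))
  base_a <- runif(n); base_b <- runif(n)
  for (r in radii) {
    # sibling radii share a base signal plus a radius-specific component
    tab[[feature_column("alpha", r)]] <- base_a * r + runif(n, 0, r / 3)
    tab[[feature_column("beta", r)]] <- base_b * r + runif(n, 0, r / 3)
    tab[[feature_column("gamma", r)]] <- 0
  }
  # the response is driven by the 500 m alpha buffer specifically
  y <- 5 + 10 * tab[[feature_column("alpha", 500)]] / 500 + rnorm(n, 0, 0.3)
  list(table = tab, response = y)
}

test_that("phase 1 returns one radius per category and flags degenerate ones", {
  toy <- toy_selection_table()
  sel <- phase1_select_buffers(toy$table, toy$response,
                               categories = c("alpha", "beta", "gamma"),
                               ntree = 80, seed = 1)
  expect_s3_class(sel, "selected_variables")
  expect_equal(nrow(sel$buffers), 3)
  expect_equal(sel$buffers$category, c("alpha", "beta", "gamma"))
  expect_true(all(sel$buffers$radius %in% default_radii()))
  # the all-zero category gets the smallest radius and a degenerate flag
  g <- sel$buffers[sel$buffers$category == "gamma", ]
  expect_true(g$degenerate)
  expect_equal(g$radius, 100)
  expect_false(any(sel$buffers$degenerate[sel$buffers$category != "gamma"]))
  # selected column names: 3 categories + 3 point features
  expect_length(selected_columns(sel), 6)
  expect_identical(selected_columns(sel)[1:3], c("x", "y", "elevation"))
})

test_that("phase 1 on the full synthetic table reduces ~200 predictors to ~20", {
  f <- small_features()
  fc <- setdiff(colnames(f), c("location_id", "no2_ppb"))
  sel <- phase1_select_buffers(f[, fc], f$no2_ppb, ntree = 150, seed = 3)
  expect_equal(nrow(sel$buffers), 16)
  expect_length(selected_columns(sel), 19)
  imp <- attr(sel, "importance")
  expect_equal(nrow(imp), 195)
})

test_that("phase 2 selects the arg-min of the persisted mean-OOB-RMSE table", {
  toy <- toy_selection_table(n = 50, seed = 5)
  sel <- phase1_select_buffers(toy$table, toy$response,
                               categories = c("alpha", "beta", "gamma"),
                               ntree = 60, seed = 1)
  sw <- phase2_sweep(toy$table, toy$response, sel,
                     ntree_grid = c(30, 60), mtry_grid = c(1, 3),
                     seeds = 1:2)
  expect_equal(nrow(sw$sweep), 2 * 2 * 2)
  # recompute the arg-min by hand from the persisted sweep table
  agg <- aggregate(oob_rmse ~ ntree + mtry, data = sw$sweep, FUN = mean)
  best <- agg[order(agg$oob_rmse, agg$ntree, agg$mtry)[1], ]
  expect_equal(sw$ntree, best$ntree)
  expect_equal(sw$mtry, best$mtry)
  expect_equal(sw$model$ntree, best$ntree)

  # determinism: identical seeds and grids give identical selections
  sw2 <- phase2_sweep(toy$table, toy$response, sel,
                      ntree_grid = c(30, 60), mtry_grid = c(1, 3),
                      seeds = 1:2)
  expect_identical(sw$summary, sw2$summary)
  expect_identical(c(sw$ntree, sw$mtry), c(sw2$ntree, sw2$mtry))

  expect_error(phase2_sweep(toy$table, toy$response, sel,
                            ntree_grid = numeric(0), mtry_grid = 1),
               "empty")
})

test_that("the classic study grid enumerates 48 combinations per seed", {
  grid <- classic_sweep_grid()
  expect_length(grid$ntree, 6)
  expect_length(grid$mtry, 8)
  set.seed(14)
  n <- 30
  tab <- data.frame(x = runif(n), y = runif(n), elevation = runif(n))
  for (r in c(100, 200)) {
    tab[[feature_column("alpha", r)]] <- runif(n) * r
    tab[[feature_column("beta", r)]] <- runif(n) * r
  }
  yresp <- 2 * tab$alpha_r0100 + rnorm(n, 0, 0.1)
  sel <- phase1_select_buffers(tab, yresp, radii = c(100, 200),
                               categories = c("alpha", "beta"),
                               ntree = 40, seed = 1)
  # p = 5 predictors, so the mtry grid truncates to 1..5
  sw <- phase2_sweep(tab, yresp, sel, ntree_grid = grid$ntree,
                     mtry_grid = grid$mtry, seeds = 1)
  expect_equal(nrow(sw$sweep), 6 * 5)
  expect_true(all(sort(unique(sw$sweep$ntree)) == grid$ntree))
})

test_that("an added independent noise column rarely changes phase-1 choices", {
  toy <- toy_selection_table(n = 60, seed = 6)
  changed <- vapply(1:10, function(s) {
    sel0 <- phase1_select_buffers(toy$table, toy$response,
                                  categories = c("alpha", "beta", "gamma"),
                                  ntree = 80, seed = s)
    tab2 <- toy$table
    set.seed(1000 + s)
    nz <- runif(nrow(tab2))
    for (r in default_radii())
      tab2[[feature_column("noise", r)]] <- nz * r + runif(nrow(tab2), 0, r / 10)
    sel1 <- phase1_select_buffers(tab2, toy$response,
                                  categories = c("alpha", "beta", "gamma",
                                                 "noise"),
                                  ntree = 80, seed = s)
    r0 <- sel0$buffers$radius[sel0$buffers$category == "alpha"]
    r1 <- sel1$buffers$radius[sel1$buffers$category == "alpha"]
    r0 != r1
  }, logical(1))
  expect_lte(mean(changed), 0.2)
})
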