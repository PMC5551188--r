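# feature table for a handful of synthetic locations with known percent
# cover; areal values stored in m^2 of buffer area (pi r^2)
pct_table <- function(radius = 400, trees = 20, dev_med = 60, dev_open = 20) {
  area <- pi * radius^2
  tab <- data.frame(location_id = sprintf("L%d", seq_along(trees)),
                    x = 0, y = 0, elevation = 0)
  tab[[feature_column("trees", radius)]] <- trees / 100 * area
  tab[[feature_column("dev_med", radius)]] <- dev_med / 100 * area
  tab[[feature_column("dev_open", radius)]] <- dev_open / 100 * area
  tab
}

pct_of <- function(tab, category, radius = 400) {
  100 * tab[[feature_column(category, radius)]] / (pi * radius^2)
}

test_that("zeroing a category clears its columns and nothing else", {
  f <- small_gf()
  z <- zero_category(f, "trees")
  info <- lurf:::feature_table_columns(f)
  tcols <- info$column[info$category == "trees"]
  expect_true(all(z[, tcols] == 0))
  other <- setdiff(colnames(f), tcols)
  expect_identical(z[, other], f[, other])
  # idempotent, and a no-op on an already-zero category
  expect_identical(zero_category(z, "trees"), z)
  expect_error(zero_category(f, "nonexistent"), "no columns")
})

test_that("tree-canopy modification reproduces the worked percentage examples", {
  # 20% cover: +2/+5/+10 percentage points -> 22/25/30%
  for (d in c(2, 5, 10)) {
    out <- apply_modification(pct_table(trees = 20), scenario("trees", "modify", d))
    expect_equal(pct_of(out, "trees"), 20 + d, tolerance = 1e-12)
  }
  # 0% cover: +2/+5/+10 -> 2/5/10% (an increase even where there were none)
  for (d in c(2, 5, 10)) {
    out <- apply_modification(pct_table(trees = 0), scenario("trees", "modify", d))
    expect_equal(pct_of(out, "trees"), d, tolerance = 1e-12)
  }
})

test_that("proportional rebalancing preserves the areal total", {
  out <- apply_modification(pct_table(trees = 20, dev_med = 60, dev_open = 20),
                            scenario("trees", "modify", 5))
  expect_equal(pct_of(out, "trees"), 25, tolerance = 1e-12)
  expect_equal(pct_of(out, "dev_med"), 56.25, tolerance = 1e-12)
  expect_equal(pct_of(out, "dev_open"), 18.75, tolerance = 1e-12)
  tot <- pct_of(out, "trees") + pct_of(out, "dev_med") + pct_of(out, "dev_open")
  expect_equal(tot, 100, tolerance = 1e-12)

  # a decrease scales the others up
  dn <- apply_modification(pct_table(trees = 20, dev_med = 40, dev_open = 20),
                           scenario("trees", "modify", -10))
  expect_equal(pct_of(dn, "trees"), 10, tolerance = 1e-12)
  expect_equal(pct_of(dn, "dev_med") + pct_of(dn, "dev_open"), 70,
               tolerance = 1e-12)
})

test_that("modification clamps to [0, 100] and warns on an empty pool", {
  out <- apply_modification(pct_table(trees = 95, dev_med = 5, dev_open = 0),
                            scenario("trees", "modify", 10))
  expect_equal(pct_of(out, "trees"), 100, tolerance = 1e-12)
  expect_warning(
    apply_modification(pct_table(trees = 0, dev_med = 0, dev_open = 0),
                       scenario("trees", "modify", 10)),
    "pool")
  dn <- apply_modification(pct_table(trees = 5, dev_med = 10, dev_open = 0),
                           scenario("trees", "modify", -10))
  expect_equal(pct_of(dn, "trees"), 0, tolerance = 1e-12)
})

test_that("post-modification fractions stay within bounds on the real grid", {
  f <- small_gf()
  for (d in c(-10, 10)) {
    out <- suppressWarnings(
      apply_modification(f, scenario("trees", "modify", d)))
    info <- lurf:::feature_table_columns(out)
    areal <- info[info$category %in% lulc_categories()$areal, ]
    pct <- mapply(function(cc, r) 100 * out[[cc]] / (pi * r^2),
                  areal$column, areal$radius)
    expect_true(all(pct >= -1e-9 & pct <= 100 + 1e-9))
    # per-buffer totals (categories sharing a radius) stay at or below 100
    for (r in unique(areal$radius)) {
      cols <- areal$column[areal$radius == r]
      if (length(cols) > 1) {
        tot <- rowSums(as.matrix(out[, cols])) / (pi * r^2) * 100
        expect_true(all(tot <= 100 + 1e-6))
      }
    }
  }
})

test_that("VMT scenarios scale traffic multiplicatively without rebalancing", {
  f <- small_gf()
  out <- apply_modification(f, scenario("vmt_freeway", "modify", -10))
  info <- lurf:::feature_table_columns(f)
  vcols <- info$column[info$category == "vmt_freeway"]
  for (cc in vcols) expect_equal(out[[cc]], f[[cc]] * 0.9, tolerance = 1e-12)
  other <- setdiff(colnames(f), vcols)
  expect_identical(out[, other], f[, other])
})

test_that("driving a category to zero without rebalancing equals zero_category", {
  tab <- pct_table(trees = 37, dev_med = 40, dev_open = 10)
  a <- apply_modification(tab, scenario("trees", "modify", -100),
                          rebalance = FALSE)
  b <- zero_category(tab, "trees")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("attribution on an additive model is exactly additive", {
  city <- small_city()
  sel <- small_sel()
  gf <- small_gf()
  cols <- selected_columns(sel)
  coefs <- stats::setNames(rep(0, length(cols)), cols)
  tcol <- sel$buffers$column[sel$buffers$category == "trees"]
  dcol <- sel$buffers$column[sel$buffers$category == "dev_high"]
  coefs[tcol] <- -1e-6
  coefs[dcol] <- 2e-6
  mdl <- toy_additive_model(as.list(coefs), intercept = 10)

  at <- attribute_category(mdl, mdl, city, sel, "trees", gf)
  ad <- attribute_category(mdl, mdl, city, sel, "dev_high", gf)
  both <- attribute_category(mdl, mdl, city, sel, c("trees", "dev_high"), gf)
  expect_equal(both$delta$values, at$delta$values + ad$delta$values,
               tolerance = 1e-9)
  # for the additive oracle, attribution equals coefficient times feature
  expect_equal(at$mean, -1e-6 * mean(gf[[tcol]]), tolerance = 1e-9)
  # zero-presence category -> identically zero surface
  zero_cat <- sel$buffers$category[which(vapply(
    sel$buffers$column, function(cc) all(gf[[cc]] == 0), logical(1)))]
  a0 <- attribute_category(mdl, mdl, city, sel, "rail", gf)
  if (all(gf[[sel$buffers$column[sel$buffers$category == "rail"]]] == 0)) {
    expect_true(all(a0$delta$values == 0))
  } else {
    expect_true(all(abs(a0$delta$values) < 1e-12))  # rail coefficient is 0
  }
})

test_that("opposite tree scenarios produce opposite responses for a linear model", {
  city <- small_city()
  sel <- small_sel()
  gf <- small_gf()
  cols <- selected_columns(sel)
  coefs <- stats::setNames(as.list(rep(0, length(cols))), cols)
  tcol <- sel$buffers$column[sel$buffers$category == "trees"]
  coefs[[tcol]] <- -1e-6
  mdl <- toy_additive_model(coefs, intercept = 12)
  sens <- suppressWarnings(
    run_sensitivity(mdl, mdl, city, sel,
                    list(scenario("trees", "modify", 5),
                         scenario("trees", "modify", -5)), gf))
  expect_equal(nrow(sens$table), 2)
  up <- sens$surfaces[["trees+5"]]$values
  dn <- sens$surfaces[["trees-5"]]$values
  live <- abs(up) > 1e-9 | abs(dn) > 1e-9
  agree <- sign(up[live]) == -sign(dn[live])
  expect_gte(mean(agree), 0.9)

  empty <- run_sensitivity(mdl, mdl, city, sel, list(), gf)
  expect_equal(nrow(empty$table), 0)
})
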