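# End-to-end pipeline ----------------------------------------------------------

#' Default pipeline configuration
#'
#' A desk-scale configuration: a 20 x 20 km synthetic city on 40 m LULC
#' cells and a 200 m prediction grid, 174 summer / 82 winter sites,
#' twelve 100-1200 m buffers, a 25% hold-out (42 summer / 20 winter
#' records), a reduced phase-2 sweep grid, and the default scenario and
#' health-impact registries. One global seed drives every stage through
#' fixed offsets.
#'
#' @param seed global integer seed
#' @return configuration list (YAML-serializable)
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    city = list(extent_km = 20, lulc_cellsize = 40, grid_cellsize = 200,
                total_population = 320000),
    sites = list(n_summer = 174, n_winter = 82),
    radii = as.integer(default_radii()),
    split = list(fraction = 0.25),
    forest = list(phase1_ntree = 300, cor_threshold = 0.2,
                  ntree_grid = c(200, 500), mtry_grid = c(2, 4, 6),
                  n_sweep_seeds = 2, final_ntree = NULL),
    lur = list(vif_ceiling = 10, k = 6, cor_threshold = 0.7),
    attribution = list(categories = c(
      "dev_high", "vmt_freeway", "freeway", "road_primary", "road_secondary",
      "road_local", "rail", "housing", "emissions", "dev_open", "trees",
      "shrub")),
    scenarios = lapply(default_scenarios(), unclass),
    health = list(endpoint_band = "age_4_12")
  )
}

stage_seed <- function(seed, stage) {
  offsets <- c(generate = 11L, sites = 23L, split = 37L, phase1 = 41L,
               sweep = 53L, lur = 67L, importance = 71L)
  seed + unname(offsets[stage])
}

#' Run the full analysis pipeline
#'
#' Executes generate, extract, split, fit (LURF and LUR), evaluate,
#' predict, attribute, sensitivity and health stages on a synthetic city,
#' writing every artifact plus a manifest (stage list, seeds, file
#' checksums) to `out_dir`. Re-running with the same configuration
#' reproduces the same artifacts.
#'
#' @param config a [default_pipeline_config()]-style list
#' @param out_dir output directory (created if missing)
#' @param quiet suppress progress messages
#' @return invisible list of in-memory results (`city`, `models`,
#'   `metrics`, `surfaces`, `attribution`, `sensitivity`, `health`,
#'   `manifest`)
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- character(0)
  files <- character(0)
  keep <- function(f) { files[[length(files) + 1L]] <<- f; f }
  seed <- config$seed

  # 1. generate ---------------------------------------------------------
  say("[generate] synthetic city")
  params <- truth_params()
  city <- generate_city(extent_km = config$city$extent_km,
                        lulc_cellsize = config$city$lulc_cellsize,
                        grid_cellsize = config$city$grid_cellsize,
                        seed = stage_seed(seed, "generate"),
                        total_population = config$city$total_population)
  truth_s <- simulate_no2_truth(city, params, "summer")
  truth_w <- simulate_no2_truth(city, params, "winter")
  sites <- sample_sites(city, truth_s, truth_w,
                        n_summer = config$sites$n_summer,
                        n_winter = config$sites$n_winter,
                        noise_sd = params$noise_sd,
                        seed = stage_seed(seed, "sites"))
  write_table_csv(sites, keep(file.path(out_dir, "sites.csv")))
  write_surface_asc(truth_s, keep(file.path(out_dir, "truth_summer.asc")))
  write_surface_asc(truth_w, keep(file.path(out_dir, "truth_winter.asc")))
  write_network_geojson(city$roads, keep(file.path(out_dir, "roads.geojson")))
  write_points_geojson(city$emitters,
                       keep(file.path(out_dir, "emitters.geojson")))
  stages <- c(stages, "generate")

  # 2. extract ----------------------------------------------------------
  say("[extract] buffer features at %d site records", nrow(sites))
  season_tables <- lapply(c("summer", "winter"), function(ss) {
    sub <- sites[sites$season == ss, ]
    f <- extract_features(
      data.frame(location_id = sub$site_id, x = sub$x, y = sub$y),
      city, radii = config$radii)
    f$no2_ppb <- sub$no2_ppb
    f
  })
  names(season_tables) <- c("summer", "winter")
  write_table_csv(season_tables$summer,
                  keep(file.path(out_dir, "features_summer.csv")))
  write_table_csv(season_tables$winter,
                  keep(file.path(out_dir, "features_winter.csv")))
  stages <- c(stages, "extract")

  # 3. split ------------------------------------------------------------
  splits <- lapply(season_tables, split_train_validation,
                   fraction = config$split$fraction,
                   seed = stage_seed(seed, "split"))
  stages <- c(stages, "split")

  # 4. fit: two-phase LURF + LUR baseline -------------------------------
  feature_cols <- function(d) setdiff(colnames(d), c("location_id", "no2_ppb"))
  models <- list()
  for (ss in c("summer", "winter")) {
    say("[fit] %s LURF (phase 1 + sweep) and LUR", ss)
    tr <- splits[[ss]]$train
    sel <- phase1_select_buffers(
      tr[, feature_cols(tr)], tr$no2_ppb, radii = config$radii,
      ntree = config$forest$phase1_ntree,
      seed = stage_seed(seed, "phase1"),
      cor_threshold = config$forest$cor_threshold)
    sw <- phase2_sweep(
      tr, tr$no2_ppb, sel,
      ntree_grid = config$forest$ntree_grid,
      mtry_grid = config$forest$mtry_grid,
      seeds = stage_seed(seed, "sweep") + seq_len(config$forest$n_sweep_seeds))
    lur <- fit_lur(tr, tr$no2_ppb, sel,
                   vif_ceiling = config$lur$vif_ceiling, k = config$lur$k,
                   cor_threshold = config$lur$cor_threshold,
                   seed = stage_seed(seed, "lur"))
    models[[ss]] <- list(selected = sel, lurf = sw$model, sweep = sw,
                         lur = lur)
    write_table_csv(sw$sweep,
                    keep(file.path(out_dir, paste0("sweep_", ss, ".csv"))))
    write_table_csv(attr(sel, "importance"),
                    keep(file.path(out_dir, paste0("importance_", ss, ".csv"))))
    write_forest_json(sw$model,
                      keep(file.path(out_dir, paste0("lurf_", ss, ".json"))))
  }
  stages <- c(stages, "fit")

  # 5. evaluate ---------------------------------------------------------
  metrics <- do.call(rbind, lapply(c("summer", "winter"), function(ss) {
    va <- splits[[ss]]$validation
    rbind(
      cbind(season = ss, model = "LURF",
            compute_metrics(predict(models[[ss]]$lurf, va), va$no2_ppb)),
      cbind(season = ss, model = "LUR",
            compute_metrics(predict(models[[ss]]$lur, va), va$no2_ppb)))
  }))
  write_table_csv(metrics, keep(file.path(out_dir, "metrics.csv")))
  stages <- c(stages, "evaluate")

  # 6. predict ----------------------------------------------------------
  say("[predict] 200 m surfaces")
  gf <- list(
    summer = extract_selected_features(grid_points(city$grid), city,
                                       models$summer$selected),
    winter = extract_selected_features(grid_points(city$grid), city,
                                       models$winter$selected))
  surf <- list(
    summer = predict_grid(models$summer$lurf, city, models$summer$selected,
                          gf$summer),
    winter = predict_grid(models$winter$lurf, city, models$winter$selected,
                          gf$winter))
  surf$annual <- annual_average(surf$summer, surf$winter)
  for (nm in names(surf))
    write_surface_asc(surf[[nm]],
                      keep(file.path(out_dir, paste0("no2_", nm, ".asc"))))
  lur_annual <- annual_average(
    predict_grid(models$summer$lur, city, models$summer$selected, gf$summer),
    predict_grid(models$winter$lur, city, models$winter$selected, gf$winter))
  comparison <- compare_surfaces(surf$annual, lur_annual)
  write_table_csv(comparison, keep(file.path(out_dir, "lurf_vs_lur.csv")))
  stages <- c(stages, "predict")

  # 7. attribute --------------------------------------------------------
  say("[attribute] category zeroing")
  attribution <- do.call(rbind, lapply(config$attribution$categories,
                                       function(cat) {
    a_s <- attribute_one_season(models$summer, city, cat, gf$summer)
    a_w <- attribute_one_season(models$winter, city, cat, gf$winter)
    d <- (a_s + a_w) / 2
    data.frame(category = cat, mean_delta_ppb = mean(d),
               min_delta_ppb = min(d), max_delta_ppb = max(d))
  }))
  write_table_csv(attribution, keep(file.path(out_dir, "attribution.csv")))
  stages <- c(stages, "attribute")

  # 8. sensitivity ------------------------------------------------------
  say("[sensitivity] %d scenarios", length(config$scenarios))
  scns <- lapply(config$scenarios, function(s)
    scenario(s$category, s$kind, s$delta))
  sens <- run_sensitivity_two_tables(models, city, scns, gf)
  write_table_csv(sens$table, keep(file.path(out_dir, "sensitivity.csv")))
  stages <- c(stages, "sensitivity")

  # 9. health -----------------------------------------------------------
  say("[health] impact propagation")
  pop <- city_population(city)
  hifs <- default_hif_registry()
  band <- config$health$endpoint_band
  wq <- worst_quintile_mask(surf$annual)
  health_rows <- list()
  for (i in seq_len(nrow(attribution))) {
    cat_i <- attribution$category[i]
    a_s <- attribute_one_season(models$summer, city, cat_i, gf$summer)
    a_w <- attribute_one_season(models$winter, city, cat_i, gf$winter)
    dsurf <- grid_surface(matrix((a_s + a_w) / 2, city$grid$ny, city$grid$nx,
                                 byrow = TRUE), city$grid)
    for (h in hifs) {
      popb <- pop[[h$age_band]]
      if (is.null(popb)) next
      res <- apply_hif(h, dsurf, popb)
      health_rows[[length(health_rows) + 1L]] <- data.frame(
        category = cat_i, endpoint = h$endpoint, age_band = h$age_band,
        delta_cases = res$total_delta_cases,
        rate_per_100k = res$rate_per_100k)
    }
  }
  health <- do.call(rbind, health_rows)
  write_table_csv(health, keep(file.path(out_dir, "health_attribution.csv")))
  stages <- c(stages, "health")

  manifest <- list(
    package = "lurf",
    seed = seed,
    config = config,
    stages = stages,
    n_stages = length(stages),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    artifacts = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d stages", length(stages))

  invisible(list(city = city, params = params, sites = sites,
                 splits = splits, models = models, metrics = metrics,
                 surfaces = surf, comparison = comparison,
                 attribution = attribution, sensitivity = sens,
                 health = health, grid_features = gf, population = pop,
                 worst_quintile = wq, manifest = manifest))
}

# annual per-season attribution helper: returns delta vector over cells
attribute_one_season <- function(model_set, city, category, grid_features) {
  base <- predict(model_set$lurf, grid_features)
  zero <- predict(model_set$lurf, zero_category(grid_features, category))
  base - zero
}

# sensitivity when summer and winter models use different selected radii
run_sensitivity_two_tables <- function(models, city, scns, gf) {
  base <- annual_average(
    predict_grid(models$summer$lurf, city, models$summer$selected, gf$summer),
    predict_grid(models$winter$lurf, city, models$winter$selected, gf$winter))
  rows <- list(); surfaces <- list()
  for (scn in scns) {
    ok <- tryCatch({
      mfs <- apply_modification(gf$summer, scn)
      mfw <- apply_modification(gf$winter, scn)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
    mod <- annual_average(
      predict_grid(models$summer$lurf, city, models$summer$selected, mfs),
      predict_grid(models$winter$lurf, city, models$winter$selected, mfw))
    d <- mod$values - base$values
    pct <- 100 * d / base$values
    label <- sprintf("%s%+g", scn$category, scn$delta)
    rows[[label]] <- data.frame(
      scenario = label, category = scn$category, delta = scn$delta,
      mean_pct_change = 100 * mean(d) / mean(base$values),
      max_local_pct_change = pct[which.max(abs(pct))],
      mean_delta_ppb = mean(d))
    surfaces[[label]] <- grid_surface(d, city$grid)
  }
  table <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
           else data.frame(scenario = character(), category = character(),
                           delta = numeric(), mean_pct_change = numeric(),
                           max_local_pct_change = numeric(),
                           mean_delta_ppb = numeric())
  list(table = table, surfaces = surfaces, baseline = base)
}
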