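# Counterfactual attribution and LULC-modification scenarios -------------------

# parse buffered feature columns of a table: category + radius per column
feature_table_columns <- function(features) {
  cn <- colnames(features)
  m <- regmatches(cn, regexec("^([a-z_0-9]+)_r(\\d{4})$", cn))
  hit <- lengths(m) == 3
  data.frame(column = cn[hit],
             category = vapply(m[hit], `[`, character(1), 2),
             radius = as.integer(vapply(m[hit], `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' A land-use scenario
#'
#' `kind = "zero"` removes the category entirely (counterfactual
#' attribution, no rebalancing). `kind = "modify"` changes the category by
#' `delta`: for areal categories, signed percentage points of buffer area
#' (so a +2 change adds cover even where there was none); for
#' `vmt_freeway`, a signed relative percentage change in traffic volume.
#'
#' @param category category name
#' @param kind `"modify"` or `"zero"`
#' @param delta signed change (required for `"modify"`)
#' @return object of class `lulc_scenario`
#' @export
scenario <- function(category, kind = c("modify", "zero"), delta = NULL) {
  kind <- match.arg(kind)
  if (kind == "modify" && is.null(delta))
    stop("scenario: modify requires a delta", call. = FALSE)
  structure(list(category = category, kind = kind,
                 delta = if (kind == "modify") delta else NULL),
            class = "lulc_scenario")
}

#' Default sensitivity scenario list
#'
#' The four modifiable categories (freeway VMT, tree canopy,
#' high-intensity and open development) each at +/-2, +/-5 and +/-10.
#' @return list of [scenario()] objects
#' @export
default_scenarios <- function() {
  out <- list()
  for (cat in c("vmt_freeway", "trees", "dev_high", "dev_open"))
    for (d in c(-10, -5, -2, 2, 5, 10))
      out[[length(out) + 1L]] <- scenario(cat, "modify", d)
  out
}

#' Zero out one category's feature columns
#'
#' Sets every buffer column of `category` to zero and leaves every other
#' column untouched -- the "replace with an NO2-neutral land use"
#' counterfactual. Idempotent.
#'
#' @param features a buffer feature table
#' @param category category name present in the table
#' @return modified feature table
#' @export
zero_category <- function(features, category) {
  info <- feature_table_columns(features)
  cols <- info$column[info$category %in% category]
  if (!length(cols))
    stop("zero_category: no columns for category ",
         paste(category, collapse = ","), call. = FALSE)
  features[, cols] <- 0
  features
}

#' Counterfactual NO2 attribution of a category
#'
#' The annual (summer/winter mean) difference between predictions on the
#' unmodified feature table and predictions with the category's columns
#' set to zero study-wide. Positive values mean the category adds NO2.
#' Passing several categories zeroes them jointly (used, e.g., to
#' aggregate the freeway-length and freeway-VMT encodings of one physical
#' source).
#'
#' @param model_summer,model_winter fitted seasonal models
#' @param city the city dataset
#' @param selected the [phase1_select_buffers()] result used by the models
#' @param category category name(s) to zero
#' @param grid_features optional precomputed grid feature table
#' @return list: `category`, `delta` ([grid_surface()] of delta-ppb),
#'   `mean` and `range` over valid cells
#' @export
attribute_category <- function(model_summer, model_winter, city, selected,
                               category, grid_features = NULL) {
  if (is.null(grid_features))
    grid_features <- extract_selected_features(grid_points(city$grid), city,
                                               selected)
  base <- annual_average(
    predict_grid(model_summer, city, selected, grid_features),
    predict_grid(model_winter, city, selected, grid_features))
  zf <- zero_category(grid_features, category)
  zero <- annual_average(
    predict_grid(model_summer, city, selected, zf),
    predict_grid(model_winter, city, selected, zf))
  d <- base$values - zero$values
  list(category = paste(category, collapse = "+"),
       delta = grid_surface(d, city$grid),
       mean = mean(d, na.rm = TRUE),
       range = range(d, na.rm = TRUE))
}

#' Apply a land-use modification scenario to a feature table
#'
#' Areal scenarios change the target category by `delta` percentage
#' points of buffer area (`pi * r^2` per column radius), clamped to
#' 0-100%. With `rebalance = TRUE` the other areal categories are scaled
#' by a common factor so the areal total within the buffer is preserved
#' where possible: the pool is the other areal columns at the same radius
#' when the table carries them, otherwise all other areal columns (each
#' in its own buffer's percentage terms). If an increase exhausts the
#' pool, the others are clamped at zero with a warning. `vmt_freeway`
#' scenarios multiply the VMT columns by `1 + delta/100`; nothing is
#' rebalanced. `kind = "zero"` scenarios zero the columns without
#' rebalancing, exactly like [zero_category()].
#'
#' @param features buffer feature table (areal values in m^2)
#' @param scn a [scenario()]
#' @param rebalance rebalance other areal categories (default TRUE)
#' @return modified feature table
#' @export
apply_modification <- function(features, scn, rebalance = TRUE) {
  stopifnot(inherits(scn, "lulc_scenario"))
  if (scn$kind == "zero") return(zero_category(features, scn$category))

  info <- feature_table_columns(features)
  areal <- lulc_categories()$areal
  tcols <- info[info$category == scn$category, , drop = FALSE]
  if (!nrow(tcols))
    stop("apply_modification: no columns for category ", scn$category,
         call. = FALSE)

  if (scn$category == "vmt_freeway") {
    for (cc in tcols$column)
      features[[cc]] <- features[[cc]] * (1 + scn$delta / 100)
    return(features)
  }
  if (!scn$category %in% areal)
    stop("apply_modification: modify is defined for areal categories and ",
         "vmt_freeway", call. = FALSE)

  other <- info[info$category %in% setdiff(areal, scn$category), , drop = FALSE]
  warned <- FALSE
  for (i in seq_len(nrow(tcols))) {
    r <- tcols$radius[i]
    area <- pi * r^2
    pct <- 100 * features[[tcols$column[i]]] / area
    new <- pmin(100, pmax(0, pct + scn$delta))
    dact <- new - pct
    features[[tcols$column[i]]] <- new / 100 * area

    if (!rebalance || !nrow(other)) next
    pool <- other[other$radius == r, , drop = FALSE]
    if (!nrow(pool)) pool <- other
    pool_area <- pi * pool$radius^2
    pp <- mapply(function(cc, a) 100 * features[[cc]] / a,
                 pool$column, pool_area)
    pp <- matrix(pp, nrow = nrow(features))
    tot <- rowSums(pp)
    f <- ifelse(tot > 0, (tot - dact) / tot, 1)
    if (any(dact > 0 & tot <= 0) && !warned) {
      warning("apply_modification: empty rebalancing pool at some ",
              "locations; other categories clamped")
      warned <- TRUE
    }
    if (any(f < 0) && !warned) {
      warning("apply_modification: rebalancing pool smaller than the ",
              "requested increase; other categories clamped at 0")
      warned <- TRUE
    }
    f <- pmax(0, f)
    for (j in seq_len(nrow(pool))) {
      newpp <- pmin(100, pp[, j] * f)
      features[[pool$column[j]]] <- newpp / 100 * pool_area[j]
    }
  }
  features
}

#' Run the LULC-modification sensitivity analysis
#'
#' For each scenario, predicts the modified annual surface, subtracts the
#' baseline, and summarizes the study-wide mean percentage change in
#' annual NO2 and the largest local percentage change (signed, largest in
#' magnitude).
#'
#' @inheritParams attribute_category
#' @param scenarios list of [scenario()] objects (may be empty)
#' @return list: `table` (one row per scenario) and `surfaces` (list of
#'   delta [grid_surface()]s)
#' @export
run_sensitivity <- function(model_summer, model_winter, city, selected,
                            scenarios, grid_features = NULL) {
  if (is.null(grid_features))
    grid_features <- extract_selected_features(grid_points(city$grid), city,
                                               selected)
  base <- annual_average(
    predict_grid(model_summer, city, selected, grid_features),
    predict_grid(model_winter, city, selected, grid_features))

  rows <- list(); surfaces <- list()
  for (scn in scenarios) {
    mf <- apply_modification(grid_features, scn)
    mod <- annual_average(
      predict_grid(model_summer, city, selected, mf),
      predict_grid(model_winter, city, selected, mf))
    d <- mod$values - base$values
    pct <- 100 * d / base$values
    label <- sprintf("%s%+g", scn$category, scn$delta)
    rows[[label]] <- data.frame(
      scenario = label, category = scn$category, delta = scn$delta,
      mean_pct_change = 100 * mean(d, na.rm = TRUE) /
        mean(base$values, na.rm = TRUE),
      max_local_pct_change = pct[which.max(abs(pct))],
      mean_delta_ppb = mean(d, na.rm = TRUE))
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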