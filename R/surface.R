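# Prediction surfaces ----------------------------------------------------------

#' Extract only the selected buffer columns at a set of locations
#'
#' Buffer features for the reduced predictor set (one radius per
#' category), as used for grid prediction; columns match
#' [selected_columns()].
#'
#' @param locations data.frame with `x`, `y`
#' @param city a city dataset
#' @param selected a [phase1_select_buffers()] result
#' @return feature data.frame
#' @export
extract_selected_features <- function(locations, city, selected) {
  base <- NULL
  out <- NULL
  for (i in seq_len(nrow(selected$buffers))) {
    b <- selected$buffers[i, ]
    f <- extract_features(locations, city, radii = b$radius,
                          categories = b$category)
    if (is.null(base)) base <- f[, c("location_id", "x", "y", "elevation")]
    col <- f[, b$column, drop = FALSE]
    out <- if (is.null(out)) col else cbind(out, col)
  }
  cbind(base, out)
}

#' Apply a fitted model to the prediction grid
#'
#' Evaluates a seasonal LURF or LUR model at every cell center of the
#' city's prediction grid (200 m by default), with features computed at
#' the model's selected radii only.
#'
#' @param model a [fit_forest()] or [fit_lur()] model
#' @param city a city dataset
#' @param selected the [phase1_select_buffers()] result the model was
#'   trained on
#' @param grid_features optional precomputed
#'   [extract_selected_features()] table for the grid (avoids repeated
#'   extraction across scenarios)
#' @return a [grid_surface()] of predicted NO2 (ppb)
#' @export
predict_grid <- function(model, city, selected, grid_features = NULL) {
  g <- city$grid
  if (is.null(grid_features))
    grid_features <- extract_selected_features(grid_points(g), city, selected)
  if (nrow(grid_features) != g$nx * g$ny)
    stop("predict_grid: grid feature table does not match the grid",
         call. = FALSE)
  p <- predict(model, grid_features)
  grid_surface(matrix(p, g$ny, g$nx, byrow = TRUE), g)
}

#' Annual average of two seasonal surfaces
#'
#' Cellwise arithmetic mean of the summer and winter surfaces; no-data
#' propagates.
#'
#' @param summer,winter [grid_surface()] objects on identical geometry
#' @return a [grid_surface()]
#' @export
annual_average <- function(summer, winter) {
  if (!same_geometry(summer$grid, winter$grid))
    stop("annual_average: geometry mismatch", call. = FALSE)
  grid_surface((summer$values + winter$values) / 2, summer$grid)
}
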