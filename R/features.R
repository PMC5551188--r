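# Buffer feature extraction ----------------------------------------------------

#' Feature column name for a category and radius
#' @param category category name
#' @param radius buffer radius (m)
#' @return character vector like `"trees_r0300"`
#' @export
feature_column <- function(category, radius) {
  sprintf("%s_r%04d", category, as.integer(radius))
}

# areal layer lookup; "trees" may be supplied as deciduous+evergreen+mixed
areal_layer <- function(city, category) {
  if (!is.null(city$areal[[category]])) return(city$areal[[category]])
  if (category == "trees" &&
      all(c("deciduous", "evergreen", "mixed") %in% names(city$areal)))
    return(city$areal$deciduous + city$areal$evergreen + city$areal$mixed)
  stop("areal layer not found: ", category, call. = FALSE)
}

# chord length of each segment inside a disc of radius r around each point;
# returns |points| vector of summed lengths (optionally AADT-weighted)
chord_lengths <- function(px, py, segs, radius, weights = NULL) {
  out <- numeric(length(px))
  for (k in seq_len(nrow(segs))) {
    ux <- segs$x1[k] - segs$x0[k]; uy <- segs$y1[k] - segs$y0[k]
    len2 <- ux * ux + uy * uy
    if (len2 == 0) next
    wx <- segs$x0[k] - px; wy <- segs$y0[k] - py
    b <- wx * ux + wy * uy
    c0 <- wx * wx + wy * wy - radius^2
    disc <- b * b - len2 * c0
    hit <- disc > 0
    if (!any(hit)) next
    sq <- sqrt(disc[hit])
    t1 <- pmax(0, (-b[hit] - sq) / len2)
    t2 <- pmin(1, (-b[hit] + sq) / len2)
    l <- pmax(0, t2 - t1) * sqrt(len2)
    if (!is.null(weights)) l <- l * weights[k]
    out[hit] <- out[hit] + l
  }
  out
}

# do the locations coincide with LULC raster cell centers?
aligned_with_raster <- function(grid, x, y, tol = 1e-6) {
  fx <- (x - grid$xmin) / grid$cellsize - 0.5
  fy <- (y - grid$ymin) / grid$cellsize - 0.5
  all(abs(fx - round(fx)) < tol) && all(abs(fy - round(fy)) < tol)
}

#' Extract buffer land-use features at a set of locations
#'
#' For every location and every buffer radius, computes: area of each
#' areal land-cover category within the buffer disc (m^2, by cell-center
#' inclusion of the fraction raster), length of each road class and rail
#' within the buffer (m, exact chord geometry), freeway vehicle miles
#' traveled (sum of AADT x in-buffer segment length, vehicle-miles/day),
#' housing units and permitted NOx emissions (tons/year) within the
#' buffer; plus the point features x, y and elevation (m). Buffers at the
#' study-area edge are clipped to the extent without renormalization.
#'
#' @param locations data.frame with columns `x`, `y` and optionally
#'   `location_id`
#' @param city a [generate_city()]-style city dataset
#' @param radii buffer radii in m, positive ascending
#' @param categories buffered categories to extract (default all sixteen)
#' @return data.frame: `location_id`, `x`, `y`, `elevation`, then one
#'   column per (category, radius), categories alphabetical and radii
#'   ascending
#' @export
extract_features <- function(locations, city, radii = default_radii(),
                             categories = lulc_categories()$all) {
  if (any(radii <= 0)) stop("extract_features: radii must be positive",
                            call. = FALSE)
  radii <- sort(as.integer(radii))
  ext <- city$extent
  x <- locations$x; y <- locations$y
  if (any(x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]))
    stop("extract_features: location outside the study extent", call. = FALSE)

  ids <- if (!is.null(locations$location_id)) as.character(locations$location_id)
         else sprintf("L%05d", seq_along(x))
  lg <- city$lulc_grid
  cats <- lulc_categories()
  categories <- sort(categories)
  cell_area <- lg$cellsize^2
  aligned <- aligned_with_raster(lg, x, y)

  out <- data.frame(location_id = ids, x = x, y = y,
                    elevation = raster_at_points(city$elevation, lg, x, y),
                    stringsAsFactors = FALSE)

  # raster buffer sums for all radii at once: a per-location window scan
  # (one distance computation per location) for small location sets, or
  # cumulative-sum disc kernels when many aligned locations are queried
  raster_buffer_multi <- function(mat) {
    if (aligned && length(x) > 500) {
      out <- vapply(radii, function(r)
        raster_at_points(disc_sum(mat, r, lg$cellsize), lg, x, y),
        numeric(length(x)))
      return(matrix(out, nrow = length(x)))
    }
    xs <- grid_x_centers(lg); ys <- grid_y_centers(lg)
    rmax <- max(radii)
    out <- matrix(0, length(x), length(radii))
    for (i in seq_along(x)) {
      ix <- which(abs(xs - x[i]) <= rmax)
      iy <- which(abs(ys - y[i]) <= rmax)
      if (!length(ix) || !length(iy)) next
      d2 <- outer((ys[iy] - y[i])^2, (xs[ix] - x[i])^2, `+`)
      vv <- mat[iy, ix, drop = FALSE]
      for (j in seq_along(radii))
        out[i, j] <- sum(vv[d2 <= radii[j]^2])
    }
    out
  }

  for (cat in categories) {
    vals <- matrix(0, length(x), length(radii))
    if (cat %in% cats$areal) {
      vals <- raster_buffer_multi(areal_layer(city, cat)) * cell_area
    } else if (cat %in% cats$line) {
      segs <- class_segments(city, cat)
      for (j in seq_along(radii))
        if (nrow(segs)) vals[, j] <- chord_lengths(x, y, segs, radii[j])
    } else if (cat == "vmt_freeway") {
      segs <- class_segments(city, "freeway")
      for (j in seq_along(radii))
        if (nrow(segs))
          vals[, j] <- chord_lengths(x, y, segs, radii[j],
                                     weights = segs$aadt) / 1609.344
    } else if (cat == "housing") {
      vals <- raster_buffer_multi(city$housing)
    } else if (cat == "emissions") {
      em <- city$emitters
      if (nrow(em)) {
        d <- sqrt(outer(x, em$x, `-`)^2 + outer(y, em$y, `-`)^2)
        for (j in seq_along(radii))
          vals[, j] <- as.vector((d <= radii[j]) %*% em$nox_tpy)
      }
    } else stop("unknown category: ", cat, call. = FALSE)
    colnames(vals) <- feature_column(cat, radii)
    out <- cbind(out, as.data.frame(vals))
  }
  out
}

#' Split observations into training and validation sets
#'
#' A fixed random split made once, before any model fitting. With an
#' explicit `n_validation` the validation set has exactly that size;
#' otherwise `round(fraction * n)` records are set aside.
#'
#' @param table data.frame of observations (one row per record)
#' @param fraction validation fraction in (0, 1)
#' @param seed integer seed
#' @param n_validation optional explicit validation count
#' @return list with `train` and `validation` data.frames (disjoint,
#'   exhaustive)
#' @export
split_train_validation <- function(table, fraction = 0.25, seed = 1,
                                   n_validation = NULL) {
  n <- nrow(table)
  if (n < 8) stop("split_train_validation: need at least 8 records",
                  call. = FALSE)
  if (is.null(n_validation)) {
    if (fraction <= 0 || fraction >= 1)
      stop("split_train_validation: fraction must be in (0, 1)", call. = FALSE)
    n_validation <- round(fraction * n)
  }
  if (n_validation < 1 || n_validation >= n)
    stop("split_train_validation: invalid validation size", call. = FALSE)
  with_seed(seed, {
    idx <- sort(sample(n, n_validation))
    list(train = table[-idx, , drop = FALSE],
         validation = table[idx, , drop = FALSE])
  })
}
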