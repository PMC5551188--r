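#' Planar grid geometry
#'
#' A `city_grid` describes a regular raster geometry in a planar,
#' meter-based coordinate system: lower-left corner, square cell size and
#' cell counts. Cell centers are at `xmin + (ix - 0.5) * cellsize`,
#' `ymin + (iy - 0.5) * cellsize`, with y increasing northwards. Matrices
#' backed by a grid are indexed `[iy, ix]` with row 1 the southernmost row.
#'
#' @param xmin,ymin lower-left corner of the grid (m)
#' @param cellsize square cell edge length (m), positive
#' @param nx,ny number of columns / rows, positive integers
#' @return an object of class `city_grid`
#' @export
city_grid <- function(xmin, ymin, cellsize, nx, ny) {
  if (cellsize <= 0 || nx <= 0 || ny <= 0)
    stop("city_grid: cellsize, nx and ny must be positive", call. = FALSE)
  structure(
    list(xmin = xmin, ymin = ymin, cellsize = cellsize,
         nx = as.integer(nx), ny = as.integer(ny)),
    class = "city_grid"
  )
}

#' @export
print.city_grid <- function(x, ...) {
  cat(sprintf("<city_grid> %d x %d cells of %g m, origin (%g, %g)\n",
              x$nx, x$ny, x$cellsize, x$xmin, x$ymin))
  invisible(x)
}

#' Cell-center coordinates of a grid
#' @param grid a [city_grid()]
#' @return numeric vector of cell-center x (or y) coordinates (m)
#' @export
grid_x_centers <- function(grid) grid$xmin + (seq_len(grid$nx) - 0.5) * grid$cellsize

#' @rdname grid_x_centers
#' @export
grid_y_centers <- function(grid) grid$ymin + (seq_len(grid$ny) - 0.5) * grid$cellsize

#' Extent of a grid
#' @param grid a [city_grid()]
#' @return named vector xmin, xmax, ymin, ymax (m)
#' @export
grid_extent <- function(grid) {
  c(xmin = grid$xmin, xmax = grid$xmin + grid$nx * grid$cellsize,
    ymin = grid$ymin, ymax = grid$ymin + grid$ny * grid$cellsize)
}

same_geometry <- function(a, b, tol = 1e-9) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol && a$nx == b$nx && a$ny == b$ny
}

#' NO2 (or delta-NO2) surface on a regular grid
#'
#' A `grid_surface` couples a [city_grid()] with a matrix of cell values
#' (ppb, or delta-ppb for difference surfaces). `NA` cells are no-data.
#'
#' @param values numeric matrix, `ny` rows by `nx` columns
#' @param grid a [city_grid()]
#' @return an object of class `grid_surface`
#' @export
grid_surface <- function(values, grid) {
  values <- as.matrix(values)
  if (nrow(values) != grid$ny || ncol(values) != grid$nx)
    stop("grid_surface: values must be ny x nx", call. = FALSE)
  structure(list(values = values, grid = grid), class = "grid_surface")
}

#' @export
print.grid_surface <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_surface> %d x %d cells of %g m; %d valid cells",
              x$grid$nx, x$grid$ny, x$grid$cellsize, length(v)))
  if (length(v))
    cat(sprintf("; range %.3g..%.3g, mean %.3g", min(v), max(v), mean(v)))
  cat("\n")
  invisible(x)
}

#' Convert a surface to a long table of cell centers
#'
#' Cells are enumerated row-major from the southwest corner (x varies
#' fastest), the same ordering used for grid prediction points.
#'
#' @param x a [grid_surface()]
#' @param row.names,optional,... ignored (S3 signature)
#' @return data.frame with columns `x`, `y`, `value`
#' @export
as.data.frame.grid_surface <- function(x, row.names = NULL, optional = FALSE, ...) {
  g <- x$grid
  data.frame(
    x = rep(grid_x_centers(g), times = g$ny),
    y = rep(grid_y_centers(g), each = g$nx),
    value = as.vector(t(x$values))
  )
}

#' Grid prediction points of a geometry
#'
#' @param grid a [city_grid()]
#' @return data.frame of cell-center coordinates in row-major
#'   (southwest-first, x-fastest) order
#' @keywords internal
grid_points <- function(grid) {
  data.frame(
    x = rep(grid_x_centers(grid), times = grid$ny),
    y = rep(grid_y_centers(grid), each = grid$nx)
  )
}

#' Sum raster values over a disc neighbourhood of every cell
#'
#' For each cell, sums `mat` over all cells whose center lies within
#' `radius` of that cell's center (cell-center inclusion, the same rule
#' used by buffer feature extraction). Implemented with per-row cumulative
#' sums so cost is O(ny * nx * radius/cellsize).
#'
#' @param mat numeric matrix on the grid
#' @param radius disc radius (m)
#' @param cellsize cell size (m)
#' @return matrix of disc sums, same shape as `mat`
#' @keywords internal
disc_sum <- function(mat, radius, cellsize) {
  ny <- nrow(mat); nx <- ncol(mat)
  m <- floor(radius / cellsize)
  cs <- matrix(0, ny, nx + 1L)
  cs[, 2L:(nx + 1L)] <- t(apply(mat, 1L, cumsum))
  out <- matrix(0, ny, nx)
  ix <- seq_len(nx)
  for (dy in -m:m) {
    w <- floor(sqrt(radius^2 - (dy * cellsize)^2) / cellsize)
    src <- seq_len(ny) + dy
    ok <- src >= 1L & src <= ny
    if (!any(ok)) next
    hi <- pmin(ix + w, nx) + 1L
    lo <- pmax(ix - w, 1L)
    out[ok, ] <- out[ok, ] + cs[src[ok], hi, drop = FALSE] -
      cs[src[ok], lo, drop = FALSE]
  }
  out
}

#' Mean raster value over a disc neighbourhood (local density)
#'
#' Disc sums divided by the count of in-extent cells in each disc, giving
#' a local density in the units of `mat` (e.g. a mean areal fraction).
#'
#' @inheritParams disc_sum
#' @return matrix of local densities
#' @keywords internal
disc_density <- function(mat, radius, cellsize) {
  disc_sum(mat, radius, cellsize) /
    disc_sum(matrix(1, nrow(mat), ncol(mat)), radius, cellsize)
}

# value of raster at arbitrary points (nearest cell); points outside -> NA
raster_at_points <- function(mat, grid, x, y) {
  ix <- floor((x - grid$xmin) / grid$cellsize) + 1L
  iy <- floor((y - grid$ymin) / grid$cellsize) + 1L
  ok <- ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny
  out <- rep(NA_real_, length(x))
  out[ok] <- mat[cbind(iy[ok], ix[ok])]
  out
}
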