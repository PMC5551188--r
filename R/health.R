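# Health impact functions and population allocation ----------------------------

#' A log-linear concentration-response health impact function
#'
#' The BenMAP-convention log-linear form: for a cell with population
#' `Pop` in the age band and an NO2 change `dC` (ppb), the incidence
#' change is `dy = y0 * (1 - exp(-beta * dC)) * Pop` cases/year.
#'
#' @param endpoint endpoint name (e.g. "asthma_exacerbation_symptoms")
#' @param age_band name of the population age band the function applies to
#' @param beta concentration-response coefficient (per ppb)
#' @param baseline_incidence baseline rate y0 (cases per person per year)
#' @return object of class `hif`
#' @export
health_impact_function <- function(endpoint, age_band, beta,
                                   baseline_incidence) {
  stopifnot(is.finite(beta), baseline_incidence >= 0)
  structure(list(endpoint = endpoint, age_band = age_band, beta = beta,
                 baseline_incidence = baseline_incidence,
                 form = "log-linear"),
            class = "hif")
}

#' Default health-impact-function registry
#'
#' Respiratory endpoints in the style of EPA BenMAP NO2 functions.
#' The coefficients and baseline rates shipped here are synthetic
#' stand-in values of plausible magnitude, clearly labeled as such: they
#' reproduce the structure (endpoints, age bands, log-linear form) of a
#' BenMAP configuration, not any particular published coefficients.
#'
#' @return list of [health_impact_function()]s
#' @export
default_hif_registry <- function() {
  list(
    health_impact_function("asthma_exacerbation_symptoms", "age_4_12",
                           beta = 0.0095, baseline_incidence = 0.42),
    health_impact_function("asthma_exacerbation_missed_school", "age_4_12",
                           beta = 0.0095, baseline_incidence = 0.14),
    health_impact_function("cough", "age_7_14",
                           beta = 0.0070, baseline_incidence = 0.12),
    health_impact_function("er_visits_asthma", "age_65_plus",
                           beta = 0.0040, baseline_incidence = 0.0002),
    health_impact_function("hospital_admissions_respiratory", "age_65_plus",
                           beta = 0.0020, baseline_incidence = 0.0014))
}

# close a polygon ring and clip it to an axis-aligned rectangle
# (Sutherland-Hodgman); returns list(x, y)
clip_polygon_rect <- function(px, py, xmin, xmax, ymin, ymax) {
  clip_edge <- function(x, y, inside, intersect) {
    if (!length(x)) return(list(x = numeric(0), y = numeric(0)))
    nx <- numeric(0); ny <- numeric(0)
    n <- length(x)
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      cur_in <- inside(x[i], y[i]); prev_in <- inside(x[j], y[j])
      if (cur_in) {
        if (!prev_in) {
          p <- intersect(x[j], y[j], x[i], y[i])
          nx <- c(nx, p[1]); ny <- c(ny, p[2])
        }
        nx <- c(nx, x[i]); ny <- c(ny, y[i])
      } else if (prev_in) {
        p <- intersect(x[j], y[j], x[i], y[i])
        nx <- c(nx, p[1]); ny <- c(ny, p[2])
      }
    }
    list(x = nx, y = ny)
  }
  ix <- function(x0, y0, x1, y1, xc) {
    t <- (xc - x0) / (x1 - x0); c(xc, y0 + t * (y1 - y0))
  }
  iy <- function(x0, y0, x1, y1, yc) {
    t <- (yc - y0) / (y1 - y0); c(x0 + t * (x1 - x0), yc)
  }
  p <- list(x = px, y = py)
  p <- clip_edge(p$x, p$y, function(x, y) x >= xmin,
                 function(x0, y0, x1, y1) ix(x0, y0, x1, y1, xmin))
  p <- clip_edge(p$x, p$y, function(x, y) x <= xmax,
                 function(x0, y0, x1, y1) ix(x0, y0, x1, y1, xmax))
  p <- clip_edge(p$x, p$y, function(x, y) y >= ymin,
                 function(x0, y0, x1, y1) iy(x0, y0, x1, y1, ymin))
  p <- clip_edge(p$x, p$y, function(x, y) y <= ymax,
                 function(x0, y0, x1, y1) iy(x0, y0, x1, y1, ymax))
  p
}

shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# normalize polygon input: rectangles data.frame or list of polygons
as_polygon_list <- function(polygons) {
  if (is.data.frame(polygons)) {
    stopifnot(all(c("xmin", "xmax", "ymin", "ymax", "count") %in%
                    colnames(polygons)))
    lapply(seq_len(nrow(polygons)), function(i) {
      r <- polygons[i, ]
      list(id = if (!is.null(r$block_id)) r$block_id else as.character(i),
           x = c(r$xmin, r$xmax, r$xmax, r$xmin),
           y = c(r$ymin, r$ymin, r$ymax, r$ymax),
           count = r$count)
    })
  } else polygons
}

#' Allocate polygon population counts to a grid
#'
#' Areal weighting in the Popgrid style: each polygon's count is split
#' across grid cells in proportion to the polygon-cell overlap area
#' (share = overlap / polygon area), so totals are conserved for polygons
#' inside the grid. Polygons may be census-block-style rectangles (a
#' data.frame with `xmin`/`xmax`/`ymin`/`ymax`/`count`) or arbitrary
#' simple polygons (a list of `list(id, x, y, count)` rings).
#'
#' @param polygons polygon source counts (see above)
#' @param grid target [city_grid()]
#' @return a [grid_surface()] of persons per cell
#' @export
allocate_population <- function(polygons, grid) {
  polys <- as_polygon_list(polygons)
  counts <- vapply(polys, function(p) p$count, numeric(1))
  if (any(counts < 0))
    stop("allocate_population: negative population count", call. = FALSE)
  cs <- grid$cellsize
  out <- matrix(0, grid$ny, grid$nx)
  for (p in polys) {
    if (p$count == 0) next
    parea <- shoelace_area(p$x, p$y)
    if (parea == 0) next
    ix0 <- max(1L, floor((min(p$x) - grid$xmin) / cs) + 1L)
    ix1 <- min(grid$nx, ceiling((max(p$x) - grid$xmin) / cs))
    iy0 <- max(1L, floor((min(p$y) - grid$ymin) / cs) + 1L)
    iy1 <- min(grid$ny, ceiling((max(p$y) - grid$ymin) / cs))
    if (ix1 < ix0 || iy1 < iy0) next
    is_rect <- length(p$x) == 4 &&
      setequal(round(p$x, 9), round(range(p$x), 9)) &&
      setequal(round(p$y, 9), round(range(p$y), 9)) &&
      all(p$x %in% range(p$x)) && all(p$y %in% range(p$y))
    if (is_rect) {
      # axis-aligned rectangle: overlap is a product of interval overlaps
      for (iy in iy0:iy1) {
        cymin <- grid$ymin + (iy - 1) * cs
        oy <- min(max(p$y), cymin + cs) - max(min(p$y), cymin)
        if (oy <= 0) next
        for (ix in ix0:ix1) {
          cxmin <- grid$xmin + (ix - 1) * cs
          ox <- min(max(p$x), cxmin + cs) - max(min(p$x), cxmin)
          if (ox > 0) out[iy, ix] <- out[iy, ix] + p$count * ox * oy / parea
        }
      }
      next
    }
    for (iy in iy0:iy1) {
      for (ix in ix0:ix1) {
        cxmin <- grid$xmin + (ix - 1) * cs
        cymin <- grid$ymin + (iy - 1) * cs
        cl <- clip_polygon_rect(p$x, p$y, cxmin, cxmin + cs,
                                cymin, cymin + cs)
        ov <- shoelace_area(cl$x, cl$y)
        if (ov > 0) out[iy, ix] <- out[iy, ix] + p$count * ov / parea
      }
    }
  }
  grid_surface(out, grid)
}

#' Apply a health impact function to an NO2 change surface
#'
#' Per cell, `dy = y0 * (1 - exp(-beta * dC)) * Pop`; aggregated over the
#' requested scope together with the rate per 100,000 persons in the age
#' band (`1e5 * sum(dy) / sum(Pop)`).
#'
#' @param hif a [health_impact_function()]
#' @param delta_surface [grid_surface()] of NO2 change (ppb); positive
#'   means added NO2
#' @param population [grid_surface()] of persons in the age band
#' @param scope_mask optional logical matrix restricting the aggregate
#'   (e.g. the worst NO2 quintile); default whole study area
#' @return list: `endpoint`, `cell_delta` ([grid_surface()],
#'   cases/year), `total_delta_cases`, `rate_per_100k`, `population`,
#'   `scope`
#' @export
apply_hif <- function(hif, delta_surface, population, scope_mask = NULL) {
  stopifnot(inherits(hif, "hif"))
  if (!same_geometry(delta_surface$grid, population$grid))
    stop("apply_hif: geometry mismatch", call. = FALSE)
  dC <- delta_surface$values
  pop <- population$values
  dy <- hif$baseline_incidence * (1 - exp(-hif$beta * dC)) * pop
  scope <- if (is.null(scope_mask)) "study_area" else "masked"
  m <- if (is.null(scope_mask)) !is.na(dy) else (scope_mask & !is.na(dy))
  tot <- sum(dy[m])
  ptot <- sum(pop[m])
  list(endpoint = hif$endpoint,
       cell_delta = grid_surface(dy, delta_surface$grid),
       total_delta_cases = tot,
       rate_per_100k = if (ptot > 0) 1e5 * tot / ptot else NA_real_,
       population = ptot,
       scope = scope)
}

#' Mask of the worst NO2 quintile
#'
#' The `ceiling(n/5)` valid cells with the highest values: every cell at
#' or above the k-th largest value. A constant surface yields a
#' whole-area mask with a warning.
#'
#' @param surface a [grid_surface()] with at least 5 valid cells
#' @return logical matrix (TRUE = in the worst quintile)
#' @export
worst_quintile_mask <- function(surface) {
  v <- surface$values
  ok <- !is.na(v)
  n <- sum(ok)
  if (n < 5)
    stop("worst_quintile_mask: need at least 5 valid cells", call. = FALSE)
  vals <- v[ok]
  if (max(vals) == min(vals)) {
    warning("worst_quintile_mask: constant surface; masking whole area")
    return(ok)
  }
  k <- ceiling(n / 5)
  thr <- sort(vals, decreasing = TRUE)[k]
  ok & !is.na(v) & v >= thr
}

#' Population rasters per age band for a synthetic city
#'
#' Allocates the city's census-block-style polygons to the prediction
#' grid and splits the total into age bands using the city's fixed age
#' fractions.
#'
#' @param city a [generate_city()] result
#' @return named list of [grid_surface()]s: `total` plus one per age band
#' @export
city_population <- function(city) {
  total <- allocate_population(city$blocks, city$grid)
  out <- list(total = total)
  for (band in names(city$age_fractions))
    out[[band]] <- grid_surface(total$values * city$age_fractions[[band]],
                                total$grid)
  out
}
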