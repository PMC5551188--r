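#' @useDynLib lurf, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif quantile cor coef lm predict sd
#' @importFrom utils read.csv write.csv head
"_PACKAGE"

# Land use / land cover category registry -------------------------------------

#' Land-use categories used by the feature extractor
#'
#' Eight areal fraction categories (NLCD-style), five line classes, freeway
#' vehicle-miles-traveled, housing units and permitted NOx emissions:
#' sixteen buffered categories in all, matching a ~200-column feature table
#' at twelve buffer radii plus the three point features x, y and elevation.
#'
#' @return named list with elements `areal`, `line`, `vmt`, `count`,
#'   `point_sum`, and `all` (alphabetical order used for feature columns)
#' @export
lulc_categories <- function() {
  areal <- c("dev_high", "dev_low", "dev_med", "dev_open",
             "grassland", "pasture", "shrub", "trees")
  line <- c("freeway", "rail", "road_local", "road_primary", "road_secondary")
  out <- list(
    areal = areal,
    line = line,
    vmt = "vmt_freeway",
    count = "housing",
    point_sum = "emissions"
  )
  out$all <- sort(c(areal, line, out$vmt, out$count, out$point_sum))
  out
}

#' Default buffer radii (m)
#'
#' Twelve concentric buffer radii from 100 to 1200 m in 100 m steps.
#' @return integer vector
#' @export
default_radii <- function() seq(100L, 1200L, by = 100L)

# RNG scoping: run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Synthetic truth parameters ---------------------------------------------------

#' Parameters of the synthetic NO2-generating process
#'
#' The synthetic truth at a point is
#' `seasonal_mult * (background + sum(source terms) - sum(sink terms))`,
#' floored at a small positive value. Line and point categories contribute
#' exponential distance-decay kernels `strength * exp(-d / decay)` (the
#' freeway term additionally scaled by local AADT relative to `aadt_ref`;
#' emitters by permitted NOx relative to `nox_ref`). Areal categories and
#' housing contribute local disc-density terms: the mean category fraction
#' (or mean housing units per cell relative to `dens_ref`) within `decay`
#' meters of the point.
#'
#' Defaults are calibrated so that, with the default city layout and site
#' design, summer site observations average ~11 ppb in the 4-23 ppb range
#' and winter ~13 ppb in 3-29 ppb, and the study-area tree association is
#' about -0.4 ppb.
#'
#' @param background regional background (ppb)
#' @param seasonal named multipliers for summer and winter
#' @param floor lower floor of the truth surface (ppb)
#' @param noise_sd observation noise standard deviation (ppb)
#' @param terms data.frame with columns `category`, `kind`
#'   (line/point/density), `strength` (ppb; positive = source, negative =
#'   sink) and `decay` (m)
#' @param aadt_ref,nox_ref,dens_ref normalizing constants for the
#'   AADT-weighted freeway kernel, emitter kernel (tons/year) and housing
#'   density (units per LULC cell)
#' @return object of class `truth_params`
#' @export
truth_params <- function(background = 10.2,
                         seasonal = c(summer = 1, winter = 13 / 11),
                         floor = 1,
                         noise_sd = 1,
                         terms = default_truth_terms(),
                         aadt_ref = 120000,
                         nox_ref = 500,
                         dens_ref = 2.4) {
  stopifnot(background >= 0, noise_sd >= 0, all(terms$decay > 0))
  structure(list(background = background, seasonal = seasonal, floor = floor,
                 noise_sd = noise_sd, terms = terms, aadt_ref = aadt_ref,
                 nox_ref = nox_ref, dens_ref = dens_ref),
            class = "truth_params")
}

#' Default generative strengths and kernel scales
#'
#' Eleven categories carry signal (eight sources, three sinks), mirroring
#' the sign structure of road/development-positive, vegetation-negative
#' associations; `dev_low`, `grassland` and `pasture` are landscape-only.
#'
#' @return data.frame of term definitions
#' @export
default_truth_terms <- function() {
  data.frame(
    category = c("freeway", "road_primary", "road_secondary", "road_local",
                 "rail", "emissions",
                 "dev_high", "dev_med", "housing",
                 "trees", "dev_open", "shrub"),
    kind = c("line", "line", "line", "line", "line", "point",
             "density", "density", "density",
             "density", "density", "density"),
    strength = c(6.7, 1.6, 1.3, 0.6, 2.5, 3.2,
                 6.8, 2.2, 0.5,
                 -1.35, -2.6, -1.8),
    decay = c(300, 250, 180, 120, 400, 700,
              500, 500, 500,
              600, 400, 500),
    stringsAsFactors = FALSE
  )
}

#' Remove one category's generative term
#'
#' Sets the strength of `category`'s truth term to zero, leaving everything
#' else untouched; used to compute ground-truth attributions.
#'
#' @param params a [truth_params()]
#' @param category one or more category names
#' @return modified `truth_params`
#' @export
drop_truth_term <- function(params, category) {
  params$terms$strength[params$terms$category %in% category] <- 0
  params
}

# City generation --------------------------------------------------------------

# smooth [0,1]-ish random field on a grid: white noise averaged over a disc
smooth_field <- function(ny, nx, cellsize, radius) {
  z <- matrix(rnorm(ny * nx), ny, nx)
  f <- disc_density(z, radius, cellsize)
  (f - min(f)) / (max(f) - min(f) + 1e-12)
}

gauss_blob <- function(xm, ym, cx, cy, radius) {
  exp(-((xm - cx)^2 + (ym - cy)^2) / (2 * radius^2))
}

# polyline -> segment table
segs_from_path <- function(xs, ys, class, aadt = NA_real_) {
  k <- length(xs) - 1L
  data.frame(x0 = xs[-length(xs)], y0 = ys[-length(ys)],
             x1 = xs[-1L], y1 = ys[-1L],
             class = class, aadt = rep_len(aadt, k),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic metropolitan area
#'
#' Builds a virtual ~20 x 20 km city with a dense urban core, a secondary
#' center, two crossing freeway corridors, primary/secondary/local road
#' grids, a rail line, a handful of permitted NOx point sources, housing,
#' elevation, census-block-style population polygons and eight NLCD-style
#' areal land-cover fraction layers (40 m cells). The layout guarantees
#' representation of every buffered category: a freeway corridor, a
#' high-intensity core, peripheral tree cover and open-development patches.
#'
#' @param extent_km square study-area edge length (km)
#' @param lulc_cellsize LULC raster cell (m); must divide `grid_cellsize`
#'   with an odd quotient so prediction points coincide with LULC cell
#'   centers
#' @param grid_cellsize prediction-grid cell (m), default 200
#' @param seed integer seed controlling the stochastic texture of the
#'   landscape
#' @param total_population persons in the study area
#' @param age_fractions named fractions of total population per age band
#' @return object of class `city_dataset`: LULC fraction rasters
#'   (`areal`), `roads`, `rail`, `emitters`, `housing`, `elevation`
#'   rasters, population `blocks` polygons, and grid geometries
#' @export
generate_city <- function(extent_km = 20, lulc_cellsize = 40,
                          grid_cellsize = 200, seed = 1,
                          total_population = 320000,
                          age_fractions = c(age_4_12 = 0.11,
                                            age_65_plus = 0.15)) {
  if (extent_km <= 0 || lulc_cellsize <= 0 || grid_cellsize <= 0)
    stop("generate_city: extent and cell sizes must be positive",
         call. = FALSE)
  ratio <- grid_cellsize / lulc_cellsize
  if (abs(ratio - round(ratio)) > 1e-9 || round(ratio) %% 2 != 1)
    stop("generate_city: grid_cellsize must be an odd multiple of ",
         "lulc_cellsize", call. = FALSE)

  ext <- extent_km * 1000
  lg <- city_grid(0, 0, lulc_cellsize, ext / lulc_cellsize, ext / lulc_cellsize)
  pg <- city_grid(0, 0, grid_cellsize, ext / grid_cellsize, ext / grid_cellsize)

  with_seed(seed, {
    xs <- grid_x_centers(lg); ys <- grid_y_centers(lg)
    xm <- matrix(xs, lg$ny, lg$nx, byrow = TRUE)
    ym <- matrix(ys, lg$ny, lg$nx)
    s <- ext / 20000  # layout scale relative to the 20 km reference design

    # road and rail networks ---------------------------------------------
    fw1 <- segs_from_path(c(8200, 8200, 8700, 8700) * s,
                          c(0, 8000, 12000, 20000) * s,
                          "freeway", c(95000, 130000, 110000))
    fw2 <- segs_from_path(c(0, 6000, 12000, 20000) * s,
                          c(11800, 11600, 11600, 12100) * s,
                          "freeway", c(90000, 140000, 100000))
    prim <- rbind(
      segs_from_path(c(4600, 4600) * s, c(0, 20000) * s, "primary", 22000),
      segs_from_path(c(14600, 14600) * s, c(0, 20000) * s, "primary", 18000),
      segs_from_path(c(0, 20000) * s, c(5000, 5000) * s, "primary", 20000),
      segs_from_path(c(0, 20000) * s, c(16200, 16200) * s, "primary", 15000))
    secx <- c(2000, 6500, 11000, 12800, 17000) * s
    secy <- c(2500, 7800, 9800, 13800, 18000) * s
    sec <- rbind(
      do.call(rbind, lapply(secx, function(x)
        segs_from_path(c(x, x), c(0, 20000) * s, "secondary", 8000))),
      do.call(rbind, lapply(secy, function(y)
        segs_from_path(c(0, 20000) * s, c(y, y), "secondary", 8000))))
    locv <- seq(2250, 17750, by = 500) * s
    loc <- rbind(
      do.call(rbind, lapply(locv, function(x)
        segs_from_path(c(x, x), c(2000, 18000) * s, "local", 1200))),
      do.call(rbind, lapply(locv, function(y)
        segs_from_path(c(2000, 18000) * s, c(y, y), "local", 1200))))
    roads <- rbind(fw1, fw2, prim, sec, loc)
    rail <- rbind(segs_from_path(c(0, 20000) * s, c(9200, 9200) * s, "rail"),
                  segs_from_path(c(10000, 14000) * s, c(9200, 6200) * s, "rail"))

    emitters <- data.frame(
      x = c(8600, 12000, 4000, 6000, 13500, 9500, 15500, 3400, 10800,
            6800) * s,
      y = c(4000, 9000, 9500, 6000, 13500, 15500, 10400, 16800, 12400,
            18600) * s,
      nox_tpy = c(900, 650, 520, 380, 300, 260, 420, 340, 280, 220))

    # areal land-cover fractions -----------------------------------------
    core1 <- gauss_blob(xm, ym, 10000 * s, 10500 * s, 4000 * s)
    core2 <- gauss_blob(xm, ym, 5500 * s, 14000 * s, 2500 * s)
    urban <- pmin(core1 + 0.8 * core2, 1)
    tex <- function(r) smooth_field(lg$ny, lg$nx, lg$cellsize, r * s)

    dev_high <- pmin((0.85 * core1^3 + 0.5 * core2^3) *
                       (0.7 + 0.6 * tex(800)), 0.95)
    dev_med <- pmin(0.8 * urban * (1 - core1^3) * (0.6 + 0.8 * tex(1000)), 0.9)
    dev_low <- pmin(0.8 * urban^0.5 * (1 - urban) * (0.5 + tex(1200)), 0.9)
    # parks and open spaces are scattered across both core and periphery,
    # and street-tree cover varies independently of development intensity,
    # so vegetation sinks are identifiable rather than mere mirrors of the
    # urban gradient
    parks <- matrix(0, lg$ny, lg$nx)
    park_xy <- cbind(c(12500, 6500, 9200, 4200, 15200, 11200, 2200, 17600,
                       17000, 3000, 7800),
                     c(14500, 4500, 8200, 10800, 7200, 17200, 2600, 17600,
                       12800, 14800, 13400))
    park_r <- c(1100, 1000, 700, 800, 900, 750, 900, 800, 850, 750, 650)
    for (k in seq_len(nrow(park_xy)))
      parks <- parks + 0.65 * gauss_blob(xm, ym, park_xy[k, 1] * s,
                                         park_xy[k, 2] * s, park_r[k] * s)
    dev_open <- pmin(parks + 0.30 * tex(1200), 0.8)
    trees <- pmin(0.35 * (1 - urban)^1.5 * (0.5 + 0.6 * tex(1500)) +
                    0.75 * gauss_blob(xm, ym, 15800 * s, 16500 * s, 2200 * s) +
                    0.65 * gauss_blob(xm, ym, 2800 * s, 3200 * s, 1700 * s) +
                    0.35 * tex(1000), 0.95)
    shrub <- pmin(0.15 * tex(1400) +
                    0.55 * gauss_blob(xm, ym, 2400 * s, 7000 * s, 1800 * s) +
                    0.55 * gauss_blob(xm, ym, 13800 * s, 2400 * s, 1700 * s) +
                    0.50 * gauss_blob(xm, ym, 18200 * s, 9800 * s, 1500 * s) +
                    0.45 * gauss_blob(xm, ym, 9000 * s, 18000 * s, 1300 * s), 0.7)
    grassland <- pmin(0.45 * (1 - urban)^2 * tex(1800) +
                        0.4 * gauss_blob(xm, ym, 18000 * s, 2500 * s, 2200 * s), 0.7)
    pasture <- pmin(0.5 * (1 - urban)^3 * tex(2200) +
                      0.45 * gauss_blob(xm, ym, 17500 * s, 8000 * s, 2000 * s), 0.7)

    areal <- list(dev_high = dev_high, dev_low = dev_low, dev_med = dev_med,
                  dev_open = dev_open, grassland = grassland,
                  pasture = pasture, shrub = shrub, trees = trees)
    total <- Reduce(`+`, areal)
    scale <- ifelse(total > 0.98, 0.98 / total, 1)
    areal <- lapply(areal, function(m) m * scale)

    # housing (units per LULC cell) and elevation -------------------------
    # housing density follows the development layers with an independent
    # texture component, so the housing signal is identifiable and not a
    # pure linear combination of the development fractions
    cell_km2 <- (lg$cellsize / 1000)^2
    housing <- (1200 * areal$dev_low + 2600 * areal$dev_med +
                  1600 * areal$dev_high) * cell_km2 *
      (0.45 + 1.1 * tex(1100))
    elevation <- 40 +
      180 * gauss_blob(xm, ym, 16500 * s, 4500 * s, 2600 * s) +
      70 * gauss_blob(xm, ym, 2500 * s, 17500 * s, 3200 * s) +
      0.002 * ym

    # census-block-style population polygons ------------------------------
    bs <- 250 * s
    nb <- floor(ext / bs)
    bx <- rep(seq_len(nb), times = nb); by <- rep(seq_len(nb), each = nb)
    # resident population is suppressed near the freeway corridors
    # (industrial/commercial frontage, vacancies), so few residents -- and
    # few children -- live inside the near-freeway impact zone
    hsum <- block_sums(housing, lg, bs, nb)
    bcx <- (bx - 0.5) * bs; bcy <- (by - 0.5) * bs
    bfw <- apply(point_segment_distance(bcx, bcy, rbind(fw1, fw2)), 1L, min)
    cnt <- as.vector(t(hsum)) * 2.5 * runif(nb * nb, 0.9, 1.1) *
      (1 - 0.95 * exp(-(bfw / 650)^2))
    cnt <- cnt * total_population / sum(cnt)
    blocks <- data.frame(
      block_id = sprintf("B%04d", seq_len(nb * nb)),
      xmin = (bx - 1) * bs, xmax = bx * bs,
      ymin = (by - 1) * bs, ymax = by * bs,
      count = cnt)

    structure(list(
      lulc_grid = lg, grid = pg, extent = grid_extent(lg),
      areal = areal, roads = roads, rail = rail, emitters = emitters,
      housing = housing, elevation = elevation, blocks = blocks,
      age_fractions = age_fractions, crs = "local planar meters",
      seed = seed),
      class = "city_dataset")
  })
}

# sum a raster over square blocks of edge `bs` meters (cells assigned by
# center) -> nb x nb matrix, rows = y blocks, cols = x blocks
block_sums <- function(mat, grid, bs, nb) {
  gy <- pmin(nb, floor(grid_y_centers(grid) / bs) + 1L)
  gx <- pmin(nb, floor(grid_x_centers(grid) / bs) + 1L)
  t(rowsum(t(rowsum(mat, gy)), gx))
}

#' @export
print.city_dataset <- function(x, ...) {
  cat(sprintf("<city_dataset> %g x %g km, LULC %g m cells, grid %g m\n",
              diff(x$extent[c("xmin", "xmax")]) / 1000,
              diff(x$extent[c("ymin", "ymax")]) / 1000,
              x$lulc_grid$cellsize, x$grid$cellsize))
  cat(sprintf("  %d road segments, %d rail segments, %d emitters, %d blocks\n",
              nrow(x$roads), nrow(x$rail), nrow(x$emitters), nrow(x$blocks)))
  invisible(x)
}

# Distance from points to a set of segments -----------------------------------

# returns matrix |points| x |segments| of distances
point_segment_distance <- function(px, py, segs) {
  out <- matrix(NA_real_, length(px), nrow(segs))
  for (k in seq_len(nrow(segs))) {
    dx <- segs$x1[k] - segs$x0[k]; dy <- segs$y1[k] - segs$y0[k]
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      out[, k] <- sqrt((px - segs$x0[k])^2 + (py - segs$y0[k])^2)
    } else {
      t <- pmin(1, pmax(0, ((px - segs$x0[k]) * dx + (py - segs$y0[k]) * dy) / len2))
      out[, k] <- sqrt((px - (segs$x0[k] + t * dx))^2 +
                         (py - (segs$y0[k] + t * dy))^2)
    }
  }
  out
}

# Truth surface ----------------------------------------------------------------

# segments of one buffered line category
class_segments <- function(city, category) {
  if (category == "rail") return(city$rail)
  cls <- switch(category, freeway = "freeway", road_primary = "primary",
                road_secondary = "secondary", road_local = "local",
                stop("unknown line category: ", category))
  city$roads[city$roads$class == cls, , drop = FALSE]
}

# Evaluate the deterministic truth process at arbitrary points.
# Line kernels take the maximum per-segment contribution within the class
# (avoids double counting at polyline joints); emitter kernels sum over
# sources; density kernels are disc means around each point.
truth_at_points <- function(city, params, season, px, py) {
  season <- match.arg(season, c("summer", "winter"))
  lg <- city$lulc_grid
  val <- rep(params$background, length(px))

  for (i in seq_len(nrow(params$terms))) {
    tm <- params$terms[i, ]
    if (tm$strength == 0) next
    contrib <- switch(
      tm$kind,
      line = {
        segs <- class_segments(city, tm$category)
        if (nrow(segs) == 0) 0 else {
          d <- point_segment_distance(px, py, segs)
          w <- if (tm$category == "freeway") segs$aadt / params$aadt_ref else
            rep(1, nrow(segs))
          k <- exp(-d / tm$decay) * matrix(w, nrow(d), ncol(d), byrow = TRUE)
          tm$strength * apply(k, 1L, max)
        }
      },
      point = {
        if (nrow(city$emitters) == 0) 0 else {
          d <- point_segment_distance(px, py, data.frame(
            x0 = city$emitters$x, y0 = city$emitters$y,
            x1 = city$emitters$x, y1 = city$emitters$y))
          k <- exp(-d / tm$decay) %*% (city$emitters$nox_tpy / params$nox_ref)
          tm$strength * as.vector(k)
        }
      },
      density = {
        mat <- if (tm$category == "housing") city$housing / params$dens_ref
               else city$areal[[tm$category]]
        density_at_points(mat, lg, px, py, tm$decay) * tm$strength
      },
      stop("unknown term kind: ", tm$kind)
    )
    val <- val + contrib
  }
  pmax(params$floor, val) * params$seasonal[[season]]
}

# mean of raster cells whose centers fall within `radius` of each point
density_at_points <- function(mat, grid, px, py, radius) {
  cs <- grid$cellsize
  out <- numeric(length(px))
  xs <- grid_x_centers(grid); ys <- grid_y_centers(grid)
  for (i in seq_along(px)) {
    ix <- which(abs(xs - px[i]) <= radius)
    iy <- which(abs(ys - py[i]) <= radius)
    if (!length(ix) || !length(iy)) { out[i] <- 0; next }
    d2 <- outer((ys[iy] - py[i])^2, (xs[ix] - px[i])^2, `+`)
    inside <- d2 <= radius^2
    out[i] <- sum(mat[iy, ix, drop = FALSE][inside]) / max(1, sum(inside))
  }
  out
}

#' Simulate the known NO2 truth surface
#'
#' Evaluates the synthetic generative process on the city's prediction
#' grid for one season. This is the ground truth that fitted models are
#' later compared against.
#'
#' @param city a [generate_city()] result
#' @param params a [truth_params()]
#' @param season `"summer"` or `"winter"`
#' @return a [grid_surface()] of NO2 (ppb)
#' @export
simulate_no2_truth <- function(city, params, season) {
  season <- match.arg(season, c("summer", "winter"))
  pts <- grid_points(city$grid)
  # density terms are cheap on the aligned grid; reuse the raster path
  vals <- truth_grid_fast(city, params, pts)
  v <- pmax(params$floor, vals) * params$seasonal[[season]]
  grid_surface(matrix(v, city$grid$ny, city$grid$nx, byrow = TRUE), city$grid)
}

# fast truth evaluation at prediction-grid points: density terms via raster
# disc means indexed at the aligned points, line/point terms vectorized
truth_grid_fast <- function(city, params, pts) {
  lg <- city$lulc_grid
  val <- rep(params$background, nrow(pts))
  for (i in seq_len(nrow(params$terms))) {
    tm <- params$terms[i, ]
    if (tm$strength == 0) next
    if (tm$kind == "density") {
      mat <- if (tm$category == "housing") city$housing / params$dens_ref
             else city$areal[[tm$category]]
      dd <- disc_density(mat, tm$decay, lg$cellsize)
      val <- val + tm$strength * raster_at_points(dd, lg, pts$x, pts$y)
    } else if (tm$kind == "line") {
      segs <- class_segments(city, tm$category)
      if (nrow(segs)) {
        d <- point_segment_distance(pts$x, pts$y, segs)
        w <- if (tm$category == "freeway") segs$aadt / params$aadt_ref else
          rep(1, nrow(segs))
        k <- exp(-d / tm$decay) * matrix(w, nrow(d), ncol(d), byrow = TRUE)
        val <- val + tm$strength * apply(k, 1L, max)
      }
    } else if (tm$kind == "point") {
      if (nrow(city$emitters)) {
        d <- point_segment_distance(pts$x, pts$y, data.frame(
          x0 = city$emitters$x, y0 = city$emitters$y,
          x1 = city$emitters$x, y1 = city$emitters$y))
        k <- exp(-d / tm$decay) %*% (city$emitters$nox_tpy / params$nox_ref)
        val <- val + tm$strength * as.vector(k)
      }
    }
  }
  val
}

#' Ground-truth annual attribution of one or more categories
#'
#' Annual (summer/winter mean) difference between the truth surface and
#' the truth surface with the categories' generative terms removed;
#' positive for sources, negative for sinks. This is the quantity a
#' fitted model's counterfactual attribution tries to recover.
#'
#' @inheritParams simulate_no2_truth
#' @param category category name(s) whose truth terms are dropped
#' @return list with `delta` (a [grid_surface()]), `mean` and `range`
#' @export
truth_attribution <- function(city, params, category) {
  ann <- function(p) {
    s <- simulate_no2_truth(city, p, "summer")$values
    w <- simulate_no2_truth(city, p, "winter")$values
    (s + w) / 2
  }
  d <- ann(params) - ann(drop_truth_term(params, category))
  list(delta = grid_surface(d, city$grid),
       mean = mean(d), range = range(d))
}

# Site sampling ----------------------------------------------------------------

#' Sample passive-sampler monitoring sites
#'
#' Draws `n_summer` sites with a design that over-represents road and
#' vegetation gradients -- 30% of sites placed along freeway/primary
#' corridors at varied perpendicular offsets (30-500 m, resolving the
#' near-road concentration drop-off), 25% in high tree-cover areas, the
#' rest uniform -- then re-samples a random subset of `n_winter` sites in
#' winter. Observations are truth plus Gaussian noise, truncated below at
#' 0.5 ppb. When `params` is supplied, the truth is evaluated exactly at
#' the (continuous) site coordinates; otherwise sites snap to
#' prediction-grid cell centers and truth is read from the surfaces.
#'
#' @param city a [generate_city()] result
#' @param truth_summer,truth_winter [grid_surface()] truth surfaces on the
#'   city's prediction grid
#' @param n_summer,n_winter site counts (winter a subset of summer)
#' @param noise_sd observation noise sd (ppb)
#' @param seed integer seed
#' @param params optional [truth_params()] for exact point evaluation
#' @return data.frame of site observations: `site_id`, `x`, `y`, `season`,
#'   `no2_ppb`
#' @export
sample_sites <- function(city, truth_summer, truth_winter,
                         n_summer = 174, n_winter = 82,
                         noise_sd = 1, seed = 1, params = NULL) {
  if (n_winter > n_summer)
    stop("sample_sites: n_winter must not exceed n_summer", call. = FALSE)
  g <- city$grid
  stopifnot(same_geometry(g, truth_summer$grid),
            same_geometry(g, truth_winter$grid))
  ext <- grid_extent(g)
  margin <- 100
  clampx <- function(v) pmin(pmax(v, ext["xmin"] + margin), ext["xmax"] - margin)
  clampy <- function(v) pmin(pmax(v, ext["ymin"] + margin), ext["ymax"] - margin)

  with_seed(seed, {
    n_road <- round(0.30 * n_summer)
    n_veg <- round(0.25 * n_summer)
    n_unif <- n_summer - n_road - n_veg

    if (is.null(params)) {
      # grid-snapped design: truth read off the prediction surfaces
      pts <- grid_points(g)
      fw <- city$roads[city$roads$class %in% c("freeway", "primary"), ]
      droad <- apply(point_segment_distance(pts$x, pts$y, fw), 1L, min)
      treefrac <- raster_at_points(
        disc_density(city$areal$trees, 300, city$lulc_grid$cellsize),
        city$lulc_grid, pts$x, pts$y)
      pick <- function(pool, n) {
        if (length(pool) < n) stop("site stratum too small", call. = FALSE)
        sample(pool, n)
      }
      taken <- pick(which(droad <= 400), n_road)
      taken <- c(taken, pick(setdiff(which(treefrac >= 0.4), taken), n_veg))
      taken <- c(taken, pick(setdiff(seq_len(nrow(pts)), taken), n_unif))
      sx <- pts$x[taken]; sy <- pts$y[taken]
    } else {
      # continuous design: points along corridors at varied offsets
      fw <- city$roads[city$roads$class %in% c("freeway", "primary"), ]
      len <- sqrt((fw$x1 - fw$x0)^2 + (fw$y1 - fw$y0)^2)
      seg <- sample(nrow(fw), n_road, replace = TRUE, prob = len)
      t <- runif(n_road)
      off <- runif(n_road, 30, 500) * sample(c(-1, 1), n_road, replace = TRUE)
      ux <- (fw$x1 - fw$x0)[seg] / len[seg]; uy <- (fw$y1 - fw$y0)[seg] / len[seg]
      sx <- clampx(fw$x0[seg] + t * (fw$x1 - fw$x0)[seg] - uy * off)
      sy <- clampy(fw$y0[seg] + t * (fw$y1 - fw$y0)[seg] + ux * off)

      lg <- city$lulc_grid
      tdens <- disc_density(city$areal$trees, 300, lg$cellsize)
      veg_cells <- which(tdens >= 0.4)
      if (length(veg_cells) < n_veg)
        veg_cells <- order(tdens, decreasing = TRUE)[seq_len(5 * n_veg)]
      vc <- sample(veg_cells, n_veg)
      iy <- (vc - 1) %% lg$ny + 1; ix <- (vc - 1) %/% lg$ny + 1
      sx <- c(sx, clampx(lg$xmin + (ix - 1 + runif(n_veg)) * lg$cellsize))
      sy <- c(sy, clampy(lg$ymin + (iy - 1 + runif(n_veg)) * lg$cellsize))

      sx <- c(sx, runif(n_unif, ext["xmin"] + margin, ext["xmax"] - margin))
      sy <- c(sy, runif(n_unif, ext["ymin"] + margin, ext["ymax"] - margin))
    }

    ids <- sprintf("S%03d", seq_len(n_summer))
    if (is.null(params)) {
      tS <- raster_at_points(truth_summer$values, g, sx, sy)
      tW <- raster_at_points(truth_winter$values, g, sx, sy)
    } else {
      tS <- truth_at_points(city, params, "summer", sx, sy)
      tW <- truth_at_points(city, params, "winter", sx, sy)
    }
    obsS <- pmax(0.5, tS + rnorm(n_summer, 0, noise_sd))
    win <- sort(sample(seq_len(n_summer), n_winter))
    obsW <- pmax(0.5, tW[win] + rnorm(n_winter, 0, noise_sd))

    rbind(
      data.frame(site_id = ids, x = sx, y = sy, season = "summer",
                 no2_ppb = obsS),
      data.frame(site_id = ids[win], x = sx[win], y = sy[win],
                 season = "winter", no2_ppb = obsW))
  })
}
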