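# Readers and writers ----------------------------------------------------------
#
# Rasters/surfaces travel as ESRI ASCII grid (.asc, plain text, a standard
# raster interchange format); vector networks, emitters and population
# polygons as GeoJSON; tables and reports as CSV; configuration as YAML.
# Numeric round-trips are faithful to ~1e-15 relative (17 significant
# digits are written).

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a surface as an ESRI ASCII grid
#'
#' @param surface a [grid_surface()]
#' @param path output file (.asc)
#' @param nodata value written for no-data cells (default -9999)
#' @export
write_surface_asc <- function(surface, path, nodata = -9999) {
  g <- surface$grid
  hdr <- c(sprintf("ncols %d", g$nx),
           sprintf("nrows %d", g$ny),
           sprintf("xllcorner %.17g", g$xmin),
           sprintf("yllcorner %.17g", g$ymin),
           sprintf("cellsize %.17g", g$cellsize),
           sprintf("NODATA_value %.17g", nodata))
  v <- surface$values
  v[is.na(v)] <- nodata
  rows <- vapply(rev(seq_len(g$ny)), function(iy)
    paste(sprintf("%.17g", v[iy, ]), collapse = " "), character(1))
  writeLines(c(hdr, rows), path)
}

#' Read an ESRI ASCII grid surface
#'
#' @param path input .asc file
#' @return a [grid_surface()] (no-data as NA)
#' @export
read_surface_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(kv) != 2)
      stop("read_surface_asc: malformed header line ", i, ": ", lines[i],
           call. = FALSE)
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("read_surface_asc: missing header fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "), call. = FALSE)
  nx <- hdr$ncols; ny <- hdr$nrows
  body <- lines[i:length(lines)]
  if (length(body) != ny)
    stop("read_surface_asc: expected ", ny, " data rows, found ",
         length(body), call. = FALSE)
  vals <- matrix(NA_real_, ny, nx)
  for (r in seq_len(ny)) {
    row <- as.numeric(strsplit(trimws(body[r]), "\\s+")[[1]])
    if (length(row) != nx)
      stop("read_surface_asc: row ", r, " has ", length(row), " values, ",
           "expected ", nx, call. = FALSE)
    vals[ny - r + 1, ] <- row
  }
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  grid_surface(vals, city_grid(hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                               nx, ny))
}

#' Write a surface as x,y,value CSV
#' @param surface a [grid_surface()]
#' @param path output CSV
#' @export
write_surface_csv <- function(surface, path) {
  write_table_csv(as.data.frame(surface), path)
}

#' Write a data.frame as CSV with full numeric precision
#' @param table data.frame
#' @param path output CSV
#' @export
write_table_csv <- function(table, path) {
  out <- table
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read a CSV table
#' @param path input CSV
#' @return data.frame
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a site observation table
#'
#' Columns `site_id`, `x`, `y`, `season`, `no2_ppb`; every observation
#' must be strictly positive and seasons must be summer/winter with
#' winter sites a subset of summer sites.
#'
#' @param path input CSV
#' @return validated data.frame
#' @export
read_sites_csv <- function(path) {
  d <- read_table_csv(path)
  need <- c("site_id", "x", "y", "season", "no2_ppb")
  if (!all(need %in% colnames(d)))
    stop("read_sites_csv: missing columns: ",
         paste(setdiff(need, colnames(d)), collapse = ", "), call. = FALSE)
  bad <- d$site_id[d$no2_ppb <= 0]
  if (length(bad))
    stop("read_sites_csv: non-positive NO2 at site ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  if (!all(d$season %in% c("summer", "winter")))
    stop("read_sites_csv: season must be summer or winter", call. = FALSE)
  ws <- d$site_id[d$season == "winter"]
  if (!all(ws %in% d$site_id[d$season == "summer"]))
    stop("read_sites_csv: winter sites must be a subset of summer sites",
         call. = FALSE)
  d
}

# GeoJSON ----------------------------------------------------------------------

#' Write a segment network as GeoJSON LineStrings
#' @param segs data.frame with `x0`, `y0`, `x1`, `y1` and optional
#'   property columns (`class`, `aadt`)
#' @param path output .geojson
#' @export
write_network_geojson <- function(segs, path) {
  props <- setdiff(colnames(segs), c("x0", "y0", "x1", "y1"))
  feats <- lapply(seq_len(nrow(segs)), function(i) {
    pr <- as.list(segs[i, props, drop = FALSE])
    list(type = "Feature",
         properties = if (length(pr)) pr else stats::setNames(list(), character(0)),
         geometry = list(type = "LineString",
                         coordinates = list(c(segs$x0[i], segs$y0[i]),
                                            c(segs$x1[i], segs$y1[i]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read a GeoJSON LineString network
#' @param path input .geojson
#' @return data.frame with `x0`, `y0`, `x1`, `y1` and property columns
#' @export
read_network_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop("read_network_geojson: not a FeatureCollection", call. = FALSE)
  rows <- lapply(j$features, function(f) {
    cc <- f$geometry$coordinates
    if (f$geometry$type != "LineString")
      stop("read_network_geojson: expected LineString geometry", call. = FALSE)
    base <- data.frame(x0 = cc[[1]][[1]], y0 = cc[[1]][[2]],
                       x1 = cc[[length(cc)]][[1]], y1 = cc[[length(cc)]][[2]])
    for (p in names(f$properties)) base[[p]] <- f$properties[[p]]
    base
  })
  do.call(rbind, rows)
}

#' Write point features (emitters) as GeoJSON
#' @param points data.frame with `x`, `y` and property columns
#' @param path output .geojson
#' @export
write_points_geojson <- function(points, path) {
  props <- setdiff(colnames(points), c("x", "y"))
  feats <- lapply(seq_len(nrow(points)), function(i) {
    pr <- as.list(points[i, props, drop = FALSE])
    list(type = "Feature",
         properties = if (length(pr)) pr else stats::setNames(list(), character(0)),
         geometry = list(type = "Point",
                         coordinates = c(points$x[i], points$y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
}

#' Read GeoJSON point features
#' @param path input .geojson
#' @return data.frame with `x`, `y` and property columns
#' @export
read_points_geojson <- function(path) {
  j <- jsonlite::read_json(path)
  rows <- lapply(j$features, function(f) {
    base <- data.frame(x = f$geometry$coordinates[[1]],
                       y = f$geometry$coordinates[[2]])
    for (p in names(f$properties)) base[[p]] <- f$properties[[p]]
    base
  })
  do.call(rbind, rows)
}

# Config -----------------------------------------------------------------------

#' Write a pipeline configuration as YAML
#' @param config configuration list
#' @param path output .yaml
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(config, path, precision = 17)
}

#' Read a pipeline configuration from YAML
#' @param path input .yaml
#' @return configuration list
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

# Model serialization ----------------------------------------------------------

#' Serialize a fitted forest to JSON
#'
#' Writes the tree arrays (split variable, threshold, children, node
#' means), in-bag counts and metadata as a documented JSON structure.
#'
#' @param model a [fit_forest()] model
#' @param path output .json
#' @export
write_forest_json <- function(model, path) {
  obj <- list(
    format = "lurf_forest/1",
    ntree = model$ntree, mtry = model$mtry, seed = model$seed,
    min_split = model$min_split,
    predictors = model$predictors,
    response_range = model$response_range,
    trees = lapply(model$trees, function(t)
      list(var = t$var, split = t$split, left = t$left, right = t$right,
           value = t$value)),
    inbag = as.vector(model$inbag),
    n = nrow(model$X))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Read a serialized forest
#'
#' Restores a predict-capable forest. The training matrix itself is not
#' serialized, so OOB recomputation and importance are unavailable on a
#' restored model.
#'
#' @param path input .json
#' @return an object of class `lurf_forest`
#' @export
read_forest_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(o$format) || o$format != "lurf_forest/1")
    stop("read_forest_json: unrecognized format", call. = FALSE)
  # jsonlite simplifies the tree list to a data.frame of list-columns
  tl <- o$trees
  trees <- lapply(seq_along(tl$var), function(i)
    list(var = as.integer(tl$var[[i]]), split = as.numeric(tl$split[[i]]),
         left = as.integer(tl$left[[i]]), right = as.integer(tl$right[[i]]),
         value = as.numeric(tl$value[[i]])))
  structure(list(
    trees = trees,
    inbag = matrix(as.integer(o$inbag), nrow = o$n),
    ntree = o$ntree, mtry = o$mtry, seed = o$seed, min_split = o$min_split,
    predictors = o$predictors, response_range = o$response_range,
    oob_predictions = NULL, X = NULL, y = NULL),
    class = "lurf_forest")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
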