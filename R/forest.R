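# Land-use random forest engine ------------------------------------------------

#' Fit a bagged regression forest
#'
#' CART-style regression trees (variance-reduction splits, midpoint
#' thresholds) grown on bootstrap resamples, with a random `mtry`-subset
#' of predictors eligible at each node. Out-of-bag (OOB) predictions are
#' stored for honest error estimation, and all predictions are restricted
#' to the training response range. Deterministic under a fixed seed: all
#' randomness is drawn from R's RNG in a documented order (see the engine
#' source), which lets brute-force reference implementations reproduce
#' the ensemble exactly.
#'
#' @param train data.frame of predictors (feature columns only)
#' @param response numeric response (ppb), no missing values
#' @param ntree number of trees (>= 1)
#' @param mtry predictors tried per split (1..p)
#' @param seed integer seed
#' @param min_split minimum node size eligible for splitting (nodes
#'   smaller than this become leaves); regression-forest convention 5
#' @param max_depth maximum tree depth (0 = unlimited, the default);
#'   shallow forests are used where coarse, interpretable strata matter,
#'   e.g. the phase-1 selection forest
#' @return object of class `lurf_forest`
#' @export
fit_forest <- function(train, response, ntree = 500, mtry = max(1, floor(ncol(train) / 3)),
                       seed = 1, min_split = 5, max_depth = 0) {
  X <- as.matrix(train)
  storage.mode(X) <- "double"
  y <- as.numeric(response)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("fit_forest: need at least 10 observations", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("fit_forest: missing values", call. = FALSE)
  if (mtry > p) stop("fit_forest: mtry exceeds number of predictors",
                     call. = FALSE)
  if (ntree < 1) stop("fit_forest: ntree must be >= 1", call. = FALSE)
  if (length(unique(y)) == 1)
    warning("fit_forest: constant response; trees are single leaves")

  fit <- with_seed(seed, rf_fit_cpp(X, y, as.integer(ntree),
                                    as.integer(mtry), as.integer(min_split),
                                    as.integer(max_depth)))
  oob <- rf_oob_predict_cpp(fit$trees, fit$inbag, X)
  rng <- range(y)
  structure(list(
    trees = fit$trees, inbag = fit$inbag,
    ntree = ntree, mtry = mtry, seed = seed, min_split = min_split,
    max_depth = max_depth,
    predictors = colnames(train), response_range = rng,
    oob_predictions = pmin(rng[2], pmax(rng[1], oob)),
    X = X, y = y),
    class = "lurf_forest")
}

#' @export
print.lurf_forest <- function(x, ...) {
  cat(sprintf("<lurf_forest> %d trees, mtry %d, %d predictors, n = %d\n",
              x$ntree, x$mtry, length(x$predictors), length(x$y)))
  ok <- !is.na(x$oob_predictions)
  cat(sprintf("  OOB RMSE %.3f ppb; response range [%.2f, %.2f]\n",
              sqrt(mean((x$oob_predictions[ok] - x$y[ok])^2)),
              x$response_range[1], x$response_range[2]))
  invisible(x)
}

#' Predict from a fitted forest
#'
#' Ensemble-mean predictions, clamped to the training response range
#' (tree leaf means already lie within it; the clamp makes the bound an
#' explicit contract).
#'
#' @param object a [fit_forest()] model
#' @param newdata data.frame containing the model's predictor columns
#' @param ... unused
#' @return numeric predictions (ppb)
#' @export
predict.lurf_forest <- function(object, newdata, ...) {
  miss <- setdiff(object$predictors, colnames(newdata))
  if (length(miss))
    stop("predict.lurf_forest: missing predictors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[, object$predictors, drop = FALSE])
  storage.mode(X) <- "double"
  p <- rf_predict_cpp(object$trees, X)
  pmin(object$response_range[2], pmax(object$response_range[1], p))
}

#' Out-of-bag RMSE of a forest
#' @param model a [fit_forest()] model
#' @return OOB root-mean-square error (ppb)
#' @export
oob_rmse <- function(model) {
  ok <- !is.na(model$oob_predictions)
  sqrt(mean((model$oob_predictions[ok] - model$y[ok])^2))
}

#' Permutation variable importance
#'
#' Mean increase in per-tree out-of-bag squared-error loss when a
#' predictor is permuted (ppb^2). In `"marginal"` mode each predictor is
#' permuted freely across OOB observations. In `"conditional"` mode
#' (Strobl-style) a predictor is permuted within strata formed by the
#' split points that covariates correlated with it (|r| above
#' `cor_threshold`) use in each tree, which deflates the importance that
#' plain permutation attributes to merely-correlated predictors. Raw
#' (possibly negative) values are returned in `raw_importance`; the
#' `importance` column floors them at zero for reporting.
#'
#' @param model a [fit_forest()] model
#' @param data data.frame with the model's predictors (defaults to the
#'   training data stored in the model)
#' @param response response values matching `data`
#' @param mode `"marginal"` or `"conditional"`
#' @param cor_threshold correlation threshold for conditioning (default
#'   0.2, the published conditional-importance default)
#' @param n_perm number of independent permutation repetitions averaged
#'   (variance reduction for near-zero conditional importances)
#' @param cond_exclude optional logical p x p matrix; TRUE entries are
#'   removed from the conditioning sets (row = conditioning variable,
#'   column = permuted variable)
#' @param cond_groups optional character vector (one label per model
#'   predictor): variables sharing a label are near-duplicate encodings
#'   (e.g. the twelve radii of one buffer category) and are excluded from
#'   each other's conditioning strata -- permuting a variable within
#'   strata of its own near-copies would permute nothing
#' @param seed integer seed for the permutations
#' @return data.frame: `variable`, `importance`, `raw_importance`, with
#'   attributes `mode` and `cor_threshold`
#' @export
permutation_importance <- function(model, data = NULL, response = NULL,
                                   mode = c("conditional", "marginal"),
                                   cor_threshold = 0.2, cond_groups = NULL,
                                   cond_exclude = NULL, n_perm = 1, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(data)) {
    X <- model$X; y <- model$y
  } else {
    miss <- setdiff(model$predictors, colnames(data))
    if (length(miss))
      stop("permutation_importance: variable absent from data: ",
           paste(miss, collapse = ", "), call. = FALSE)
    X <- as.matrix(data[, model$predictors, drop = FALSE])
    storage.mode(X) <- "double"
    y <- as.numeric(response)
  }
  p <- ncol(X)
  cond <- matrix(FALSE, p, p)
  if (mode == "conditional") {
    sdv <- apply(X, 2, sd)
    ok <- sdv > 0
    if (any(ok)) {
      cm <- suppressWarnings(abs(cor(X[, ok, drop = FALSE])))
      cm[is.na(cm)] <- 0
      cond[ok, ok] <- cm > cor_threshold
    }
    diag(cond) <- FALSE
    if (!is.null(cond_groups)) {
      if (length(cond_groups) != p)
        stop("permutation_importance: cond_groups must have one label per ",
             "predictor", call. = FALSE)
      cond[outer(cond_groups, cond_groups, `==`)] <- FALSE
    }
    if (!is.null(cond_exclude)) cond[cond_exclude] <- FALSE
  }
  imps <- vapply(seq_len(n_perm), function(k)
    with_seed(seed + k - 1L, rf_importance_cpp(
      model$trees, model$inbag, X, y,
      if (mode == "conditional") 1L else 0L, cond)),
    numeric(p))
  imp <- rowMeans(matrix(imps, nrow = p))
  out <- data.frame(variable = model$predictors,
                    importance = pmax(0, imp),
                    raw_importance = imp,
                    stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "cor_threshold") <- if (mode == "conditional") cor_threshold else NA
  out
}

# Two-phase predictor selection -------------------------------------------------

#' Phase 1: pick the most important buffer radius per category
#'
#' Fits one forest on the full buffer feature table and, for each
#' land-use category, selects the radius whose column has the highest
#' conditional permutation importance, reducing ~200 candidate predictors
#' to one per category plus the point features x, y and elevation.
#' Categories whose columns are all zero are flagged degenerate and
#' assigned the smallest radius.
#'
#' @param train feature table including `x`, `y`, `elevation` and the
#'   buffered columns
#' @param response response values (ppb)
#' @param radii buffer radii present in the table
#' @param categories buffered categories present in the table
#' @param ntree,mtry,seed forest configuration for the selection forest
#' @param max_depth depth of the shallow selection trees (default 4):
#'   with ~200 correlated candidates, conditional strata built from deep
#'   trees fragment the out-of-bag sample into singletons and destroy the
#'   importance signal; shallow trees mirror the early-stopped trees of
#'   conditional-inference forests
#' @param cor_threshold conditional-importance correlation threshold
#' @return object of class `selected_variables`: data.frame
#'   (`category`, `radius`, `column`, `degenerate`) plus the point
#'   features, with the importance table as attribute `importance`
#' @export
phase1_select_buffers <- function(train, response, radii = default_radii(),
                                  categories = lulc_categories()$all,
                                  ntree = 300, mtry = NULL, seed = 1,
                                  max_depth = 4, cor_threshold = 0.2,
                                  n_perm = 3) {
  radii <- sort(as.integer(radii))
  cols <- unlist(lapply(sort(categories), feature_column, radius = radii))
  cols <- c("x", "y", "elevation", cols)
  miss <- setdiff(cols, colnames(train))
  if (length(miss))
    stop("phase1_select_buffers: missing columns: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  X <- train[, cols, drop = FALSE]
  if (is.null(mtry)) mtry <- max(1, floor(ncol(X) / 3))
  fit <- fit_forest(X, response, ntree = ntree, mtry = mtry, seed = seed,
                    max_depth = max_depth)
  # sibling radii stay in each other's conditioning sets: stratifying a
  # radius by its near-duplicate siblings isolates the unique signal of
  # that radius, which is what discriminates buffer sizes within a
  # category. The freeway-length and freeway-VMT encodings of the same
  # physical source, however, are excluded from each other's strata:
  # conditioning either on the other leaves only the traffic-volume
  # residue and reduces both radius profiles to noise.
  twin_groups <- rep("", ncol(X))
  names(twin_groups) <- colnames(X)
  fw_cols <- grepl("^(freeway|vmt_freeway)_r", colnames(X))
  twin_groups[fw_cols] <- sub("_r\\d+$", "", colnames(X)[fw_cols])
  twin <- outer(twin_groups, twin_groups,
                function(a, b) a != b & a != "" & b != "")
  imp <- permutation_importance(fit, mode = "conditional",
                                cor_threshold = cor_threshold,
                                cond_exclude = twin, n_perm = n_perm,
                                seed = seed)

  sel <- do.call(rbind, lapply(sort(categories), function(cat) {
    cc <- feature_column(cat, radii)
    degenerate <- all(abs(as.matrix(train[, cc])) == 0)
    if (degenerate) {
      r <- radii[1]
    } else {
      iv <- imp$raw_importance[match(cc, imp$variable)]
      r <- radii[which.max(iv)]
    }
    data.frame(category = cat, radius = r, column = feature_column(cat, r),
               degenerate = degenerate, stringsAsFactors = FALSE)
  }))
  structure(list(buffers = sel,
                 point_features = c("x", "y", "elevation")),
            class = "selected_variables", importance = imp)
}

#' Predictor columns named by a selection
#' @param selected a [phase1_select_buffers()] result
#' @return character vector of column names (point features first)
#' @export
selected_columns <- function(selected) {
  c(selected$point_features, selected$buffers$column)
}

#' @export
print.selected_variables <- function(x, ...) {
  cat(sprintf("<selected_variables> %d categories + %d point features\n",
              nrow(x$buffers), length(x$point_features)))
  print(x$buffers, row.names = FALSE)
  invisible(x)
}

#' Phase 2: hyperparameter sweep over ntree x mtry x seeds
#'
#' Fits every (ntree, mtry) combination for each seed on the reduced
#' predictor set, records out-of-bag RMSE, and selects the robust model:
#' the combination minimizing mean OOB RMSE across seeds, ties broken
#' toward smaller ntree then smaller mtry. The selected model is refitted
#' with the first seed.
#'
#' @param train feature table (reduced predictors are taken from
#'   `selected`)
#' @param response response values (ppb)
#' @param selected a [phase1_select_buffers()] result
#' @param ntree_grid,mtry_grid hyperparameter grids (non-empty)
#' @param seeds integer seeds swept
#' @return list: `model` (the selected [fit_forest()]), `ntree`, `mtry`,
#'   `sweep` (per-combination-per-seed OOB RMSE table), `summary`
#'   (mean OOB RMSE per combination)
#' @export
phase2_sweep <- function(train, response, selected,
                         ntree_grid = c(500, 1000, 2000, 3000, 4000, 5000),
                         mtry_grid = 1:8, seeds = 1:3) {
  if (!length(ntree_grid) || !length(mtry_grid) || !length(seeds))
    stop("phase2_sweep: empty grid", call. = FALSE)
  cols <- selected_columns(selected)
  X <- train[, cols, drop = FALSE]
  p <- ncol(X)
  mtry_grid <- mtry_grid[mtry_grid <= p]
  if (!length(mtry_grid))
    stop("phase2_sweep: all mtry values exceed predictor count", call. = FALSE)

  combos <- expand.grid(ntree = sort(ntree_grid), mtry = sort(mtry_grid))
  sweep <- do.call(rbind, lapply(seeds, function(sd) {
    rmse <- mapply(function(nt, mt)
      oob_rmse(fit_forest(X, response, ntree = nt, mtry = mt, seed = sd)),
      combos$ntree, combos$mtry)
    cbind(combos, seed = sd, oob_rmse = rmse)
  }))
  agg <- aggregate(oob_rmse ~ ntree + mtry, data = sweep, FUN = mean)
  agg <- agg[order(agg$oob_rmse, agg$ntree, agg$mtry), ]
  best <- agg[1, ]
  model <- fit_forest(X, response, ntree = best$ntree, mtry = best$mtry,
                      seed = seeds[1])
  list(model = model, ntree = best$ntree, mtry = best$mtry,
       selected = selected, sweep = sweep, summary = agg)
}

#' The classic hyperparameter sweep grid
#'
#' The full ntree (500..5000) x mtry (1..8) exploration grid used for
#' model selection at study scale; desk-scale configurations typically
#' use a reduced grid.
#' @return list with `ntree` and `mtry`
#' @export
classic_sweep_grid <- function() {
  list(ntree = c(500, 1000, 2000, 3000, 4000, 5000), mtry = 1:8)
}
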