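# Land-use regression baseline -------------------------------------------------

# variance inflation factors for a design matrix (columns = model terms)
vif_values <- function(X) {
  p <- ncol(X)
  if (p <= 1) return(stats::setNames(rep(1, p), colnames(X)))
  out <- numeric(p)
  for (j in seq_len(p)) {
    r2 <- summary(lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    out[j] <- 1 / max(1e-12, 1 - r2)
  }
  stats::setNames(out, colnames(X))
}

# drop variables until all VIFs are at or below the ceiling
enforce_vif <- function(vars, data, ceiling) {
  vars <- vars[vapply(vars, function(v) sd(data[[v]]) > 0, logical(1))]
  while (length(vars) > 1) {
    v <- vif_values(as.matrix(data[, vars, drop = FALSE]))
    if (max(v) <= ceiling) break
    vars <- vars[-which.max(v)]
  }
  vars
}

kfold_rmse <- function(vars, data, response, k, seed) {
  n <- nrow(data)
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  err <- numeric(n)
  for (f in seq_len(k)) {
    te <- folds == f
    fml <- stats::as.formula(paste(".y ~", paste(vars, collapse = " + ")))
    d <- cbind(.y = response, data[, vars, drop = FALSE])
    fit <- lm(fml, data = d[!te, , drop = FALSE])
    err[te] <- response[te] - predict(fit, d[te, , drop = FALSE])
  }
  sqrt(mean(err^2))
}

#' Fit the stepwise land-use regression baseline
#'
#' The classical LUR pipeline on the reduced predictor set: (1) correlation
#' pruning -- for any predictor pair with |r| above `cor_threshold` the
#' later column is dropped; (2) stepwise AIC searches (forward and both
#' directions from the null model, backward and both from the full model)
#' yielding up to four candidate models; (3) each candidate is thinned
#' until every variance inflation factor is at or below `vif_ceiling`;
#' (4) the final model is the candidate with the lowest k-fold
#' cross-validated RMSE (k = 6 by convention). If no multi-variable
#' candidate survives, the best single predictor is used, with a warning.
#'
#' @param train feature table
#' @param response response values (ppb)
#' @param selected a [phase1_select_buffers()] result naming the reduced
#'   predictor set
#' @param vif_ceiling maximum tolerated VIF (default 10)
#' @param k number of cross-validation folds (default 6)
#' @param cor_threshold correlation-pruning threshold on |r| (default 0.7)
#' @param seed integer seed for fold assignment
#' @return object of class `lur_model` with coefficients, retained
#'   variables, AIC, VIFs and the candidate comparison table
#' @export
fit_lur <- function(train, response, selected, vif_ceiling = 10, k = 6,
                    cor_threshold = 0.7, seed = 1) {
  if (k < 2) stop("fit_lur: k must be >= 2", call. = FALSE)
  vars <- selected_columns(selected)
  vars <- vars[vars %in% colnames(train)]
  data <- train[, vars, drop = FALSE]
  y <- as.numeric(response)

  # correlation pruning: keep the earlier of any highly correlated pair
  keep <- vars[vapply(vars, function(v) sd(data[[v]]) > 0, logical(1))]
  i <- 1
  while (i < length(keep)) {
    r <- abs(vapply(keep[-seq_len(i)], function(v)
      cor(data[[keep[i]]], data[[v]]), numeric(1)))
    keep <- c(keep[seq_len(i)], keep[-seq_len(i)][r <= cor_threshold])
    i <- i + 1
  }

  d <- cbind(.y = y, data[, keep, drop = FALSE])
  full_fml <- stats::as.formula(paste(".y ~", paste(keep, collapse = " + ")))
  null_fit <- lm(.y ~ 1, data = d)
  full_fit <- lm(full_fml, data = d)
  scope <- list(lower = .y ~ 1, upper = full_fml)

  cand_fits <- list(
    forward = stats::step(null_fit, scope = scope, direction = "forward",
                          trace = 0),
    both_null = stats::step(null_fit, scope = scope, direction = "both",
                            trace = 0),
    backward = stats::step(full_fit, scope = scope, direction = "backward",
                           trace = 0),
    both_full = stats::step(full_fit, scope = scope, direction = "both",
                            trace = 0))

  cand_vars <- unique(lapply(cand_fits, function(f)
    enforce_vif(attr(stats::terms(f), "term.labels"), d, vif_ceiling)))
  cand_vars <- Filter(length, cand_vars)
  if (!length(cand_vars)) {
    warning("fit_lur: no candidate passed the VIF ceiling; ",
            "falling back to the best single predictor")
    r2 <- vapply(keep, function(v) cor(d[[v]], y)^2, numeric(1))
    cand_vars <- list(keep[which.max(r2)])
  }

  cv <- vapply(cand_vars, kfold_rmse, numeric(1),
               data = d, response = y, k = k, seed = seed)
  best <- cand_vars[[which.min(cv)]]
  fml <- stats::as.formula(paste(".y ~", paste(best, collapse = " + ")))
  fit <- lm(fml, data = d)

  structure(list(
    coefficients = coef(fit),
    variables = best,
    aic = stats::AIC(fit),
    vif = vif_values(as.matrix(d[, best, drop = FALSE])),
    cv_rmse = min(cv),
    candidates = data.frame(
      model = vapply(cand_vars, paste, character(1), collapse = " + "),
      cv_rmse = cv),
    fit = fit),
    class = "lur_model")
}

#' @export
print.lur_model <- function(x, ...) {
  cat(sprintf("<lur_model> %d terms, AIC %.1f, %d-fold CV RMSE %.3f ppb\n",
              length(x$variables), x$aic, 6, x$cv_rmse))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predict from a fitted LUR model
#'
#' Linear predictions; unlike the forest these are not restricted to the
#' training response range.
#'
#' @param object a [fit_lur()] model
#' @param newdata data.frame containing the retained variables
#' @param ... unused
#' @return numeric predictions (ppb)
#' @export
predict.lur_model <- function(object, newdata, ...) {
  miss <- setdiff(object$variables, colnames(newdata))
  if (length(miss))
    stop("predict.lur_model: missing predictors: ",
         paste(miss, collapse = ", "), call. = FALSE)
  as.vector(predict(object$fit, newdata))
}
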