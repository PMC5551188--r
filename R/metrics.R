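# Evaluation metrics -----------------------------------------------------------

#' Model performance metrics against observations
#'
#' Standard air-quality evaluation metrics of a modeled series against
#' observations: normalized mean bias `NMB = mean((mod - obs) / obs)`,
#' normalized mean error `NME = mean(|mod - obs| / obs)`, RMSE, MAE, and
#' goodness of fit R^2 computed as the squared Pearson correlation (the
#' conventional hold-out-validation variant; set `r2_variant =
#' "explained"` for 1 - SS_res / SS_tot). NMB measures systematic over-
#' or under-prediction; NME the typical relative discrepancy.
#'
#' @param modeled,observed numeric series of equal length (ppb);
#'   observations must be strictly positive
#' @param r2_variant `"correlation"` (default) or `"explained"`
#' @return one-row data.frame: `n`, `r2`, `normalized_mean_bias`,
#'   `normalized_mean_error`, `rmse`, `mae`. `r2` is `NA` when either
#'   series is constant (flagged by attribute `r2_undefined`).
#' @export
compute_metrics <- function(modeled, observed,
                            r2_variant = c("correlation", "explained")) {
  r2_variant <- match.arg(r2_variant)
  if (length(modeled) != length(observed))
    stop("compute_metrics: length mismatch", call. = FALSE)
  bad <- which(observed <= 0)
  if (length(bad))
    stop("compute_metrics: non-positive observation at record ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  d <- modeled - observed
  r2 <- NA_real_
  undefined <- sd(observed) == 0 || sd(modeled) == 0
  if (!undefined) {
    r2 <- if (r2_variant == "correlation") cor(modeled, observed)^2
          else 1 - sum(d^2) / sum((observed - mean(observed))^2)
  }
  out <- data.frame(
    n = length(observed),
    r2 = r2,
    normalized_mean_bias = mean(d / observed),
    normalized_mean_error = mean(abs(d) / observed),
    rmse = sqrt(mean(d^2)),
    mae = mean(abs(d)))
  attr(out, "r2_undefined") <- undefined
  out
}

#' Compare two surfaces cell by cell
#'
#' Pearson correlation, the least-squares line mapping surface `b` to
#' surface `a` (slope, intercept, adjusted R^2), and the normalized mean
#' bias/error of `a` relative to `b`, over cells valid in both surfaces.
#'
#' @param a,b [grid_surface()] objects on the same geometry
#' @return one-row data.frame: `n`, `pearson_r`, `slope`, `intercept`,
#'   `adj_r2`, `normalized_mean_bias`, `normalized_mean_error`
#' @export
compare_surfaces <- function(a, b) {
  if (!same_geometry(a$grid, b$grid))
    stop("compare_surfaces: geometry mismatch", call. = FALSE)
  ok <- !is.na(a$values) & !is.na(b$values)
  if (!any(ok))
    stop("compare_surfaces: no jointly valid cells", call. = FALSE)
  va <- a$values[ok]; vb <- b$values[ok]
  if (any(vb <= 0))
    stop("compare_surfaces: reference surface must be positive for ",
         "normalized bias", call. = FALSE)
  fit <- lm(va ~ vb)
  # a perfect fit (identical surfaces) is legitimate input; lm's summary
  # warns about it
  adj <- suppressWarnings(summary(fit)$adj.r.squared)
  data.frame(
    n = sum(ok),
    pearson_r = cor(va, vb),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    adj_r2 = adj,
    normalized_mean_bias = mean((va - vb) / vb),
    normalized_mean_error = mean(abs(va - vb) / vb))
}
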