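# Phase-separation statistics: turbidity-onset threshold extraction,
# simple linear regression reporting, PCA of virial feature tables, and
# multilinear regression of thresholds on selected principal components.

#' Construct a turbidity series
#'
#' @param concentration module concentrations in uM, strictly increasing.
#' @param A340 absorbance at 340 nm (>= 0) at each concentration.
#' @param variant,pH optional condition labels.
#' @return data frame of class `turbidity_series`.
#' @export
turbidity_series <- function(concentration, A340, variant = "", pH = NA) {
  if (length(concentration) != length(A340))
    stopf("concentration and A340 lengths differ")
  if (any(diff(concentration) <= 0))
    stopf("concentrations must be strictly increasing")
  if (any(A340 < 0)) stopf("A340 must be >= 0")
  out <- data.frame(concentration = concentration, A340 = A340)
  attr(out, "variant") <- variant
  attr(out, "pH") <- pH
  class(out) <- c("turbidity_series", "data.frame")
  out
}

#' Phase-separation threshold from a turbidity series
#'
#' Finds the first (onset) concentration whose absorbance exceeds `onset`,
#' fits an ordinary least-squares line through the three points at
#' strictly greater concentrations, and returns that line's x-intercept as
#' the threshold concentration. If no point exceeds the onset, or fewer
#' than three points lie beyond it, no threshold is reported (the sample
#' is treated as not phase-separating up to the maximum tested
#' concentration).
#'
#' @param s a [turbidity_series()] with at least 4 points.
#' @param onset absorbance onset value (default 0.1).
#' @return list of class `threshold_estimate`: `threshold` (uM, or `NA`),
#'   `status` (`"ok"`, `"no_onset"` or `"insufficient_points"`),
#'   `max_tested`, and for `"ok"` the fitted `slope` and `intercept`.
#'   A negative x-intercept on pathological input is reported as-is with a
#'   warning.
#' @export
extract_threshold <- function(s, onset = 0.1) {
  if (nrow(s) < 4L) stopf("need at least 4 turbidity points")
  if (any(diff(s$concentration) <= 0))
    stopf("concentrations must be strictly increasing")
  max_tested <- max(s$concentration)
  first_above <- which(s$A340 > onset)[1]
  mk <- function(threshold, status, slope = NA_real_, intercept = NA_real_) {
    structure(list(threshold = threshold, status = status,
                   max_tested = max_tested, slope = slope,
                   intercept = intercept, onset = onset),
              class = "threshold_estimate")
  }
  if (is.na(first_above)) return(mk(NA_real_, "no_onset"))
  beyond <- which(s$concentration > s$concentration[first_above])
  if (length(beyond) < 3L) return(mk(NA_real_, "insufficient_points"))
  use <- beyond[1:3]
  fit <- stats::lm(A340 ~ concentration, data = s[use, , drop = FALSE])
  b <- stats::coef(fit)
  if (abs(b[[2]]) < .Machine$double.eps)
    return(mk(NA_real_, "insufficient_points"))
  x0 <- -b[[1]] / b[[2]]
  if (x0 < 0) warnf("negative x-intercept (%.3g uM) from pathological series", x0)
  mk(x0, "ok", slope = b[[2]], intercept = b[[1]])
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<threshold_estimate> %.4g uM (onset A340 > %g)\n",
                x$threshold, x$onset))
  } else {
    cat(sprintf("<threshold_estimate> none (%s); > %g uM tested\n",
                x$status, x$max_tested))
  }
  invisible(x)
}

#' Simple linear regression with R-squared
#'
#' Ordinary least squares of `y` on `x`, reporting the slope, intercept and
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param x,y numeric vectors (>= 3 points).
#' @return list with `slope`, `intercept`, `r_squared`, `fit` (the `lm`).
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  if (length(x) < 3L) stopf("need at least 3 points")
  if (stats::var(x) == 0) stopf("zero variance in x")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Assemble a virial feature table
#'
#' Rows keyed by `(variant, pH)` with the four virial features (A2 and A23
#' for the open and closed conformations, mol mL g^-2) and the measured
#' phase-separation threshold. Missing thresholds (conditions that did not
#' phase-separate up to the maximum tested concentration) are imputed at
#' `impute` and flagged.
#'
#' @param variant,pH condition keys.
#' @param A2_open,A2_closed,A23_open,A23_closed virial features.
#' @param threshold measured thresholds in uM; `NA` marks censored rows.
#' @param impute imputation value in uM for censored rows (default 400).
#' @return data frame of class `feature_table` with an added logical
#'   column `imputed`.
#' @export
feature_table <- function(variant, pH, A2_open, A2_closed, A23_open,
                          A23_closed, threshold, impute = 400) {
  out <- data.frame(variant = variant, pH = pH, A2_open = A2_open,
                    A2_closed = A2_closed, A23_open = A23_open,
                    A23_closed = A23_closed, threshold = threshold)
  if (any(!is.finite(as.matrix(out[, 3:6]))))
    stopf("feature cells must be complete and finite")
  out$imputed <- is.na(out$threshold)
  out$threshold[out$imputed] <- impute
  class(out) <- c("feature_table", "data.frame")
  out
}

.feature_cols <- c("A2_open", "A2_closed", "A23_open", "A23_closed")

#' Principal component analysis of virial features
#'
#' Column-centers the feature matrix (optionally standardizing) and
#' decomposes it by singular values. Component signs are fixed by the
#' convention that each component's largest-magnitude loading is positive,
#' so results are deterministic.
#'
#' @param features a [feature_table()], or a numeric matrix/data frame of
#'   feature columns.
#' @param standardize scale columns to unit variance before the
#'   decomposition (default `FALSE`: the four virial features share
#'   units).
#' @return list of class `virial_pca`: `scores` (rows x components,
#'   columns `PC1`...), `loadings` (features x components), `sdev`,
#'   `explained` (fraction of variance per component), `center`, `scale`.
#' @export
virial_pca <- function(features, standardize = FALSE) {
  x <- if (inherits(features, "feature_table")) {
    as.matrix(features[, .feature_cols])
  } else as.matrix(features)
  if (nrow(x) < 2L) stopf("need at least 2 rows")
  pr <- stats::prcomp(x, center = TRUE, scale. = standardize)
  if (all(pr$sdev < 1e-14)) stopf("rank-0 input: no variance to decompose")
  # deterministic sign: largest |loading| positive in every component
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  structure(list(scores = pr$x, loadings = pr$rotation, sdev = pr$sdev,
                 explained = pr$sdev^2 / sum(pr$sdev^2),
                 center = pr$center, scale = pr$scale),
            class = "virial_pca")
}

#' @export
print.virial_pca <- function(x, ...) {
  cat("<virial_pca> explained variance:",
      paste(sprintf("%s %.1f%%", colnames(x$scores),
                    100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}

#' Multilinear regression of thresholds on principal components
#'
#' Ordinary least squares of the measured (or imputed) threshold
#' concentrations on a selected subset of PCA scores, defaulting to PC1
#' and PC4. All rows are weighted equally, including imputed ones. Trial
#' fits on every single component are reported alongside to document the
#' component selection.
#'
#' @param scores score matrix from [virial_pca()] (or any numeric matrix
#'   with named columns).
#' @param thresholds numeric response (uM), one per row of `scores`.
#' @param select character vector of component names (default
#'   `c("PC1", "PC4")`).
#' @return list of class `regression_fit`: `coefficients` (named, per
#'   selected component), `intercept`, `r_squared`, `predictions`,
#'   `residuals`, `selected_components`, `trial_r_squared` (R^2 of a
#'   single-component fit for every available component), and the `lm`
#'   object.
#' @export
mlr_on_components <- function(scores, thresholds,
                              select = c("PC1", "PC4")) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(thresholds))
    stopf("scores and thresholds disagree on row count")
  missing_pc <- setdiff(select, colnames(scores))
  if (length(missing_pc)) stopf("selected component(s) not available: %s",
                                paste(missing_pc, collapse = ", "))
  if (nrow(scores) < length(select) + 1L)
    stopf("fewer rows than regression parameters")
  df <- data.frame(threshold = thresholds,
                   scores[, select, drop = FALSE], check.names = FALSE)
  fml <- stats::as.formula(paste("threshold ~",
                                 paste(sprintf("`%s`", select), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((thresholds - mean(thresholds))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  trial <- vapply(colnames(scores), function(pc) {
    f <- stats::lm(thresholds ~ scores[, pc])
    1 - sum(stats::resid(f)^2) / max(ss_tot, .Machine$double.xmin)
  }, numeric(1))
  cf <- stats::coef(fit)
  structure(list(coefficients = cf[-1], intercept = unname(cf[1]),
                 r_squared = r2, predictions = unname(stats::fitted(fit)),
                 residuals = unname(stats::resid(fit)),
                 selected_components = select, trial_r_squared = trial,
                 fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> threshold ~ %s; R^2 = %.3f\n",
              paste(x$selected_components, collapse = " + "), x$r_squared))
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "),
      sprintf("; intercept = %.4g\n", x$intercept))
  invisible(x)
}
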