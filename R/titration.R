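# Hill-equation fitting of chemical-shift pH titrations.
# (The Henderson-Hasselbalch protonated fraction itself lives with the
# protonation machinery in structure.R.)

#' Construct a titration series
#'
#' @param pH numeric vector of pH values (distinct).
#' @param shift observed chemical shifts (ppm) at those pH values.
#' @param nucleus_label optional label, e.g. `"H35 1He"`.
#' @return data frame of class `titration_series` with columns `pH`,
#'   `shift`.
#' @export
titration_series <- function(pH, shift, nucleus_label = "") {
  if (length(pH) != length(shift)) stopf("pH and shift lengths differ")
  if (anyDuplicated(pH)) stopf("pH values must be distinct")
  out <- data.frame(pH = pH, shift = shift)
  out <- out[order(out$pH), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nucleus_label") <- nucleus_label
  class(out) <- c("titration_series", "data.frame")
  out
}

# two-plateau base-10 logistic: observed shift as a function of pH
.hill_curve <- function(pH, pKa, hill_n, shift_prot, shift_neutral) {
  shift_neutral + (shift_prot - shift_neutral) /
    (1 + 10^(hill_n * (pH - pKa)))
}

#' Fit a modified Hill equation to a pH titration
#'
#' Nonlinear least squares of the two-plateau logistic
#' `shift = shift_neutral + (shift_prot - shift_neutral) /
#' (1 + 10^(n (pH - pKa)))`, where `shift_prot` and `shift_neutral` are
#' the chemical shifts of the protonated and neutral forms of the
#' imidazole ring. Initial values are taken from the series extremes
#' (plateaus), the midpoint crossing (pKa) and `n = 1`.
#'
#' @param series a [titration_series()] (>= 4 points spanning the
#'   transition).
#' @param fix_n if non-`NULL`, the Hill coefficient is fixed at this value
#'   instead of being fitted.
#' @param ci `"linear"` (default) for Wald 95% intervals from the fit
#'   covariance, or `"monte_carlo"` for a parametric resample of the fit
#'   using the residual standard deviation.
#' @param n_mc Monte Carlo resamples when `ci = "monte_carlo"`.
#' @param mc_seed seed for the Monte Carlo resampling.
#' @return list of class `titration_fit`: `pKa`, `hill_n`, `shift_prot`,
#'   `shift_neutral`, `ci` (2-column matrix of 95% bounds per parameter),
#'   `residual_sd`, and the underlying `nls` fit.
#' @export
fit_hill <- function(series, fix_n = NULL, ci = c("linear", "monte_carlo"),
                     n_mc = 200, mc_seed = 1L) {
  ci <- match.arg(ci)
  if (nrow(series) < 4L) stopf("need at least 4 titration points")
  rng <- range(series$shift)
  if (diff(rng) < 1e-8) stopf("flat titration series: no transition to fit")
  # initialization: plateaus from the extremes, pKa from midpoint crossing
  lowside <- series$shift[which.min(series$pH)]
  highside <- series$shift[which.max(series$pH)]
  mid <- (lowside + highside) / 2
  pKa0 <- series$pH[which.min(abs(series$shift - mid))]
  start <- list(pKa = pKa0, shift_prot = lowside, shift_neutral = highside)
  df <- as.data.frame(series)
  fit <- tryCatch({
    if (is.null(fix_n)) {
      start$hill_n <- 1
      minpack.lm::nlsLM(
        shift ~ .hill_curve(pH, pKa, hill_n, shift_prot, shift_neutral),
        data = df, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      n_fixed <- fix_n
      minpack.lm::nlsLM(
        shift ~ .hill_curve(pH, pKa, n_fixed, shift_prot, shift_neutral),
        data = df, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) stopf("Hill fit did not converge: %s", conditionMessage(e)))
  est <- stats::coef(fit)
  if (!is.null(fix_n)) est <- c(est, hill_n = fix_n)
  if (abs(est[["shift_prot"]] - est[["shift_neutral"]]) < 1e-10)
    stopf("degenerate fit: protonated and neutral shifts coincide")

  if (ci == "linear") {
    sm <- summary(fit)
    se <- sm$coefficients[, "Std. Error"]
    tq <- stats::qt(0.975, stats::df.residual(fit))
    cims <- cbind(lower = stats::coef(fit) - tq * se,
                  upper = stats::coef(fit) + tq * se)
  } else {
    sigma <- summary(fit)$sigma
    pred <- stats::fitted(fit)
    mc_formula <- if (is.null(fix_n)) {
      shift ~ .hill_curve(pH, pKa, hill_n, shift_prot, shift_neutral)
    } else {
      n_fixed <- fix_n
      shift ~ .hill_curve(pH, pKa, n_fixed, shift_prot, shift_neutral)
    }
    environment(mc_formula) <- environment()
    sims <- with_local_seed(mc_seed, {
      replicate(n_mc, {
        yb <- pred + stats::rnorm(length(pred), 0, sigma)
        dfb <- df; dfb$shift <- yb
        fb <- tryCatch(minpack.lm::nlsLM(
          mc_formula,
          data = dfb, start = as.list(stats::coef(fit)),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(fb)) rep(NA_real_, length(stats::coef(fit)))
        else stats::coef(fb)
      })
    })
    cims <- t(apply(sims, 1, stats::quantile, c(0.025, 0.975), na.rm = TRUE))
    colnames(cims) <- c("lower", "upper")
    rownames(cims) <- names(stats::coef(fit))
  }
  structure(list(pKa = est[["pKa"]], hill_n = est[["hill_n"]],
                 shift_prot = est[["shift_prot"]],
                 shift_neutral = est[["shift_neutral"]],
                 ci = cims, residual_sd = summary(fit)$sigma, fit = fit),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("<titration_fit> pKa = %.3f, n = %.3f, shifts %.3f (H+) / %.3f (H0) ppm, sd %.4g\n",
              x$pKa, x$hill_n, x$shift_prot, x$shift_neutral, x$residual_sd))
  invisible(x)
}
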