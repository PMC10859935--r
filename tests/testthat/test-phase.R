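# Turbidity thresholds, linear regression reporting, PCA and
# principal-component multilinear regression.

test_that("turbidity threshold is the x-intercept of the three points past onset", {
  s <- turbidity_series(c(100, 150, 200, 250, 300),
                        c(0.00, 0.12, 0.30, 0.50, 0.70))
  est <- extract_threshold(s)
  expect_equal(est$status, "ok")
  expect_equal(est$threshold, 125.0, tolerance = 1e-9)
  expect_equal(est$slope, 0.004, tolerance = 1e-12)
  expect_equal(est$intercept, -0.5, tolerance = 1e-9)

  # exactly linear points after an onset at 150
  s2 <- turbidity_series(c(100, 150, 200, 250, 300),
                         c(0.02, 0.12, 0.20, 0.40, 0.60))
  expect_equal(extract_threshold(s2)$threshold, 150.0, tolerance = 1e-9)

  # nothing exceeds the onset: no phase separation up to the max tested
  s3 <- turbidity_series(c(100, 200, 300, 400), c(0.01, 0.02, 0.05, 0.08))
  est3 <- extract_threshold(s3)
  expect_equal(est3$status, "no_onset")
  expect_true(is.na(est3$threshold))
  expect_equal(est3$max_tested, 400)

  # fewer than three points beyond the onset concentration
  s4 <- turbidity_series(c(100, 150, 200, 250), c(0, 0.2, 0.4, 0.6))
  expect_equal(extract_threshold(s4)$status, "insufficient_points")

  expect_error(turbidity_series(c(100, 100, 200, 300), c(0, 0.2, 0.4, 0.6)),
               "strictly increasing")
})

test_that("threshold extraction ignores points below the onset concentration", {
  base <- turbidity_series(c(150, 200, 250, 300), c(0.12, 0.30, 0.50, 0.70))
  padded <- turbidity_series(c(25, 50, 100, 150, 200, 250, 300),
                             c(0.0, 0.01, 0.0, 0.12, 0.30, 0.50, 0.70))
  expect_equal(extract_threshold(padded)$threshold,
               extract_threshold(base)$threshold, tolerance = 1e-12)
})

test_that("simple linear regression reports slope, intercept and R^2", {
  x <- c(1, 2, 3, 4, 5)
  f <- linear_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  fc <- linear_fit(x, rep(3, 5))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
  expect_error(linear_fit(rep(2, 5), x), "zero variance")
})

test_that("feature PCA is orthonormal, centered, and recovers planted directions", {
  ft <- make_feature_table(noise_sd = 0, seed = 17)
  pc <- virial_pca(ft)
  # orthonormal loadings, centered scores
  expect_equal(t(pc$loadings) %*% pc$loadings, diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(pc$scores)) < 1e-12))
  # scores reproduce the centered data
  X <- as.matrix(as.data.frame(ft)[, c("A2_open", "A2_closed",
                                       "A23_open", "A23_closed")])
  expect_equal(pc$scores %*% t(pc$loadings),
               sweep(X, 2, colMeans(X)), tolerance = 1e-9,
               ignore_attr = TRUE)
  # leading planted direction recovered up to numerical noise
  cos1 <- abs(sum(pc$loadings[, 1] * attr(ft, "planted_loadings")[, 1]))
  expect_gt(cos1, 0.999)
  # two collinear columns leave a null direction in their subspace
  Z <- cbind(a = rnorm(20), b = rnorm(20))
  Z <- cbind(Z, c = Z[, 1] * 2, d = rnorm(20))
  pz <- virial_pca(Z)
  expect_lt(pz$sdev[4], 1e-10)
})

test_that("component regression recovers a planted linear model exactly", {
  ft <- make_feature_table(a = 6.1, b = 413.4, c = 182.5, noise_sd = 0,
                           seed = 23)
  pc <- virial_pca(ft)
  fit <- mlr_on_components(pc$scores, ft$threshold)
  expect_equal(unname(fit$coefficients), c(6.1, 413.4), tolerance = 1e-9)
  expect_equal(fit$intercept, 182.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # residuals orthogonal to the selected scores
  expect_lt(abs(sum(fit$residuals * pc$scores[, "PC1"])), 1e-9)
  expect_lt(abs(sum(fit$residuals * pc$scores[, "PC4"])), 1e-9)
  # constant response: zero slopes, mean intercept
  fit0 <- mlr_on_components(pc$scores, rep(250, nrow(pc$scores)))
  expect_equal(unname(fit0$coefficients), c(0, 0), tolerance = 1e-12)
  expect_equal(fit0$intercept, 250)
  expect_error(mlr_on_components(pc$scores[1:2, ], c(1, 2)), "fewer rows")
  expect_error(mlr_on_components(pc$scores, ft$threshold, select = "PC9"),
               "not available")
})

test_that("imputation flags censored thresholds at the configured ceiling", {
  ft <- make_feature_table(censor_rows = c(3, 7), impute = 400, seed = 5)
  expect_true(all(ft$imputed[c(3, 7)]))
  expect_equal(ft$threshold[c(3, 7)], c(400, 400))
  expect_false(any(ft$imputed[-c(3, 7)]))
})
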