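test_that("quadrature weights partition the window area", {
  w <- plot_window(100, 100)
  empty <- point_pattern(numeric(0), numeric(0), w)
  q0 <- make_quadrature(empty, w, 10)
  expect_identical(nrow(q0), 100L)
  expect_true(all(q0$w == 100))

  one <- point_pattern(2, 2, plot_window(10, 10))
  q1 <- make_quadrature(one, plot_window(10, 10), 10)
  expect_identical(nrow(q1), 2L)       # one data + one dummy in one tile
  expect_true(all(q1$w == 50))

  p <- csr_pattern(200, plot_window(400, 400), 61)
  q <- make_quadrature(p, plot_window(400, 400), 10)
  expect_lt(abs(sum(q$w) - 400^2) / 400^2, 1e-3)
  expect_identical(sum(q$z), 200L)
  expect_true(all(q$w > 0))

  expect_error(make_quadrature(one, plot_window(10, 10), 20), "spacing")
})

test_that("intercept-only fit equals the closed-form MLE", {
  w <- plot_window(670, 670)
  p <- csr_pattern(100, w, 71)
  f <- fit_homog_null(p)
  expect_equal(as.numeric(f$coef[1]), log(100 / window_area(w)),
               tolerance = 1e-6)
  expect_equal(f$aic, 2 - 2 * f$loglik, tolerance = 1e-6)
  expect_true(all(f$lambda_grid$values > 0))
  expect_error(fit_homog_null(point_pattern(numeric(0), numeric(0), w)),
               "empty")
})

test_that("IPP fitting recovers a known log-linear intensity", {
  w <- plot_window(500, 500)
  X <- smooth_covariate(w, seed = 81)
  lam <- raster_grid(exp(-8.2 + 1.2 * X$values), cell = 20)
  stack <- unit_stack(X, w)
  pat <- simulate_ipp(lam, w, seed = 82)
  fit <- fit_ipp(pat, stack)
  se1 <- fit$se[["x1"]]
  expect_lt(abs(fit$coef[["x1"]] - 1.2), 3 * se1)
  expect_lt(fit$p_values[["x1"]], 0.001)
  # score equation: fitted intensity integrates to the point count
  tot <- sum(fit$lambda_grid$values) * 400
  expect_lt(abs(tot - n_points(pat)) / n_points(pat), 0.05)
  # AIC identity
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik, tolerance = 1e-9)
  # null AIC equals fit AIC plus the parameter penalty when the covariate
  # grid is constant
  const_stack <- unit_stack(raster_grid(matrix(0, X$n_rows, X$n_cols),
                                        cell = 20, name = "x1"), w)
  expect_error(fit_ipp(pat, const_stack), "singular|collinear")
})

test_that("AIC comparison reproduces the published table arithmetic", {
  aic <- reference_aic()
  expect_identical(aic$null[aic$year == 2011] -
                     aic$exogenous[aic$year == 2011], 27L)
  expect_identical(aic$null[aic$year == 2005] -
                     aic$endogenous[aic$year == 2005], 599L)

  w <- plot_window(400, 400)
  p <- csr_pattern(150, w, 91)
  f1 <- fit_homog_null(p)
  tab <- compare_aic(list(null = f1, same = f1))
  expect_true(all(tab$delta_vs_null == 0))
  p2 <- csr_pattern(140, w, 92)
  expect_error(compare_aic(list(null = f1, other = fit_homog_null(p2))),
               "different datasets")
})

test_that("intensity prediction is log-linear in the coefficients", {
  w <- plot_window(400, 400)
  X <- smooth_covariate(w, seed = 95)
  stack <- unit_stack(X, w)
  pat <- simulate_ipp(raster_grid(exp(-8 + X$values), cell = 20), w,
                      seed = 96)
  fit <- fit_ipp(pat, stack)
  lam <- predict_intensity(fit, stack)
  fit2 <- fit
  fit2$coef[1] <- fit2$coef[1] + log(2)
  lam2 <- predict_intensity(fit2, stack)
  expect_equal(lam2$values, 2 * lam$values, tolerance = 1e-12)
  zero_stack <- unit_stack(raster_grid(matrix(0, X$n_rows, X$n_cols),
                                       cell = 20, name = "x1"), w)
  lam0 <- predict_intensity(fit, zero_stack)
  expect_true(all(abs(lam0$values - exp(fit$coef[1])) < 1e-12))
})

test_that("prediction curves follow the disc-count conversion", {
  disc <- pi * 40^2
  # zero slope: flat curve at exp(b0) * disc area
  flat <- quadratic_fit(-5, 0, 0)
  pc <- prediction_curve(flat, "nest", c(1, 10, 30))
  expect_true(all(abs(pc$fit - exp(-5) * disc) < 1e-9))

  # hump-shaped curve peaks where b1 + 2 b2 x = 0
  hump <- quadratic_fit(-6, 0.2, -0.004)
  xg <- seq(0.5, 50, by = 0.1)
  ph <- prediction_curve(hump, "nest", xg)
  x_peak <- xg[which.max(ph$fit)]
  expect_lt(abs(x_peak - 0.2 / (2 * 0.004)), 0.1001)

  # CI width is a quadratic form in the distance from the covariate mean:
  # with a diagonal covariance it grows monotonically away from zero
  handfit <- quadratic_fit(-5, 0.3, 0)
  handfit$variables <- "nest"
  handfit$coef <- handfit$coef[1:2]
  handfit$vcov <- diag(c(0.01, 0.04))
  handfit$scaling <- handfit$scaling["nest"]
  handfit$stack_means <- c(nest = 0)
  px <- prediction_curve(handfit, "nest", c(1, 2, 5, 10))
  widths <- log(px$hi) - log(px$lo)
  expect_true(all(diff(widths) > 0))

  expect_error(prediction_curve(flat, "trees", 1:3), "not in the fit")
})
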