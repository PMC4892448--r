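test_that("MAD p-value core behaves on injected curves", {
  r_len <- 20
  set.seed(9)
  sims <- matrix(rnorm(r_len * 99, mean = 10), r_len, 99)
  # observed equal to the simulated mean: zero statistic, p = 1
  mp <- nestpp:::mad_pvalue(rowMeans(sims), sims)
  expect_identical(mp$T_obs, 0)
  expect_identical(mp$p, 1)
  # an extreme observed curve is rejected at the smallest attainable p
  mp2 <- nestpp:::mad_pvalue(rowMeans(sims) + 100, sims)
  expect_identical(mp2$p, 1 / 100)
  # p-values live on the discrete support [1/(n+1), 1]
  expect_gte(mp2$p, 1 / 100)
  # permuting the simulations leaves the p-value unchanged
  perm <- sims[, sample.int(99)]
  expect_identical(nestpp:::mad_pvalue(rowMeans(sims) + 2, sims)$p,
                   nestpp:::mad_pvalue(rowMeans(sims) + 2, perm)$p)
})

test_that("MAD test accepts its own generating model", {
  w <- plot_window(500, 500)
  p <- simulate_thomas_homog(3e-4, 8, 4, w, seed = 61)
  f0 <- fit_homog_null(p)
  tf <- fit_thomas_mincontrast(p, f0, r_max = 100)
  md <- mad_test(tf, p, n_sim = 39, r_max = 100, r_step = 4, seed = 62)
  expect_gte(md$p_value, 0.05)
  expect_false(md$rejected)
  expect_gte(md$p_value, 1 / 40)
  expect_error(mad_test(tf, p, n_sim = 10), "at least 39")
})

test_that("bootstrap CIs cover the estimate and detect failures", {
  w <- plot_window(500, 500)
  p <- simulate_thomas_homog(4e-4, 8, 4, w, seed = 71)
  f0 <- fit_homog_null(p)
  tf <- fit_thomas_mincontrast(p, f0, r_max = 100)
  ci <- parametric_bootstrap_ci(tf, n_sim = 99, seed = 72)
  expect_lte(ci$sigma$lo, ci$sigma$hi)
  expect_lte(ci$kappa$lo, ci$kappa$hi)
  expect_false(ci$unreliable)
  # percentile intervals bracket the point estimates in a healthy run
  expect_gte(tf$sigma, ci$sigma$lo * 0.5)
  expect_lte(tf$sigma, ci$sigma$hi * 2)
  expect_error(parametric_bootstrap_ci(tf, n_sim = 50), "at least 99")
})

test_that("threshold analysis finds a constructed break-even crossing", {
  disc <- pi * 40^2
  # engineered so that f(30) = 30 exactly, crossing downward
  b1 <- 0.2; b2 <- -0.005
  b0 <- log(30 / disc) - b1 * 30 - b2 * 900
  fit <- quadratic_fit(b0, b1, b2)
  th <- breakeven_thresholds(fit, x_range = c(0.5, 60), n_draws = 50,
                             seed = 81)
  expect_lt(abs(th$breakeven$estimate - 30), 1e-3)
  expect_true(is.finite(th$breakeven$lo) && is.finite(th$breakeven$hi))

  # raising the intercept by log 2 moves the break-even crossing upward
  fit2 <- quadratic_fit(b0 + log(2), b1, b2)
  th2 <- breakeven_thresholds(fit2, x_range = c(0.5, 60), n_draws = 50,
                              seed = 82)
  expect_gt(th2$breakeven$estimate, th$breakeven$estimate)

  # a curve entirely above the diagonal has no threshold, without error
  high <- quadratic_fit(log(500 / disc), 0.01, -1e-4)
  th3 <- breakeven_thresholds(high, x_range = c(0.5, 40), n_draws = 50,
                              seed = 83)
  expect_true(is.na(th3$breakeven$estimate))

  # Allee structure: a curve dipping below the diagonal at low density
  # reports lower (Allee) and upper (break-even) crossings in order
  ba <- quadratic_fit(log(0.5 / disc), 0.35, -0.006)
  th4 <- breakeven_thresholds(ba, x_range = c(0.1, 80), n_draws = 50,
                              seed = 84)
  if (is.finite(th4$allee$estimate) && is.finite(th4$breakeven$estimate))
    expect_lt(th4$allee$estimate, th4$breakeven$estimate)

  expect_error(breakeven_thresholds(quadratic_fit(0, 0.1, -0.1)[
    c("coef", "vcov")], x_range = c(1, 10)))
})

test_that("dynamics round trip yields a plausible break-even threshold", {
  w <- plot_window(500, 500)
  trees <- gen_tree_series(w, 1800, 1:6, seed = 91)
  census <- simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 120), seed = 92)
  stats <- compute_scaling(census, NULL, 6)
  stack <- build_covariate_stack(census, NULL, 6, stats)
  nests <- census_pattern(census, 6, w, "nests")
  fit <- fit_ipp(nests, stack, variables = c("nest", "nest2"))
  expect_gt(fit$coef[["nest"]], 0)
  expect_lt(fit$coef[["nest2"]], 0)
  th <- breakeven_thresholds(fit, x_range = c(0.5, 80), n_draws = 50,
                             seed = 93)
  # the logistic survival with half-point 40 and budding ~0.35 puts the
  # dynamic equilibrium in the tens of nests per disc; in a still-growing
  # population the curve may not have crossed back down yet, which is
  # reported as an absent threshold rather than an error
  est <- th$breakeven$estimate
  expect_true(is.na(est) || (est > 3 && est < 80))
})
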