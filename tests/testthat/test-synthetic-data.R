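test_that("gen_dem honours relief, smoothness and determinism", {
  w <- plot_window(400, 400)
  flat <- gen_dem(w, cell = 20, relief = 0, smoothness = 100, seed = 1)
  expect_true(all(flat$values == flat$values[1, 1]))
  expect_true(all(slope_grid(flat)$values == 0))

  a <- gen_dem(w, cell = 20, relief = 50, smoothness = 100, seed = 7)
  b <- gen_dem(w, cell = 20, relief = 50, smoothness = 100, seed = 7)
  expect_identical(a$values, b$values)
  sds <- vapply(1:20, function(s)
    sd(gen_dem(w, 20, relief = 50, smoothness = 100, seed = s)$values),
    numeric(1))
  expect_true(all(abs(sds - 50) < 15))

  expect_error(gen_dem(w, cell = -5), "positive")
  expect_error(gen_dem(w, cell = 20, smoothness = 5), "smoothness")
})

test_that("tree thinning follows the per-year rounding recurrence", {
  w <- plot_window(500, 500)
  stable <- gen_tree_series(w, 200, 1:4, thin_start = 2, thin_frac = 0,
                            seed = 3)
  counts <- table(stable$year)
  expect_true(all(counts == 200))
  expect_identical(stable$tree_id[stable$year == 1],
                   stable$tree_id[stable$year == 4])

  # recurrence oracle: thinning visible from year 5 on, five removals
  thinned <- gen_tree_series(w, 1000, 1:9, thin_start = 4,
                             thin_frac = 0.12, seed = 4)
  cnt <- as.integer(table(thinned$year))
  oracle <- Reduce(function(n, y) round(n * 0.88), 5:9, accumulate = TRUE,
                   init = 1000)
  expect_identical(cnt, c(rep(1000L, 4), as.integer(oracle[-1])))
  expect_identical(cnt[9], 527L)

  # a 60% final/initial ratio is reached with ~0.097 over five removals
  sixty <- gen_tree_series(w, 1000, 2004:2012, thin_start = 2007,
                           thin_frac = 0.097, seed = 5)
  ratio <- sum(sixty$year == 2012) / sum(sixty$year == 2004)
  expect_lt(abs(ratio - 0.60), 0.005)

  # surviving trees are a subset with identical coordinates
  y1 <- thinned[thinned$year == 1, ]
  y9 <- thinned[thinned$year == 9, ]
  expect_true(all(y9$tree_id %in% y1$tree_id))
  expect_identical(y9$x, y1$x[match(y9$tree_id, y1$tree_id)])

  expect_error(gen_tree_series(w, 100, integer(0)), "non-empty")
  expect_error(gen_tree_series(w, 100, 1:3, thin_frac = 1), "thin_frac")
})

test_that("nest dynamics respects its degenerate limits and stays on trees", {
  w <- plot_window(300, 300)
  trees <- gen_tree_series(w, 300, 1:4, seed = 8)

  frozen <- simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 40, bud_rate = 0, s_max = 1,
                           d0 = 1e9, allee_floor = 0), seed = 2)
  per_year <- split(frozen$tree_id[frozen$nest == 1], frozen$year[frozen$nest == 1])
  expect_true(all(vapply(per_year, function(ids)
    identical(sort(ids), sort(per_year[[1]])), logical(1))))

  dead <- simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 40, s_max = 0), seed = 2)
  tab <- tapply(dead$nest, dead$year, sum)
  expect_identical(as.integer(tab), c(40L, 0L, 0L, 0L))

  grown <- simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 30), seed = 3)
  nests <- grown[grown$nest == 1, ]
  merged <- merge(nests, trees, by = c("year", "tree_id"))
  expect_identical(merged$x.x, merged$x.y)
  expect_identical(merged$y.x, merged$y.y)

  expect_error(simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 1000), seed = 1), "exceeds")
})

test_that("density-dependent dynamics produces endogenous clustering", {
  w <- plot_window(500, 500)
  trees <- gen_tree_series(w, 1500, 1:5, seed = 21)
  census <- simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 80), seed = 22)
  env <- pcf_envelope(census_pattern(census, 5, w, "trees"),
                      census_pattern(census, 5, w, "nests"),
                      r = c(5, 10, 15, 20), n_sim = 99, seed = 23)
  expect_true(any(env$curve$classification == "clustered"))
})

test_that("homogeneous Thomas simulation matches its moment structure", {
  w <- plot_window(670, 670)
  a <- simulate_thomas_homog(2e-4, 7.4, 2.5, w, seed = 5)
  b <- simulate_thomas_homog(2e-4, 7.4, 2.5, w, seed = 5)
  expect_identical(a$x, b$x)
  expect_true(all(nestpp:::inside_window(a$x, a$y, w)))

  counts <- vapply(1:500, function(s)
    n_points(simulate_thomas_homog(2e-4, 7.4, 2.5, w, seed = s)),
    numeric(1))
  expected <- 2e-4 * 2.5 * window_area(w)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("inhomogeneous Thomas thinning reduces to its oracles", {
  w <- plot_window(400, 400)
  spec <- nestpp:::grid_spec_for_window(w, 20)
  const <- raster_grid(matrix(5e-4, spec$n_rows, spec$n_cols), cell = 20)
  inh <- simulate_thomas_inhom(2e-4, 8, const, w, seed = 9)
  hom <- simulate_thomas_homog(2e-4, 8, 5e-4 / 2e-4, w, seed = 9)
  expect_identical(inh$x, hom$x)   # retention probability is exactly 1

  half <- matrix(5e-4, spec$n_rows, spec$n_cols)
  half[, seq_len(spec$n_cols / 2)] <- 0
  none_left <- simulate_thomas_inhom(2e-4, 8, raster_grid(half, cell = 20),
                                     w, seed = 10)
  # bilinear interpolation ramps across one boundary cell; points strictly
  # left of the ramp are impossible
  expect_true(all(none_left$x > w$width / 2 - 20))

  zero <- raster_grid(matrix(0, spec$n_rows, spec$n_cols), cell = 20)
  expect_identical(n_points(simulate_thomas_inhom(2e-4, 8, zero, w)), 0L)

  # binomial thinning oracle: a lambda vs 2 lambda step gives a 1:2 count
  # ratio between halves
  step <- matrix(4e-4, spec$n_rows, spec$n_cols)
  step[, seq_len(spec$n_cols / 2)] <- 2e-4
  step_g <- raster_grid(step, cell = 20)
  counts <- vapply(1:200, function(s) {
    p <- simulate_thomas_inhom(2e-4, 8, step_g, w, seed = s)
    c(sum(p$x < w$width / 2 - 20), sum(p$x > w$width / 2 + 20))
  }, numeric(2))
  ratio <- sum(counts[2, ]) / sum(counts[1, ])
  # expected ratio of the clipped halves is 2; binomial noise at ~6000
  # points per arm
  expect_lt(abs(ratio - 2), 0.15)
})
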