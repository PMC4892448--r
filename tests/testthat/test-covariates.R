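test_that("kernel density matches its closed form and conserves mass", {
  w <- plot_window(400, 400)
  # a point exactly on a cell centre: value there is 1 / (2 pi h^2)
  p1 <- point_pattern(210, 210, w)
  g <- kernel_density_grid(p1, bandwidth = 20)
  cc <- cell_centres(g)
  i <- which.min(abs(cc$y - 210)); j <- which.min(abs(cc$x - 210))
  expect_equal(g$values[i, j], 1 / (2 * pi * 400), tolerance = 1e-12)

  # normalisation: cell sums integrate to the point count for interior
  # patterns
  set.seed(4)
  p <- point_pattern(runif(30, 120, 280), runif(30, 120, 280), w)
  g30 <- kernel_density_grid(p, 20)
  expect_lt(abs(sum(g30$values) * 400 - 30) / 30, 0.01)

  # empty pattern gives a zero surface
  g0 <- kernel_density_grid(point_pattern(numeric(0), numeric(0), w), 20)
  expect_true(all(g0$values == 0))

  # translation equivariance: shifting points and grid origin together
  shift <- c(31.7, -12.3)
  gs <- kernel_density_grid(
    point_pattern(p$x + shift[1], p$y + shift[2],
                  plot_window(500, 500)),
    20, grid = list(origin = shift, cell = 20, n_cols = g30$n_cols,
                    n_rows = g30$n_rows))
  expect_lt(max(abs(gs$values - g30$values)), 1e-12)
})

test_that("slope recovers exact planar gradients", {
  mk <- function(gx, gy, n = 15, cell = 20)
    raster_grid(outer(seq_len(n), seq_len(n),
                      function(i, j) gx * cell * j + gy * cell * i),
                cell = cell)
  expect_true(all(slope_grid(mk(0, 0))$values == 0))
  east <- slope_grid(mk(0.1, 0))$values
  expect_lt(max(abs(east - 0.1)), 1e-12)
  tilted <- slope_grid(mk(0.3, 0.4))$values
  expect_lt(max(abs(tilted - 0.5)), 1e-12)
  expect_error(slope_grid(raster_grid(matrix(1, 1, 1))), "3x3")
})

test_that("wetness index follows ln(Ac/s) with D8 accumulation", {
  n <- 12; cell <- 20
  plane <- raster_grid(outer(seq_len(n), seq_len(n),
                             function(i, j) 0.1 * cell * j),
                       cell = cell)
  tw <- twi_grid(plane)
  # easternmost column is a ridge: single-cell catchment, slope 0.1
  expect_lt(max(abs(tw$values[2:(n - 1), n] - log(400 / 0.1))), 1e-9)
  # accumulation grows monotonically downslope (westward) along each row
  interior <- tw$values[2:(n - 1), 2:(n - 1)]
  expect_true(all(apply(interior, 1, function(v) all(diff(v) <= 1e-9))))
  # doubling Ac at fixed slope adds exactly ln 2: second-from-ridge cells
  # accumulate two cells of area
  expect_lt(max(abs(tw$values[2:(n - 1), n - 1] -
                      (log(400 / 0.1) + log(2)))), 1e-9)
  # invariance to a constant elevation offset
  tw2 <- twi_grid(raster_grid(plane$values + 500, cell = cell))
  expect_lt(max(abs(tw$values - tw2$values)), 1e-9)
  # flat terrain: every cell keeps its own area at the slope floor
  flat <- twi_grid(raster_grid(matrix(3, n, n), cell = cell),
                   slope_floor = 1e-3)
  expect_true(all(abs(flat$values - log(400 / 1e-3)) < 1e-9))
})

test_that("pooled scaling uses the population sd across years", {
  g1 <- raster_grid(matrix(c(0, 2, 0, 2), 2, 2))
  g2 <- raster_grid(matrix(c(0, 2, 0, 2), 2, 2))
  st <- pooled_scaling_stats(list(g1, g2))
  expect_equal(st$mean, 1)
  expect_equal(st$sd, 1)
  expect_error(pooled_scaling_stats(raster_grid(matrix(5, 3, 3))),
               "constant")
  # idempotence: scaling by the pooled stats leaves unit sd
  scaled <- raster_grid(g1$values / st$sd)
  expect_equal(pooled_scaling_stats(scaled)$sd, 1)
})

test_that("covariate stacks obey the scaling conventions", {
  w <- plot_window(300, 300)
  trees <- gen_tree_series(w, 400, 2004:2006, seed = 31)
  census <- simulate_nest_dynamics(
    trees, dynamics_params(initial_nests = 40), seed = 32)
  dem <- gen_dem(w, 20, relief = 30, smoothness = 80, seed = 33)
  stats <- compute_scaling(census, dem, 2005:2006)
  stack <- build_covariate_stack(census, dem, 2005, stats)

  expect_setequal(names(stack$grids),
                  c("nest", "nest2", "trees", "elev", "slope", "wet"))
  # terrain variables normalised over the plot
  for (v in c("elev", "slope", "wet")) {
    expect_lt(abs(mean(stack$grids[[v]]$values)), 1e-9)
    expect_equal(nestpp:::pop_sd(stack$grids[[v]]$values), 1,
                 tolerance = 1e-9)
  }
  # density variables scaled but not centred
  expect_true(all(stack$grids$nest$values >= 0))
  expect_true(all(stack$grids$trees$values >= 0))
  # nest2 is exactly the square of the scaled lag density
  expect_identical(stack$grids$nest2$values, stack$grids$nest$values^2)
  # pooled sd across the two model years is 1 for the density variables
  s05 <- build_covariate_stack(census, dem, 2005, stats)
  s06 <- build_covariate_stack(census, dem, 2006, stats)
  pooled <- nestpp:::pop_sd(c(s05$grids$nest$values, s06$grids$nest$values))
  expect_equal(pooled, 1, tolerance = 1e-9)

  expect_error(build_covariate_stack(census, dem, 2004, stats), "lag")

  man <- stack_manifest(stack)
  expect_identical(nrow(man), 6L)
})

test_that("ESRI ASCII grids round-trip exactly", {
  g <- gen_dem(plot_window(200, 160), 20, relief = 25, smoothness = 50,
               seed = 41)
  path <- tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-8)
  expect_equal(g2$cell, g$cell)
  expect_equal(g2$origin, g$origin)
  unlink(path)
})
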