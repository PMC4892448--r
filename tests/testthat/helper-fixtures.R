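# Shared fixtures: everything is generated in code at test time.

# uniform random pattern of n points
csr_pattern <- function(n, window, seed) {
  set.seed(seed)
  point_pattern(stats::runif(n, 0, window$width),
                stats::runif(n, 0, window$height), window)
}

# smooth unit-sd covariate surface on a 20 m grid
smooth_covariate <- function(window, seed, smoothness = 120) {
  dem <- gen_dem(window, cell = 20, relief = 1, smoothness = smoothness,
                 base = 0, seed = seed)
  v <- dem$values
  raster_grid((v - mean(v)) / nestpp:::pop_sd(v), cell = 20, name = "x1")
}

# single-covariate stack around a surface
unit_stack <- function(grid, window) {
  nestpp:::as_covariate_stack(list(x1 = grid), window,
    scaling = list(x1 = list(mean = 0, sd = 1, centred = TRUE)))
}

# hand-built endogenous fit with known coefficients, for curve/threshold
# oracles: scaling divisor 1/(pi R^2) makes the scaled covariate equal the
# disc count
quadratic_fit <- function(beta0, beta1, beta2, disc_radius = 40,
                          window = plot_window(400, 400)) {
  disc <- pi * disc_radius^2
  structure(list(
    coef = c(`(Intercept)` = beta0, nest = beta1, nest2 = beta2),
    vcov = diag(1e-6, 3), se = rep(1e-3, 3),
    p_values = rep(0, 3), variables = c("nest", "nest2"),
    loglik = 0, aic = 0, n = 100, window = window,
    lambda_grid = raster_grid(matrix(exp(beta0), 20, 20), cell = 20),
    scaling = list(nest = list(mean = 0, sd = 1 / disc, centred = FALSE),
                   nest2 = list(mean = NA, sd = 1 / disc, centred = FALSE)),
    stack_means = c(nest = 0, nest2 = 0)), class = "ipp_fit")
}

# small two-year census with nests placed deterministically on trees
tiny_census <- function(window = plot_window(300, 300), n_trees = 400,
                        years = 2004:2005, seed = 11) {
  gen_tree_series(window, n_trees, years, seed = seed)
}
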