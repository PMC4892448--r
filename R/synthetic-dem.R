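#' Generate a synthetic digital elevation model
#'
#' Builds a smooth random terrain surface on a regular grid: white noise
#' convolved with a Gaussian filter of standard deviation `smoothness`
#' (metres), rescaled so the cell values have (population) standard deviation
#' `relief`, plus a constant base elevation. This stands in for a coarse DEM
#' of a hillside plot when deriving slope and wetness covariates.
#'
#' @param window A [plot_window()].
#' @param cell Cell size in metres (default 20).
#' @param relief Standard deviation of elevation values (m); 0 gives a flat
#'   surface.
#' @param smoothness Correlation length of the terrain (m); must be at least
#'   one cell.
#' @param base Mean elevation added to the field (m).
#' @param seed Integer seed; identical seeds give identical grids.
#' @return A [raster_grid()] named `"elev"` covering the window.
#' @examples
#' dem <- gen_dem(plot_window(200, 200), cell = 20, relief = 30,
#'                smoothness = 60, seed = 1)
#' sd(dem$values)  # ~30
#' @export
gen_dem <- function(window, cell = 20, relief = 30, smoothness = 100,
                    base = 1000, seed = 1) {
  stopifnot(inherits(window, "plot_window"))
  if (cell <= 0) stop("cell size must be positive")
  if (smoothness < cell) stop("smoothness must be at least one cell")
  spec <- grid_spec_for_window(window, cell)
  nr <- spec$n_rows; nc <- spec$n_cols
  vals <- with_seed(seed, {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    sm <- gauss_smooth(noise, sigma_cells = smoothness / cell)
    s <- pop_sd(sm)
    if (relief > 0 && s > 0) sm <- sm * (relief / s) else sm[] <- 0
    sm + base
  })
  raster_grid(vals, origin = c(0, 0), cell = cell, name = "elev")
}

pop_sd <- function(x) {
  x <- as.numeric(x)
  sqrt(mean((x - mean(x))^2))
}

# Separable Gaussian convolution with edge replication.
gauss_smooth <- function(m, sigma_cells) {
  half <- max(1L, as.integer(ceiling(3 * sigma_cells)))
  k <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    vp <- c(rep(v[1], half), v, rep(v[length(v)], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1):(half + length(v))]
  }
  m2 <- apply(m, 2, smooth_vec)
  t(apply(t(m2), 2, smooth_vec))
}
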