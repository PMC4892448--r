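#' Simulate a homogeneous Thomas cluster process
#'
#' Neyman-Scott construction: mother points form a homogeneous Poisson
#' process of intensity `kappa` on the window dilated by `4 * sigma` on every
#' side (so that clusters seeded just outside the window still contribute;
#' the truncated offspring mass is below 0.01%), each mother receives a
#' `Poisson(mu)` number of offspring displaced by independent isotropic
#' Gaussian(`sigma`) vectors, and only offspring falling inside the window
#' are returned. Mothers are discarded.
#'
#' @param kappa Mother intensity (points per m^2).
#' @param sigma Offspring displacement standard deviation (m).
#' @param mu Mean offspring per mother.
#' @param window A [plot_window()].
#' @param seed Integer seed.
#' @return A [point_pattern()] of the offspring inside the window. The
#'   expected point count is `kappa * mu * window_area(window)`.
#' @export
simulate_thomas_homog <- function(kappa, sigma, mu, window, seed = 1) {
  stopifnot(kappa > 0, sigma > 0, mu > 0, inherits(window, "plot_window"))
  m <- 4 * sigma
  w_dil <- window$width + 2 * m
  h_dil <- window$height + 2 * m
  if (kappa * w_dil * h_dil > 5e7)
    stop("expected mother count exceeds 5e7; kappa is unrealistically large")
  with_seed(seed, {
    n_m <- stats::rpois(1, kappa * w_dil * h_dil)
    if (n_m == 0) return(point_pattern(numeric(0), numeric(0), window))
    mx <- stats::runif(n_m, -m, window$width + m)
    my <- stats::runif(n_m, -m, window$height + m)
    n_off <- stats::rpois(n_m, mu)
    tot <- sum(n_off)
    if (tot == 0) return(point_pattern(numeric(0), numeric(0), window))
    ox <- rep(mx, n_off) + stats::rnorm(tot, sd = sigma)
    oy <- rep(my, n_off) + stats::rnorm(tot, sd = sigma)
    keep <- inside_window(ox, oy, window)
    point_pattern(ox[keep], oy[keep], window)
  })
}

#' Simulate an inhomogeneous Thomas cluster process
#'
#' Draws a homogeneous Thomas pattern at the maximum of the target intensity
#' surface and thins each point independently with retention probability
#' `lambda(z) / lambda_max` (bilinear interpolation of the grid). The
#' expected local intensity of the result equals `lambda(z)` and, because
#' the thinning is independent of the clustering, the inhomogeneous K
#' function of the result equals the homogeneous Thomas K.
#'
#' @param kappa Mother intensity (per m^2).
#' @param sigma Offspring dispersal standard deviation (m).
#' @param intensity A [raster_grid()] of the target intensity `lambda(z)`
#'   (points per m^2); must be non-negative with a finite maximum. The
#'   implied mean offspring count is `mu(z) = lambda(z) / kappa`.
#' @param window A [plot_window()].
#' @param seed Integer seed.
#' @return A [point_pattern()]. An all-zero intensity gives an empty
#'   pattern.
#' @export
simulate_thomas_inhom <- function(kappa, sigma, intensity, window, seed = 1) {
  stopifnot(inherits(intensity, "raster_grid"))
  lam_max <- max(intensity$values)
  if (!is.finite(lam_max) || lam_max < 0)
    stop("intensity must be non-negative and finite")
  if (lam_max == 0) return(point_pattern(numeric(0), numeric(0), window))
  base <- simulate_thomas_homog(kappa, sigma, mu = lam_max / kappa,
                                window = window, seed = seed)
  if (n_points(base) == 0) return(base)
  with_seed(child_seed(seed, 1), {
    p_keep <- pmin(pmax(interp_bilinear(intensity, base$x, base$y), 0),
                   lam_max) / lam_max
    keep <- stats::runif(n_points(base)) < p_keep
    point_pattern(base$x[keep], base$y[keep], window)
  })
}

#' Simulate an inhomogeneous Poisson process
#'
#' Rejection sampling from an intensity surface: a homogeneous Poisson
#' pattern at `lambda_max` thinned with probability `lambda(z) / lambda_max`.
#' Used for parametric simulation from fitted Poisson models.
#'
#' @inheritParams simulate_thomas_inhom
#' @return A [point_pattern()].
#' @export
simulate_ipp <- function(intensity, window, seed = 1) {
  stopifnot(inherits(intensity, "raster_grid"), inherits(window, "plot_window"))
  lam_max <- max(intensity$values)
  if (!is.finite(lam_max) || lam_max < 0)
    stop("intensity must be non-negative and finite")
  if (lam_max == 0) return(point_pattern(numeric(0), numeric(0), window))
  with_seed(seed, {
    n <- stats::rpois(1, lam_max * window_area(window))
    if (n == 0) return(point_pattern(numeric(0), numeric(0), window))
    x <- stats::runif(n, 0, window$width)
    y <- stats::runif(n, 0, window$height)
    p_keep <- pmin(pmax(interp_bilinear(intensity, x, y), 0), lam_max) / lam_max
    keep <- stats::runif(n) < p_keep
    point_pattern(x[keep], y[keep], window)
  })
}
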