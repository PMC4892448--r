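#' Curve container for spatial summary statistics
#'
#' @param r Strictly increasing scale grid (m).
#' @param value Statistic at each `r`.
#' @param reference Theoretical value under the null (CSR) at each `r`.
#' @param lo,hi Optional pointwise envelope bounds.
#' @param classification Optional per-`r` labels
#'   (`"clustered"`, `"dispersed"`, `"ns"`).
#' @param stat Name of the statistic (`"K"`, `"L"`, `"pcf"`).
#' @return A `data.frame` of class `"ss_curve"`.
#' @export
ss_curve <- function(r, value, reference = NULL, lo = NULL, hi = NULL,
                     classification = NULL, stat = "stat") {
  stopifnot(length(r) >= 1, all(diff(r) > 0), length(value) == length(r))
  df <- data.frame(r = r, value = value)
  if (!is.null(reference)) df$reference <- reference
  if (!is.null(lo)) { stopifnot(all(lo <= hi + 1e-12)); df$lo <- lo; df$hi <- hi }
  if (!is.null(classification)) df$classification <- classification
  class(df) <- c("ss_curve", "data.frame")
  attr(df, "stat") <- stat
  df
}

# Interpolate an intensity grid at pattern points, floored to keep the
# inverse-intensity weights bounded.
lambda_at_points <- function(intensity, pattern, lambda_floor = 1e-8) {
  pmax(interp_bilinear(intensity, pattern$x, pattern$y), lambda_floor)
}

#' Ripley's K function with translation edge correction
#'
#' Without an intensity surface this is the classical estimator
#' `K(r) = |A| n^-2 sum_{i != j} 1(d_ij <= r) e_ij` with the translation
#' correction `e_ij = |A| / ((W - |dx|)(H - |dy|))`, exact for rectangular
#' windows. With an intensity surface it is the inhomogeneous (intensity
#' weighted) estimator
#' `K(r) = |A|^-1 sum_{i != j} 1(d_ij <= r) e_ij / (lambda(x_i) lambda(x_j))`,
#' with `lambda` bilinearly interpolated from the grid and floored at
#' `lambda_floor`. Under complete spatial randomness the reference value is
#' `pi r^2`.
#'
#' @param pattern A [point_pattern()] with at least two points.
#' @param r Increasing vector of scales (m); the maximum must not exceed
#'   half the shorter window side (validity of the translation correction).
#' @param intensity Optional [raster_grid()] of fitted intensity.
#' @param lambda_floor Lower bound applied to interpolated intensities.
#' @return An [ss_curve()] with `stat = "K"`.
#' @export
estimate_K <- function(pattern, r = 1:100, intensity = NULL,
                       lambda_floor = 1e-8) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- n_points(pattern)
  if (n < 2) stop("need at least two points to estimate K")
  w <- pattern$window
  if (max(r) > min(w$width, w$height) / 2 + 1e-9)
    stop("r exceeds half the shorter window side")
  pd <- pair_data(pattern)
  area <- window_area(w)
  if (is.null(intensity)) {
    wts <- 2 * pd$e * area / n^2           # x2: unordered -> ordered pairs
  } else {
    lam <- lambda_at_points(intensity, pattern, lambda_floor)
    wts <- 2 * pd$e / (lam[pd$i] * lam[pd$j] * area)
  }
  ord <- order(pd$d)
  ds <- pd$d[ord]; cs <- cumsum(wts[ord])
  k <- c(0, cs)[findInterval(r, ds) + 1]
  ss_curve(r, k, reference = pi * r^2, stat = "K")
}

#' L transform of a K curve
#'
#' `L(r) = sqrt(K(r) / pi)`, the variance-stabilised form of Ripley's K;
#' its CSR reference is `L(r) = r`.
#'
#' @param k_curve An [ss_curve()] of K values (all non-negative).
#' @return An [ss_curve()] with `stat = "L"`.
#' @export
L_transform <- function(k_curve) {
  stopifnot(inherits(k_curve, "ss_curve"))
  if (any(k_curve$value < 0)) stop("K values must be non-negative")
  ss_curve(k_curve$r, sqrt(k_curve$value / pi), reference = k_curve$r,
           stat = "L")
}

#' Pair correlation function with translation edge correction
#'
#' Kernel estimator of `g(r)`, the relative density of point pairs at ring
#' distance exactly `r`:
#' `g(r) = (2 pi r)^-1 lambda^-2 |A|^-1 sum_{i != j} kern_h(r - d_ij) e_ij`
#' with an Epanechnikov kernel of half-width `h`, `lambda = n / |A|` and
#' translation edge correction. The CSR reference is 1; values above 1
#' indicate clustering at that scale, below 1 dispersion. The default
#' smoothing bandwidth is Stoyan's rule `h = 0.26 / sqrt(lambda)`.
#'
#' @param pattern A [point_pattern()] with at least two points.
#' @param r Increasing vector of scales (m), each larger than `h / 2`.
#' @param smoothing_h Epanechnikov half-width (m); `NULL` for Stoyan's rule.
#' @return An [ss_curve()] with `stat = "pcf"`; the bandwidth used is
#'   attached as attribute `"h"`.
#' @export
estimate_pcf <- function(pattern, r = 1:100, smoothing_h = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (length(r) == 0) stop("empty r grid")
  n <- n_points(pattern)
  if (n < 2) stop("need at least two points to estimate the PCF")
  w <- pattern$window
  area <- window_area(w)
  lam <- n / area
  h <- if (is.null(smoothing_h)) 0.26 / sqrt(lam) else smoothing_h
  stopifnot(h > 0)
  pd <- pair_data(pattern)
  g <- vapply(r, function(ri) {
    u <- (ri - pd$d) / h
    ok <- abs(u) < 1
    if (!any(ok)) return(0)
    kern <- 0.75 * (1 - u[ok]^2) / h
    2 * sum(kern * pd$e[ok]) / (2 * pi * ri * lam^2 * area)
  }, numeric(1))
  cv <- ss_curve(r, g, reference = rep(1, length(r)), stat = "pcf")
  attr(cv, "h") <- h
  cv
}

#' Random reallocation of nests to available trees
#'
#' Draws a null nest pattern by sampling `n_nests` trees without
#' replacement, uniformly over subsets, from the year's available trees.
#' This conditions the null on the observed tree pattern, so departures
#' reflect nest clustering beyond what the trees impose.
#'
#' @param trees A [point_pattern()] of available trees.
#' @param n_nests Number of nests to place (at most the tree count).
#' @return A [point_pattern()] of `n_nests` distinct tree locations.
#' @export
random_nest_allocation <- function(trees, n_nests) {
  stopifnot(inherits(trees, "point_pattern"))
  nt <- n_points(trees)
  if (n_nests > nt) stop("n_nests exceeds the number of available trees")
  idx <- sample.int(nt, n_nests)
  point_pattern(trees$x[idx], trees$y[idx], trees$window,
                id = if (is.null(trees$id)) NULL else trees$id[idx])
}

# Pointwise envelope order statistics: floor((n+1) a/2) and
# ceil((n+1)(1 - a/2)) -- the 25th and 976th of 1000 at alpha = 0.05.
envelope_indices <- function(n_sim, alpha) {
  as.integer(c(max(1, floor((n_sim + 1) * alpha / 2)),
               min(n_sim, ceiling((n_sim + 1) * (1 - alpha / 2)))))
}

#' Habitat-conditioned Monte Carlo envelope for the PCF
#'
#' Tests observed nest clustering against the null of random nest placement
#' on the available trees: `n_sim` reallocations are drawn with
#' [random_nest_allocation()], the PCF of each is computed, and the
#' pointwise envelope is formed from the `floor((n_sim + 1) * alpha / 2)`-th
#' and `ceiling((n_sim + 1) * (1 - alpha / 2))`-th order statistics at each
#' scale (at `n_sim = 1000`, `alpha = 0.05` these are the 25th and 976th).
#' Scales where the observed PCF exceeds the upper bound are classified
#' `"clustered"`, below the lower bound `"dispersed"`, otherwise `"ns"`.
#'
#' @param trees A [point_pattern()] of available trees.
#' @param nests A [point_pattern()] of observed nests; every nest must
#'   coincide with a tree location.
#' @param r Scale grid (m).
#' @param n_sim Number of reallocations (>= 39 for `alpha = 0.05`).
#' @param alpha Pointwise significance level.
#' @param seed Integer seed.
#' @param smoothing_h PCF bandwidth passed to [estimate_pcf()]; the
#'   observed pattern's default is reused for the simulations.
#' @return A list of class `"envelope_result"`: `curve` (an [ss_curve()]
#'   with envelopes and classification), `n_sim`, `alpha`,
#'   `null_description`.
#' @export
pcf_envelope <- function(trees, nests, r = 1:100, n_sim = 199,
                         alpha = 0.05, seed = 1, smoothing_h = NULL) {
  stopifnot(inherits(trees, "point_pattern"), inherits(nests, "point_pattern"))
  if (n_sim < 39) stop("n_sim must be at least 39 for a 5% envelope")
  on_tree <- mapply(function(px, py)
    any(abs(trees$x - px) < 1e-9 & abs(trees$y - py) < 1e-9),
    nests$x, nests$y)
  if (length(on_tree) > 0 && !all(on_tree))
    stop("every nest must coincide exactly with a tree location")
  n_nests <- n_points(nests)
  obs <- estimate_pcf(nests, r, smoothing_h)
  h <- attr(obs, "h")
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      estimate_pcf(random_nest_allocation(trees, n_nests), r, h)$value
    }, numeric(length(r)))
  })
  sims <- matrix(sims, nrow = length(r))
  ei <- envelope_indices(n_sim, alpha)
  lo_i <- ei[1]; hi_i <- ei[2]
  srt <- apply(sims, 1, sort)
  lo <- srt[lo_i, ]; hi <- srt[hi_i, ]
  cls <- ifelse(obs$value > hi, "clustered",
                ifelse(obs$value < lo, "dispersed", "ns"))
  curve <- ss_curve(r, obs$value, reference = rep(1, length(r)),
                    lo = lo, hi = hi, classification = cls, stat = "pcf")
  attr(curve, "h") <- h
  structure(list(curve = curve, n_sim = n_sim, alpha = alpha,
                 null_description = sprintf(
                   "random allocation of %d nests to %d available trees",
                   n_nests, n_points(trees))),
            class = "envelope_result")
}

#' @export
print.envelope_result <- function(x, ...) {
  tab <- table(factor(x$curve$classification,
                      levels = c("clustered", "ns", "dispersed")))
  cat(sprintf("PCF envelope (%d sims, alpha = %g): %s\n", x$n_sim, x$alpha,
              x$null_description))
  cat(sprintf("  scales classified: %d clustered, %d ns, %d dispersed\n",
              tab["clustered"], tab["ns"], tab["dispersed"]))
  invisible(x)
}

#' Export a curve (with any envelope) to CSV
#'
#' @param curve An [ss_curve()] or [pcf_envelope()] result.
#' @param path Output file.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "envelope_result")) curve <- curve$curve
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
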