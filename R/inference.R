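# Percentile-CI order statistics: ceil((m+1) a/2) and floor((m+1)(1-a/2))
# -- the 3rd and 97th of 99 at alpha = 0.05.
boot_indices <- function(m, alpha) {
  as.integer(c(max(1, ceiling((m + 1) * alpha / 2)),
               min(m, floor((m + 1) * (1 - alpha / 2)))))
}

#' Parametric bootstrap confidence intervals for Thomas parameters
#'
#' Simulates `n_sim` patterns from the fitted inhomogeneous Thomas model
#' (mothers at the fitted `kappa`, dispersal `sigma`, intensity surface
#' from the base IPP fit) and refits `(kappa, sigma)` by minimum contrast
#' to each, reusing the original IPP intensity as the K weighting — the
#' two-step structure of the estimator. Percentile intervals use the
#' `ceiling((m + 1) alpha / 2)`-th and `floor((m + 1)(1 - alpha / 2))`-th
#' order statistics of the `m` successful refits (the 3rd and 97th at
#' `m = 99`, `alpha = 0.05`). Refit failures are dropped and counted; more
#' than 10% marks the result unreliable.
#'
#' @param fit A `thomas_fit`.
#' @param n_sim Number of bootstrap simulations (>= 99).
#' @param alpha Two-sided level (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `"bootstrap_ci"` with elements `kappa` and
#'   `sigma` (each `estimate`, `lo`, `hi`, `n_sim`, `alpha`), plus
#'   `n_failed` and `unreliable`.
#' @export
parametric_bootstrap_ci <- function(fit, n_sim = 199, alpha = 0.05,
                                    seed = 1) {
  stopifnot(inherits(fit, "thomas_fit"))
  if (n_sim < 99) stop("n_sim must be at least 99")
  window <- fit$base$window
  lam_grid <- fit$base$lambda_grid
  r_step <- diff(fit$khat$r[1:2])
  kap <- sig <- rep(NA_real_, n_sim)
  for (s in seq_len(n_sim)) {
    pat <- simulate_thomas_inhom(fit$kappa, fit$sigma, lam_grid, window,
                                 seed = child_seed(seed, s))
    if (n_points(pat) < 10) next
    rf <- tryCatch(
      fit_thomas_mincontrast(pat, fit$base, r_max = fit$r_max, q = fit$q,
                             r_step = r_step),
      error = function(e) NULL)
    if (is.null(rf)) next
    kap[s] <- rf$kappa; sig[s] <- rf$sigma
  }
  ok <- is.finite(kap) & is.finite(sig)
  m <- sum(ok)
  n_failed <- n_sim - m
  if (m < 2) stop("all bootstrap refits failed")
  bi <- boot_indices(m, alpha)
  lo_i <- bi[1]; hi_i <- bi[2]
  pick <- function(v, est) {
    s <- sort(v[ok])
    list(estimate = est, lo = s[lo_i], hi = s[hi_i], n_sim = m,
         alpha = alpha)
  }
  structure(list(kappa = pick(kap, fit$kappa),
                 sigma = pick(sig, fit$sigma),
                 n_failed = n_failed,
                 unreliable = n_failed > 0.1 * n_sim),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("parametric bootstrap (%d refits%s):\n", x$kappa$n_sim,
              if (x$unreliable) ", UNRELIABLE (>10% failures)" else ""))
  cat(sprintf("  kappa %.3g (%.3g, %.3g) /m^2\n",
              x$kappa$estimate, x$kappa$lo, x$kappa$hi))
  cat(sprintf("  sigma %.2f (%.2f, %.2f) m\n",
              x$sigma$estimate, x$sigma$lo, x$sigma$hi))
  invisible(x)
}

simulate_from_fit <- function(fit, seed) {
  if (inherits(fit, "thomas_fit"))
    simulate_thomas_inhom(fit$kappa, fit$sigma, fit$base$lambda_grid,
                          fit$base$window, seed = seed)
  else
    simulate_ipp(fit$lambda_grid, fit$window, seed = seed)
}

# MAD test core: observed statistic against the plain simulated mean,
# simulated statistics against their leave-self-out means, rank p-value
# with the +1 correction.
mad_pvalue <- function(L_obs, sims) {
  n_sim <- ncol(sims)
  mean_all <- rowMeans(sims)
  T_obs <- max(abs(L_obs - mean_all))
  T_sim <- vapply(seq_len(n_sim), function(s) {
    loo <- (mean_all * n_sim - sims[, s]) / (n_sim - 1)
    max(abs(sims[, s] - loo))
  }, numeric(1))
  list(T_obs = T_obs, T_sim = T_sim,
       p = (1 + sum(T_sim >= T_obs)) / (n_sim + 1))
}

#' Maximum absolute deviation goodness-of-fit test
#'
#' Monte Carlo test of whether a fitted model reproduces the observed
#' clustering structure: `n_sim` patterns are simulated from the fitted
#' model (Thomas or Poisson), the L function of each is estimated with the
#' same intensity weighting as the observed pattern, and the test statistic
#' is `T = max_r |L(r) - Lbar(r)|` over `r <= r_max`, where `Lbar` is the
#' pointwise mean of the simulated curves (leave-self-out for each
#' simulated statistic). The Monte Carlo p-value is
#' `(1 + #{T_i >= T_obs}) / (n_sim + 1)`; `p < 0.05` rejects the model at
#' the 95% acceptance level.
#'
#' @param fit A `thomas_fit` or `ipp_fit`.
#' @param pattern The observed [point_pattern()].
#' @param n_sim Number of simulations (>= 39).
#' @param r_max Upper scale limit (m).
#' @param r_step Spacing of the scale grid (m).
#' @param seed Integer seed.
#' @return A list of class `"mad_result"`: `statistic`, `p_value`,
#'   `rejected` (at 5%), `n_sim`, `r_max`.
#' @export
mad_test <- function(fit, pattern, n_sim = 99, r_max = 100, r_step = 1,
                     seed = 1) {
  stopifnot(inherits(fit, c("thomas_fit", "ipp_fit")),
            inherits(pattern, "point_pattern"))
  if (n_sim < 39) stop("n_sim must be at least 39")
  w <- pattern$window
  if (r_max > min(w$width, w$height) / 2 + 1e-9)
    stop("r_max exceeds half the shorter window side")
  r <- seq(r_step, r_max, by = r_step)
  lam_grid <- if (inherits(fit, "thomas_fit")) fit$base$lambda_grid
              else fit$lambda_grid
  weighted <- length(if (inherits(fit, "thomas_fit")) fit$base$variables
                     else fit$variables) > 0
  Lhat <- function(pat) {
    k <- estimate_K(pat, r, intensity = if (weighted) lam_grid else NULL)
    sqrt(pmax(k$value, 0) / pi)
  }
  L_obs <- Lhat(pattern)
  sims <- matrix(NA_real_, length(r), n_sim)
  for (s in seq_len(n_sim)) {
    pat <- simulate_from_fit(fit, seed = child_seed(seed, s))
    if (n_points(pat) < 2) { sims[, s] <- 0; next }
    sims[, s] <- Lhat(pat)
  }
  mp <- mad_pvalue(L_obs, sims)
  structure(list(statistic = mp$T_obs, p_value = mp$p,
                 rejected = mp$p < 0.05, n_sim = n_sim, r_max = r_max),
            class = "mad_result")
}

#' @export
print.mad_result <- function(x, ...) {
  cat(sprintf("MAD goodness-of-fit: T = %.3f, p = %.3f (%d sims)%s\n",
              x$statistic, x$p_value, x$n_sim,
              if (x$rejected) " -- model rejected at 95%" else ""))
  invisible(x)
}

find_crossings <- function(x, f) {
  d <- f - x
  s <- sign(d)
  idx <- which(s[-1] * s[-length(s)] < 0)
  vapply(idx, function(i) {
    # bisection refinement on the linear interpolant to 1e-3
    a <- x[i]; b <- x[i + 1]; fa <- d[i]; fb <- d[i + 1]
    while (b - a > 1e-3) {
      m <- (a + b) / 2
      fm <- fa + (fb - fa) * (m - x[i]) / (x[i + 1] - x[i])
      if (sign(fm) == sign(fa)) { a <- m; fa <- fm } else { b <- m; fb <- fm }
    }
    (a + b) / 2
  }, numeric(1))
}

threshold_from_curve <- function(xg, fg) {
  cr <- find_crossings(xg, fg)
  if (length(cr) == 0)
    return(list(breakeven = NA_real_, allee = NA_real_, crossings = cr))
  d_at <- function(x0) stats::approx(xg, fg - xg, x0)$y
  eps <- min(diff(xg)) / 4
  downward <- cr[vapply(cr, function(x0)
    d_at(max(x0 - eps, xg[1])) > 0 && d_at(min(x0 + eps, xg[length(xg)])) < 0,
    logical(1))]
  x_peak <- xg[which.max(fg)]
  upward <- setdiff(cr, downward)
  # Allee boundary: the curve re-emerging from the low-density dip (an
  # upward crossing below the curve's maximum).
  allee_cand <- upward[upward < x_peak]
  allee <- if (length(allee_cand)) max(allee_cand) else NA_real_
  # break-even: the control threshold at high density -- the largest
  # downward crossing beyond the Allee dip. A downward crossing below an
  # upward one is the entry into the dip, not density-dependent control.
  be_cand <- if (length(upward)) downward[downward > max(upward)] else downward
  list(breakeven = if (length(be_cand)) max(be_cand) else NA_real_,
       allee = allee,
       crossings = cr)
}

#' Break-even and Allee thresholds of the density-dependence curve
#'
#' Evaluates the endogenous prediction curve `f(x)` — expected nest count
#' in a disc of radius `disc_radius` given the lagged count `x` in the same
#' disc — on a 0.1-count grid over `x_range`, and locates its crossings
#' with the diagonal `f(x) = x` (refined by bisection to 1e-3). The
#' largest downward crossing (curve passing from above to below the
#' diagonal) is the break-even control threshold: above it, last year's
#' density-dependent repression outweighs budding growth. Any upward
#' crossing below the curve's maximum, where predictions for very isolated
#' nests fall short of the diagonal, is the Allee boundary. Confidence
#' intervals come from multivariate-normal draws of the coefficients
#' (using the clustering-adjusted covariance when supplied), recomputing
#' the crossings for each draw and taking percentile intervals; draws with
#' no crossing are counted and dropped.
#'
#' @param fit An `ipp_fit` with `nest` and `nest2` terms (or a
#'   `thomas_fit`, whose base fit is used).
#' @param x_range Length-2 numeric: range of lagged counts to scan (should
#'   reflect the observed support of the lagged density).
#' @param disc_radius Disc radius (m), default 40.
#' @param vcov Optional adjusted coefficient covariance.
#' @param n_draws Coefficient draws for the CIs (default 200).
#' @param seed Integer seed.
#' @return A list of class `"threshold_result"`: `breakeven` and `allee`
#'   (each `estimate`, `lo`, `hi`, `n_absent`), plus all `crossings` and
#'   the evaluated `curve`.
#' @export
breakeven_thresholds <- function(fit, x_range, disc_radius = 40,
                                 vcov = NULL, n_draws = 200, seed = 1) {
  if (inherits(fit, "thomas_fit")) fit <- fit$base
  stopifnot(inherits(fit, "ipp_fit"))
  if (!all(c("nest", "nest2") %in% fit$variables))
    stop("threshold analysis needs an endogenous fit with nest and nest2")
  stopifnot(length(x_range) == 2, x_range[1] < x_range[2])
  xg <- seq(x_range[1], x_range[2], by = 0.1)
  pc <- prediction_curve(fit, "nest", xg, disc_radius, vcov = vcov)
  point <- threshold_from_curve(xg, pc$fit)
  vc <- if (is.null(vcov)) fit$vcov else vcov
  draws <- with_seed(seed,
    MASS::mvrnorm(n_draws, mu = fit$coef, Sigma = vc))
  eta_base <- log(pc$fit / (pi * disc_radius^2))
  # design rows reused across draws: rebuild from the fit's metadata
  div <- fit$scaling[["nest"]]$sd
  xs <- (xg / (pi * disc_radius^2)) / div
  V <- matrix(rep(c(1, fit$stack_means[fit$variables]), each = length(xg)),
              nrow = length(xg))
  colnames(V) <- c("(Intercept)", fit$variables)
  V[, "nest"] <- xs
  V[, "nest2"] <- xs^2
  be <- al <- rep(NA_real_, n_draws)
  for (i in seq_len(n_draws)) {
    fi <- exp(as.numeric(V %*% draws[i, ])) * pi * disc_radius^2
    th <- threshold_from_curve(xg, fi)
    be[i] <- th$breakeven; al[i] <- th$allee
  }
  ci <- function(est, v) {
    ok <- is.finite(v)
    qs <- if (sum(ok) >= 10)
      stats::quantile(v[ok], c(0.025, 0.975), names = FALSE)
      else c(NA_real_, NA_real_)
    list(estimate = est, lo = qs[1], hi = qs[2], n_absent = sum(!ok))
  }
  structure(list(breakeven = ci(point$breakeven, be),
                 allee = ci(point$allee, al),
                 crossings = point$crossings,
                 curve = pc),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  fmt <- function(th, nm) {
    if (is.na(th$estimate))
      cat(sprintf("  %s: absent on the evaluated range\n", nm))
    else
      cat(sprintf("  %s: %.2f (%.2f, %.2f), absent in %d draws\n", nm,
                  th$estimate, th$lo, th$hi, th$n_absent))
  }
  cat("density-dependence thresholds (counts in the disc):\n")
  fmt(x$breakeven, "break-even")
  fmt(x$allee, "Allee boundary")
  invisible(x)
}
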