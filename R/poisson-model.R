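#' Berman-Turner quadrature scheme
#'
#' Discretises the Poisson process likelihood: dummy points on a regular
#' grid of tile centres are pooled with the data points, and each
#' quadrature point receives the counting weight
#' `tile area / (number of data + dummy points in its tile)`. The weights
#' sum to the window area by construction.
#'
#' @param pattern A [point_pattern()] of data points.
#' @param window A [plot_window()]; defaults to the pattern's window.
#' @param dummy_spacing Spacing of the dummy grid (m), default 10.
#' @return A `data.frame` of class `"quadrature"` with columns `x`, `y`,
#'   `z` (1 = data, 0 = dummy) and `w` (weight, m^2).
#' @export
make_quadrature <- function(pattern, window = pattern$window,
                            dummy_spacing = 10) {
  stopifnot(inherits(pattern, "point_pattern"), dummy_spacing > 0)
  if (dummy_spacing > min(window$width, window$height))
    stop("dummy spacing exceeds the window")
  nx <- as.integer(ceiling(window$width / dummy_spacing - 1e-9))
  ny <- as.integer(ceiling(window$height / dummy_spacing - 1e-9))
  tw <- window$width / nx; th <- window$height / ny
  dg <- expand.grid(x = (seq_len(nx) - 0.5) * tw,
                    y = (seq_len(ny) - 0.5) * th)
  x <- c(pattern$x, dg$x); y <- c(pattern$y, dg$y)
  z <- c(rep(1L, n_points(pattern)), rep(0L, nrow(dg)))
  tile <- pmin(floor(x / tw), nx - 1) * ny + pmin(floor(y / th), ny - 1)
  cnt <- table(tile)
  w <- (tw * th) / as.numeric(cnt[match(as.character(tile), names(cnt))])
  q <- data.frame(x = x, y = y, z = z, w = w)
  class(q) <- c("quadrature", "data.frame")
  attr(q, "window") <- window
  q
}

quad_covariates <- function(quad, stack) {
  X <- vapply(stack$grids,
              function(g) interp_bilinear(g, quad$x, quad$y),
              numeric(nrow(quad)))
  X <- matrix(X, nrow = nrow(quad),
              dimnames = list(NULL, names(stack$grids)))
  if (any(!is.finite(X))) stop("non-finite covariate at a quadrature point")
  X
}

#' Fit an inhomogeneous Poisson process model
#'
#' Maximises the Berman-Turner weighted Poisson likelihood
#' `sum_u w_u (y_u log lambda(u) - lambda(u))` with `y_u = z_u / w_u` and
#' log-linear intensity `log lambda(u) = b0 + b' X(u)`, via iteratively
#' reweighted least squares. Covariates are evaluated at quadrature points
#' by bilinear interpolation of the stack's 20 m grids. The coefficient
#' covariance is the inverse observed information and per-coefficient
#' two-sided normal Wald p-values are reported. AIC is
#' `2 dim(b) - 2 logLik` on the quadrature log-likelihood.
#'
#' @param pattern A [point_pattern()] of the response points.
#' @param stack A [build_covariate_stack()] result, or `NULL` for an
#'   intercept-only (homogeneous) fit.
#' @param quad A [make_quadrature()] scheme for `pattern`; built
#'   automatically if omitted.
#' @param variables Which stack variables to use (default all).
#' @return An object of class `"ipp_fit"`: coefficients, `vcov`,
#'   `loglik`, `aic`, Wald `p_values`, the fitted intensity grid
#'   `lambda_grid` (points per m^2), and scaling metadata carried from the
#'   stack.
#' @export
fit_ipp <- function(pattern, stack = NULL, quad = NULL, variables = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (is.null(quad)) quad <- make_quadrature(pattern)
  y <- quad$z / quad$w
  if (is.null(stack)) {
    X <- matrix(numeric(0), nrow = nrow(quad), ncol = 0)
    vars <- character(0)
  } else {
    stopifnot(inherits(stack, "covariate_stack"))
    vars <- if (is.null(variables)) names(stack$grids) else variables
    stopifnot(all(vars %in% names(stack$grids)))
    sub <- stack
    sub$grids <- stack$grids[vars]
    X <- quad_covariates(quad, sub)
  }
  Xf <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xf)
  if (qrx$rank < ncol(Xf)) stop("collinear covariates: singular design")
  fit <- suppressWarnings(stats::glm.fit(
    x = Xf, y = y, weights = quad$w, family = stats::poisson(),
    control = list(epsilon = 1e-12, maxit = 50)))
  if (!fit$converged) stop("IPP fit did not converge in 50 iterations")
  beta <- fit$coefficients
  lam_u <- as.numeric(exp(Xf %*% beta))
  info <- crossprod(Xf, Xf * (quad$w * lam_u))
  vc <- tryCatch(solve(info), error = function(e)
    stop("singular information matrix"))
  dimnames(vc) <- list(colnames(Xf), colnames(Xf))
  ll <- sum(ifelse(quad$z > 0, quad$w * y * log(lam_u), 0)) -
    sum(quad$w * lam_u)
  aic <- 2 * length(beta) - 2 * ll
  se <- sqrt(diag(vc))
  pv <- 2 * stats::pnorm(-abs(beta / se))
  lam_grid <- if (is.null(stack)) {
    spec <- grid_spec_for_window(pattern$window, 20)
    raster_grid(matrix(exp(beta[1]), spec$n_rows, spec$n_cols),
                origin = spec$origin, cell = spec$cell, name = "lambda")
  } else {
    predict_intensity_beta(beta, stack, vars)
  }
  structure(list(coef = beta, vcov = vc, loglik = ll, aic = aic,
                 se = se, p_values = pv, variables = vars,
                 lambda_grid = lam_grid, window = pattern$window,
                 n = n_points(pattern),
                 scaling = if (is.null(stack)) NULL else stack$scaling[vars],
                 stack_means = if (is.null(stack)) NULL else
                   vapply(stack$grids[vars],
                          function(g) mean(g$values), numeric(1)),
                 quad_spacing = attr(quad, "spacing")),
            class = "ipp_fit")
}

predict_intensity_beta <- function(beta, stack, vars) {
  g1 <- stack$grids[[vars[1]]]
  eta <- matrix(beta[1], g1$n_rows, g1$n_cols)
  for (v in vars) eta <- eta + beta[[v]] * stack$grids[[v]]$values
  raster_grid(exp(eta), origin = g1$origin, cell = g1$cell, name = "lambda")
}

#' Homogeneous Poisson null model
#'
#' Intercept-only special case of [fit_ipp()]; the maximum-likelihood
#' intensity is the empirical `n / |A|`.
#'
#' @inheritParams fit_ipp
#' @export
fit_homog_null <- function(pattern, quad = NULL) {
  if (n_points(pattern) == 0)
    stop("empty pattern: homogeneous intensity is zero, nothing to fit")
  fit_ipp(pattern, stack = NULL, quad = quad)
}

#' @export
print.ipp_fit <- function(x, ...) {
  cat(sprintf("inhomogeneous Poisson fit: %d points, %d terms, AIC %.1f\n",
              x$n, length(x$coef), x$aic))
  tab <- data.frame(coef = round(x$coef, 4), se = round(x$se, 4),
                    p = signif(x$p_values, 2))
  print(tab)
  invisible(x)
}

#' Coefficient table for a fit, optionally with an adjusted covariance
#'
#' @param fit An `ipp_fit`.
#' @param vcov Optional replacement covariance (e.g. clustering-adjusted);
#'   defaults to the fit's own.
#' @return `data.frame` with coefficient, se, z and p columns.
#' @export
coef_table <- function(fit, vcov = NULL) {
  stopifnot(inherits(fit, "ipp_fit"))
  vc <- if (is.null(vcov)) fit$vcov else vcov
  se <- sqrt(diag(vc))
  z <- fit$coef / se
  data.frame(term = names(fit$coef), coef = as.numeric(fit$coef),
             se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
             row.names = NULL)
}

#' Compare fits by AIC
#'
#' @param fits Named list of `ipp_fit` objects on the same data (the same
#'   point count); lower AIC means more information explained.
#' @return `data.frame` ranked by AIC with `delta_vs_null` where a fit
#'   named `"null"` is present.
#' @export
compare_aic <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1)
    stop("fits were made on different datasets (point counts differ)")
  aic <- vapply(fits, function(f) f$aic, numeric(1))
  out <- data.frame(model = names(fits), aic = aic, row.names = NULL)
  if ("null" %in% names(fits))
    out$delta_vs_null <- out$aic - aic[["null"]]
  out[order(out$aic), , drop = FALSE]
}

#' Predicted intensity surface from a fit
#'
#' `lambda(z) = exp(b0 + b' X(z))` evaluated cellwise on the stack's grids.
#'
#' @param fit An `ipp_fit`.
#' @param stack A covariate stack carrying every variable in the fit.
#' @return A [raster_grid()] of intensities (points per m^2).
#' @export
predict_intensity <- function(fit, stack) {
  stopifnot(inherits(fit, "ipp_fit"))
  if (length(fit$variables) == 0) {
    g1 <- stack$grids[[1]]
    return(raster_grid(matrix(exp(fit$coef[1]), g1$n_rows, g1$n_cols),
                       origin = g1$origin, cell = g1$cell, name = "lambda"))
  }
  if (!all(fit$variables %in% names(stack$grids)))
    stop("stack is missing covariates used by the fit")
  predict_intensity_beta(fit$coef, stack, fit$variables)
}

#' Prediction curve over one covariate, on the count-in-disc scale
#'
#' Recreates the model response curve: the expected number of points within
#' a disc of radius `disc_radius` as a function of one covariate expressed
#' as a count in that disc, all other covariates held at their plot means.
#' The axis count `x` is converted to a density `x / (pi R^2)`, scaled by
#' the variable's recorded divisor, the linear predictor
#' `eta = b0 + b' X` is evaluated and the prediction
#' `exp(eta) * pi R^2` returned with a delta-method confidence interval
#' `exp(eta +/- z se(eta)) * pi R^2`. When the fit contains both `nest` and
#' `nest2` and the axis variable is `nest`, the quadratic term co-varies as
#' the square of the axis value.
#'
#' @param fit An `ipp_fit` (fitted with a covariate stack).
#' @param variable Name of the axis variable (e.g. `"nest"` or `"trees"`).
#' @param x_counts Axis values: counts within the disc.
#' @param disc_radius Disc radius (m), default 40.
#' @param vcov Optional adjusted covariance to propagate instead of the
#'   fit's own.
#' @param level Confidence level (default 0.95).
#' @return An `ss_curve`-like `data.frame` with columns `x` (count),
#'   `fit`, `lo`, `hi` (counts in the disc).
#' @export
prediction_curve <- function(fit, variable, x_counts, disc_radius = 40,
                             vcov = NULL, level = 0.95) {
  stopifnot(inherits(fit, "ipp_fit"))
  if (!(variable %in% fit$variables))
    stop(sprintf("variable '%s' is not in the fit", variable))
  if (is.null(fit$scaling))
    stop("fit carries no scaling metadata; refit with a covariate stack")
  vc <- if (is.null(vcov)) fit$vcov else vcov
  disc <- pi * disc_radius^2
  div <- fit$scaling[[variable]]$sd
  vars <- fit$variables
  base <- fit$stack_means[vars]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  quadratic <- variable == "nest" && "nest2" %in% vars
  rows <- lapply(x_counts, function(xc) {
    xs <- (xc / disc) / div
    v <- base
    v[[variable]] <- xs
    if (quadratic) v[["nest2"]] <- xs^2
    vv <- c(1, v)
    eta <- sum(vv * fit$coef)
    se <- sqrt(as.numeric(t(vv) %*% vc %*% vv))
    data.frame(x = xc, fit = exp(eta) * disc,
               lo = exp(eta - zq * se) * disc,
               hi = exp(eta + zq * se) * disc)
  })
  out <- do.call(rbind, rows)
  attr(out, "variable") <- variable
  attr(out, "disc_radius") <- disc_radius
  out
}
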