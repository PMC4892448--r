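#' Gaussian kernel density surface of a point pattern
#'
#' Evaluates the (unnormalised-domain) Gaussian kernel density estimate at
#' every cell centre of a raster grid:
#' `d(z) = sum_i (2 pi h^2)^-1 exp(-|z - x_i|^2 / (2 h^2))`, in points per
#' m^2. No edge correction is applied, so values within a bandwidth or two
#' of the border are biased low; the model covariates inherit this
#' convention. A 20 m bandwidth places 95% of each kernel's weight within
#' 40 m of its centre (the univariate two-sigma rule along each axis).
#'
#' @param pattern A [point_pattern()].
#' @param bandwidth Kernel standard deviation (m), default 20.
#' @param grid Either a [raster_grid()] whose geometry to copy, or a
#'   geometry list as produced internally; defaults to the 20 m grid
#'   covering the pattern's window.
#' @param name Label for the resulting grid.
#' @return A [raster_grid()] of densities (points per m^2).
#' @export
kernel_density_grid <- function(pattern, bandwidth = 20, grid = NULL,
                                name = "density") {
  stopifnot(inherits(pattern, "point_pattern"), bandwidth > 0)
  spec <- if (is.null(grid)) grid_spec_for_window(pattern$window, 20)
          else if (inherits(grid, "raster_grid"))
            list(origin = grid$origin, cell = grid$cell,
                 n_cols = grid$n_cols, n_rows = grid$n_rows)
          else grid
  cx <- spec$origin[1] + spec$cell * (seq_len(spec$n_cols) - 0.5)
  cy <- spec$origin[2] + spec$cell * (seq_len(spec$n_rows) - 0.5)
  n <- n_points(pattern)
  vals <- matrix(0, spec$n_rows, spec$n_cols)
  if (n > 0) {
    h2 <- bandwidth^2
    # separable kernel: outer product of per-axis Gaussians per point
    gx <- exp(-outer(cx, pattern$x, function(a, b) (a - b)^2) / (2 * h2))
    gy <- exp(-outer(cy, pattern$y, function(a, b) (a - b)^2) / (2 * h2))
    vals <- (gy %*% t(gx)) / (2 * pi * h2)
  }
  raster_grid(vals, origin = spec$origin, cell = spec$cell, name = name)
}

#' Slope surface from a DEM
#'
#' Slope as tangent (rise over run, dimensionless) from a digital elevation
#' model by Horn's 3x3 finite-difference method at interior cells; border
#' cells use one-sided differences. An exactly planar DEM with gradient
#' `(gx, gy)` yields slope `sqrt(gx^2 + gy^2)` everywhere.
#'
#' @param dem A [raster_grid()] of elevations (m), at least 3x3.
#' @return A [raster_grid()] named `"slope"`.
#' @export
slope_grid <- function(dem) {
  stopifnot(inherits(dem, "raster_grid"))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("DEM must be at least 3x3 cells")
  cl <- dem$cell
  # pad by edge replication; Horn weights on the padded matrix reduce to
  # one-sided differences (halved span) at the borders
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  i <- 2:(nr + 1); j <- 2:(nc + 1)
  gx <- ((zp[i - 1, j + 1] + 2 * zp[i, j + 1] + zp[i + 1, j + 1]) -
         (zp[i - 1, j - 1] + 2 * zp[i, j - 1] + zp[i + 1, j - 1])) / (8 * cl)
  gy <- ((zp[i + 1, j - 1] + 2 * zp[i + 1, j] + zp[i + 1, j + 1]) -
         (zp[i - 1, j - 1] + 2 * zp[i - 1, j] + zp[i - 1, j + 1])) / (8 * cl)
  # replication halves the finite-difference span on the borders; restore it
  gx[, 1] <- gx[, 1] * 2; gx[, nc] <- gx[, nc] * 2
  gy[1, ] <- gy[1, ] * 2; gy[nr, ] <- gy[nr, ] * 2
  raster_grid(sqrt(gx^2 + gy^2), origin = dem$origin, cell = dem$cell,
              name = "slope")
}

#' Topographic wetness index from a DEM
#'
#' Computes `ln(Ac / s)` per cell, where `Ac` is the upstream contributing
#' area (m^2) from single-direction D8 flow accumulation (each cell
#' contributes its own area and passes all accumulated area to its steepest
#' downslope neighbour) and `s` is slope (tangent) floored at `slope_floor`.
#' Flow ties are broken in the fixed neighbour order E, SE, S, SW, W, NW, N,
#' NE. On a flat DEM every cell keeps only its own area and takes the slope
#' floor. Adding a constant to the DEM leaves the result unchanged.
#'
#' @param dem A [raster_grid()] of elevations.
#' @param slope_floor Minimum slope used in the ratio (default `1e-3`).
#' @return A [raster_grid()] named `"wet"`.
#' @export
twi_grid <- function(dem, slope_floor = 1e-3) {
  stopifnot(inherits(dem, "raster_grid"), slope_floor > 0)
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  cl <- dem$cell
  # neighbour offsets in tie-break order: E, SE, S, SW, W, NW, N, NE
  # (di along rows/south-north axis: row + 1 is north)
  off <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
              c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  dist <- cl * c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))
  recv <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      best <- 0; best_g <- 0
      for (k in 1:8) {
        ii <- i + off[[k]][1]; jj <- j + off[[k]][2]
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        g <- (z[i, j] - z[ii, jj]) / dist[k]
        if (g > best_g + 1e-12) { best_g <- g; best <- (jj - 1) * nr + ii }
      }
      if (best > 0) recv[i, j] <- best
    }
  }
  acc <- matrix(cl^2, nr, nc)
  ord <- order(z, decreasing = TRUE)   # process from high to low ground
  for (cell in ord) {
    r <- recv[cell]
    if (!is.na(r)) acc[r] <- acc[r] + acc[cell]
  }
  s <- pmax(slope_grid(dem)$values, slope_floor)
  raster_grid(log(acc / s), origin = dem$origin, cell = dem$cell,
              name = "wet")
}

#' Pooled scaling statistics for a covariate
#'
#' Mean and population standard deviation pooled over all cells of all
#' years' grids of one variable, so that scaled covariates have unit sd
#' "across the plot and between all years". A constant variable (zero
#' pooled sd) is unusable as a covariate and raises an error.
#'
#' @param grids A single [raster_grid()] or a list of them (one per year),
#'   sharing a common shape.
#' @return A list with `mean`, `sd` (population), `n_cells`.
#' @export
pooled_scaling_stats <- function(grids) {
  if (inherits(grids, "raster_grid")) grids <- list(grids)
  stopifnot(length(grids) >= 1)
  vals <- unlist(lapply(grids, function(g) as.numeric(g$values)))
  m <- mean(vals)
  s <- pop_sd(vals)
  if (s == 0) stop("constant variable: zero pooled standard deviation")
  list(mean = m, sd = s, n_cells = length(vals))
}

#' Pooled scaling records for all model covariates
#'
#' Convenience wrapper that computes the pooled scaling statistics the
#' covariate stack needs: lagged nest density and tree density pooled over
#' all requested model years (density variables are scaled but not centred,
#' so only the sd is used), and the abiotic terrain variables (elevation,
#' slope, wetness), which are normalised (centred and scaled) over the plot.
#'
#' @param census A tree census series.
#' @param dem A [raster_grid()] DEM, or `NULL` to skip terrain variables.
#' @param years Model years (each needs its lag year present).
#' @param bandwidth Kernel bandwidth (m).
#' @return Named list of scaling records, one per variable.
#' @export
compute_scaling <- function(census, dem, years, bandwidth = 20) {
  window <- attr(census, "window")
  spec <- if (is.null(dem)) grid_spec_for_window(window, 20) else dem
  nest_grids <- lapply(years, function(y)
    kernel_density_grid(census_pattern(census, y - 1, window, "nests"),
                        bandwidth, spec, "nest"))
  tree_grids <- lapply(years, function(y)
    kernel_density_grid(census_pattern(census, y, window, "trees"),
                        bandwidth, spec, "trees"))
  out <- list(nest = pooled_scaling_stats(nest_grids),
              trees = pooled_scaling_stats(tree_grids))
  if (!is.null(dem)) {
    out$elev <- pooled_scaling_stats(dem)
    out$slope <- pooled_scaling_stats(slope_grid(dem))
    out$wet <- pooled_scaling_stats(twi_grid(dem))
  }
  out
}

#' Build the covariate stack for one model year
#'
#' Assembles the six model covariates on a common grid: `nest` (scaled
#' kernel density of the previous year's nests), `nest2` (its elementwise
#' square), `trees` (scaled kernel density of the current year's trees) and
#' the normalised terrain variables `elev`, `slope`, `wet`. Density
#' variables are divided by their pooled sd but not centred (they stay
#' non-negative); terrain variables are centred to mean 0 and scaled to sd
#' 1 over the plot. The applied divisors and centres are recorded for
#' back-transformation (e.g. converting fitted effects back to counts in a
#' 40 m disc).
#'
#' @param census A tree census series containing years `year` and
#'   `year - 1`.
#' @param dem A [raster_grid()] DEM or `NULL` (terrain variables dropped).
#' @param year The model year (its nests are the response; its lag year
#'   supplies the endogenous covariate).
#' @param stats Scaling records from [compute_scaling()], computed over the
#'   full series.
#' @param bandwidth Kernel bandwidth (m).
#' @return An object of class `"covariate_stack"`: list of grids plus
#'   scaling metadata.
#' @export
build_covariate_stack <- function(census, dem, year, stats,
                                  bandwidth = 20) {
  window <- attr(census, "window")
  yrs <- census_years(census)
  if (!((year - 1) %in% yrs))
    stop(sprintf("lag year %d missing from census", year - 1))
  spec <- if (is.null(dem)) grid_spec_for_window(window, 20) else dem
  nest_raw <- kernel_density_grid(census_pattern(census, year - 1, window,
                                                 "nests"),
                                  bandwidth, spec, "nest")
  trees_raw <- kernel_density_grid(census_pattern(census, year, window,
                                                  "trees"),
                                   bandwidth, spec, "trees")
  scale_g <- function(g, rec, centre) {
    v <- if (centre) (g$values - rec$mean) / rec$sd else g$values / rec$sd
    raster_grid(v, origin = g$origin, cell = g$cell, name = g$name)
  }
  grids <- list(nest = scale_g(nest_raw, stats$nest, FALSE))
  grids$nest2 <- raster_grid(grids$nest$values^2, origin = nest_raw$origin,
                             cell = nest_raw$cell, name = "nest2")
  grids$trees <- scale_g(trees_raw, stats$trees, FALSE)
  scaling <- list(
    nest = c(stats$nest[c("mean", "sd")], centred = FALSE),
    nest2 = list(mean = NA, sd = stats$nest$sd, centred = FALSE,
                 note = "square of scaled nest"),
    trees = c(stats$trees[c("mean", "sd")], centred = FALSE))
  if (!is.null(dem)) {
    grids$elev <- scale_g(dem, stats$elev, TRUE)
    sl <- slope_grid(dem); we <- twi_grid(dem)
    grids$slope <- scale_g(sl, stats$slope, TRUE)
    grids$wet <- scale_g(we, stats$wet, TRUE)
    scaling$elev <- c(stats$elev[c("mean", "sd")], centred = TRUE)
    scaling$slope <- c(stats$slope[c("mean", "sd")], centred = TRUE)
    scaling$wet <- c(stats$wet[c("mean", "sd")], centred = TRUE)
  }
  structure(list(grids = grids, scaling = scaling, year = year,
                 bandwidth = bandwidth, window = window),
            class = "covariate_stack")
}

# Assemble a covariate_stack from ready-made grids (simulation studies and
# tests); scaling records default to unit divisors.
as_covariate_stack <- function(grids, window, scaling = NULL, year = 0L,
                               bandwidth = 20) {
  if (is.null(scaling))
    scaling <- lapply(grids, function(g)
      list(mean = 0, sd = 1, centred = FALSE))
  structure(list(grids = grids, scaling = scaling, year = year,
                 bandwidth = bandwidth, window = window),
            class = "covariate_stack")
}

#' @export
print.covariate_stack <- function(x, ...) {
  cat(sprintf("covariate stack for year %d: %s\n", x$year,
              paste(names(x$grids), collapse = ", ")))
  invisible(x)
}

#' Summarise a covariate stack as a manifest table
#'
#' @param stack A [build_covariate_stack()] result.
#' @return A `data.frame` with one row per variable: grid mean/sd after
#'   scaling and the applied divisor/centre.
#' @export
stack_manifest <- function(stack) {
  stopifnot(inherits(stack, "covariate_stack"))
  rows <- lapply(names(stack$grids), function(nm) {
    g <- stack$grids[[nm]]
    sc <- stack$scaling[[nm]]
    data.frame(variable = nm, year = stack$year,
               mean = mean(g$values), sd = pop_sd(g$values),
               divisor = as.numeric(sc$sd),
               centred = isTRUE(sc$centred))
  })
  do.call(rbind, rows)
}
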