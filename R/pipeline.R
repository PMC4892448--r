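#' Read and write census tables
#'
#' The pipeline's census interchange format is a plain CSV with header
#' `year,tree_id,x,y,nest` and `nest` coded 0/1. Reading validates the
#' header, the nest flag, coordinate containment in the window and
#' duplicate `(year, tree_id)` pairs, reporting offending line numbers.
#'
#' @param path CSV file path.
#' @param window A [plot_window()] the coordinates must fall in.
#' @return A tree census series (`data.frame` of class `"tree_census"`).
#' @export
read_census <- function(path, window) {
  stopifnot(inherits(window, "plot_window"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "tree_id", "x", "y", "nest")
  if (!identical(names(df), need))
    stop(sprintf("census header must be exactly '%s'",
                 paste(need, collapse = ",")))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  bad_nest <- which(!(df$nest %in% c(0, 1)))
  if (length(bad_nest) > 0)
    stop(sprintf("nest flag must be 0 or 1; bad rows at lines: %s",
                 paste(line[bad_nest], collapse = ", ")))
  bad_xy <- which(!inside_window(df$x, df$y, window) |
                    !is.finite(df$x) | !is.finite(df$y))
  if (length(bad_xy) > 0)
    stop(sprintf("coordinates outside the window at lines: %s",
                 paste(line[bad_xy], collapse = ", ")))
  dup <- duplicated(df[, c("year", "tree_id")])
  if (any(dup))
    stop(sprintf("duplicate (year, tree_id) at lines: %s",
                 paste(line[dup], collapse = ", ")))
  df$year <- as.integer(df$year)
  df$nest <- as.integer(df$nest)
  class(df) <- c("tree_census", "data.frame")
  attr(df, "window") <- window
  df
}

#' @rdname read_census
#' @param census A tree census series to write.
#' @export
write_census <- function(census, path) {
  utils::write.csv(as.data.frame(census)[, c("year", "tree_id", "x", "y",
                                             "nest")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects the analysis constants in one place. The defaults are the
#' study conditions of the full annual analysis: 20 m kernel bandwidth,
#' 40 m reporting disc, 1-100 m scale range, 1000 envelope simulations,
#' 999 bootstrap and MAD simulations at the 95% level. Reduced `n_sim`
#' values give proportionally faster (but coarser) Monte Carlo inference.
#'
#' @param years Model years; default all census years after the first
#'   (each model year needs its lag year).
#' @param bandwidth Kernel bandwidth (m).
#' @param disc_radius Reporting disc radius (m).
#' @param r_max,r_step Scale grid for K/PCF/L (m).
#' @param n_envelope,n_boot,n_mad Simulation counts for the envelope test,
#'   parametric bootstrap and MAD test.
#' @param alpha Significance level.
#' @param dummy_spacing Quadrature dummy spacing (m).
#' @param seed Master seed; every stage derives its own sub-stream.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(years = NULL, bandwidth = 20, disc_radius = 40,
                            r_max = 100, r_step = 1, n_envelope = 1000,
                            n_boot = 999, n_mad = 999, alpha = 0.05,
                            dummy_spacing = 10, seed = 1) {
  stopifnot(bandwidth > 0, disc_radius > 0, r_max > 0, alpha > 0, alpha < 1)
  min_sim <- ceiling(2 / alpha) - 1
  if (n_envelope < min_sim || n_mad < min_sim || n_boot < min_sim)
    stop(sprintf("all n_sim must be at least %d for alpha = %g",
                 min_sim, alpha))
  structure(list(years = years, bandwidth = bandwidth,
                 disc_radius = disc_radius, r_max = r_max, r_step = r_step,
                 n_envelope = n_envelope, n_boot = n_boot, n_mad = n_mad,
                 alpha = alpha, dummy_spacing = dummy_spacing, seed = seed),
            class = "pipeline_config")
}

analyse_year_internal <- function(census, dem, year, stats, config) {
  window <- attr(census, "window")
  cfg <- config
  r <- seq(cfg$r_step, cfg$r_max, by = cfg$r_step)
  trees <- census_pattern(census, year, window, "trees")
  nests <- census_pattern(census, year, window, "nests")
  lag_nests <- census_pattern(census, year - 1, window, "nests")
  stack <- build_covariate_stack(census, dem, year, stats, cfg$bandwidth)
  exo_vars <- intersect(c("trees", "elev", "slope", "wet"),
                        names(stack$grids))
  endo_vars <- c("nest", "nest2")
  env <- pcf_envelope(trees, nests, r, n_sim = cfg$n_envelope,
                      alpha = cfg$alpha, seed = child_seed(cfg$seed, year))
  quad <- make_quadrature(nests, window, cfg$dummy_spacing)
  fit_null <- fit_homog_null(nests, quad)
  fit_exo <- fit_ipp(nests, stack, quad, variables = exo_vars)
  fit_endo <- fit_ipp(nests, stack, quad, variables = endo_vars)
  aic_tab <- compare_aic(list(null = fit_null, exogenous = fit_exo,
                              endogenous = fit_endo))
  tfit_exo <- fit_thomas_mincontrast(nests, fit_exo, r_max = cfg$r_max,
                                     r_step = cfg$r_step)
  tfit_endo <- fit_thomas_mincontrast(nests, fit_endo, r_max = cfg$r_max,
                                      r_step = cfg$r_step)
  adj_exo <- adjusted_coef_vcov(fit_exo, tfit_exo, stack)
  adj_endo <- adjusted_coef_vcov(fit_endo, tfit_endo, stack)
  ci_exo <- parametric_bootstrap_ci(tfit_exo, n_sim = cfg$n_boot,
                                    alpha = cfg$alpha,
                                    seed = child_seed(cfg$seed, year * 7 + 1))
  ci_endo <- parametric_bootstrap_ci(tfit_endo, n_sim = cfg$n_boot,
                                     alpha = cfg$alpha,
                                     seed = child_seed(cfg$seed, year * 7 + 2))
  mad_exo <- mad_test(tfit_exo, nests, n_sim = cfg$n_mad, r_max = cfg$r_max,
                      r_step = cfg$r_step,
                      seed = child_seed(cfg$seed, year * 7 + 3))
  mad_endo <- mad_test(tfit_endo, nests, n_sim = cfg$n_mad,
                       r_max = cfg$r_max, r_step = cfg$r_step,
                       seed = child_seed(cfg$seed, year * 7 + 4))
  disc <- pi * cfg$disc_radius^2
  lag_counts <- kernel_density_at(lag_nests, nests$x, nests$y,
                                  cfg$bandwidth) * disc
  x_hi <- max(lag_counts, 1)
  thresholds <- tryCatch(
    breakeven_thresholds(fit_endo, x_range = c(0.1, max(x_hi, 10)),
                         disc_radius = cfg$disc_radius, vcov = adj_endo,
                         seed = child_seed(cfg$seed, year * 7 + 5)),
    error = function(e) NULL)
  coef_rows <- rbind(
    cbind(model = "exogenous", coef_table(fit_exo),
          p_adjusted = coef_table(fit_exo, adj_exo)$p),
    cbind(model = "endogenous", coef_table(fit_endo),
          p_adjusted = coef_table(fit_endo, adj_endo)$p))
  list(year = year, n_trees = n_points(trees), n_nests = n_points(nests),
       envelope = env, stack_manifest = stack_manifest(stack),
       fits = list(null = fit_null, exogenous = fit_exo,
                   endogenous = fit_endo),
       aic = aic_tab, coef_table = cbind(year = year, coef_rows),
       thomas = list(exogenous = tfit_exo, endogenous = tfit_endo),
       adjusted_vcov = list(exogenous = adj_exo, endogenous = adj_endo),
       bootstrap = list(exogenous = ci_exo, endogenous = ci_endo),
       mad = list(exogenous = mad_exo, endogenous = mad_endo),
       thresholds = thresholds)
}

#' Run the full annual analysis pipeline
#'
#' For every model year (all census years with a lag year available, or
#' the subset in the config): builds the covariate stack, runs the
#' habitat-conditioned PCF envelope test, fits the homogeneous null and
#' the exogenous and endogenous IPP models with an AIC comparison, fits
#' both inhomogeneous Thomas cluster models by minimum contrast, computes
#' clustering-adjusted coefficient tables, bootstrap CIs for
#' `(kappa, sigma)`, MAD goodness-of-fit tests, and the break-even /
#' Allee threshold analysis of the endogenous model. Deterministic given
#' the config seed. A year whose stage fails is reported as a partial
#' result with the error message rather than aborting the rest.
#'
#' @param census A tree census series (with nests flagged).
#' @param dem A [raster_grid()] DEM, or `NULL` to run without terrain
#'   covariates (exogenous model reduced to tree density, flagged in the
#'   report).
#' @param config A [pipeline_config()].
#' @return A list of class `"pipeline_report"`: per-year results plus the
#'   pooled scaling records and the config.
#' @export
run_pipeline <- function(census, dem = NULL,
                         config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  yrs <- census_years(census)
  model_years <- if (is.null(config$years)) yrs[-1] else config$years
  stopifnot(all((model_years - 1) %in% yrs))
  stats <- compute_scaling(census, dem, model_years, config$bandwidth)
  results <- lapply(model_years, function(y) {
    tryCatch(analyse_year_internal(census, dem, y, stats, config),
             error = function(e) list(year = y, failed = TRUE,
                                      error = conditionMessage(e)))
  })
  names(results) <- as.character(model_years)
  structure(list(years = results, scaling = stats, config = config,
                 terrain = !is.null(dem)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d model years%s\n", length(x$years),
              if (x$terrain) "" else " (no terrain covariates)"))
  for (res in x$years) {
    if (isTRUE(res$failed)) {
      cat(sprintf("  %d: FAILED (%s)\n", res$year, res$error)); next
    }
    cat(sprintf(
      "  %d: %d nests / %d trees; AIC null %.0f exo %.0f endo %.0f; MAD p exo %.3f endo %.3f\n",
      res$year, res$n_nests, res$n_trees,
      res$fits$null$aic, res$fits$exogenous$aic, res$fits$endogenous$aic,
      res$mad$exogenous$p_value, res$mad$endogenous$p_value))
  }
  invisible(x)
}

#' Write a pipeline report to CSV/JSON files
#'
#' Produces the consolidated output tables: per-coefficient summaries
#' (IPP and clustering-adjusted p-values), the per-year AIC comparison,
#' the Thomas parameter table with bootstrap CIs and MAD p-values, the
#' envelope classifications, thresholds and a JSON digest.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ok <- Filter(function(r) !isTRUE(r$failed), report$years)
  if (length(ok) > 0) {
    coefs <- do.call(rbind, lapply(ok, `[[`, "coef_table"))
    utils::write.csv(coefs, file.path(dir, "coefficients.csv"),
                     row.names = FALSE)
    aic <- do.call(rbind, lapply(ok, function(r)
      cbind(year = r$year, r$aic)))
    utils::write.csv(aic, file.path(dir, "aic.csv"), row.names = FALSE)
    th_rows <- unlist(lapply(ok, function(r) list(
      list(year = r$year, model = "exogenous", fit = r$thomas$exogenous,
           ci = r$bootstrap$exogenous, mad = r$mad$exogenous),
      list(year = r$year, model = "endogenous", fit = r$thomas$endogenous,
           ci = r$bootstrap$endogenous, mad = r$mad$endogenous))),
      recursive = FALSE)
    utils::write.csv(thomas_summary_table(th_rows),
                     file.path(dir, "thomas.csv"), row.names = FALSE)
    env <- do.call(rbind, lapply(ok, function(r)
      cbind(year = r$year, as.data.frame(r$envelope$curve))))
    utils::write.csv(env, file.path(dir, "envelopes.csv"),
                     row.names = FALSE)
    thr <- do.call(rbind, lapply(ok, function(r) {
      t <- r$thresholds
      data.frame(year = r$year,
                 breakeven = if (is.null(t)) NA else t$breakeven$estimate,
                 breakeven_lo = if (is.null(t)) NA else t$breakeven$lo,
                 breakeven_hi = if (is.null(t)) NA else t$breakeven$hi,
                 allee = if (is.null(t)) NA else t$allee$estimate)
    }))
    utils::write.csv(thr, file.path(dir, "thresholds.csv"),
                     row.names = FALSE)
  }
  digest <- lapply(report$years, function(r) {
    if (isTRUE(r$failed)) return(list(year = r$year, failed = TRUE,
                                      error = r$error))
    list(year = r$year, n_trees = r$n_trees, n_nests = r$n_nests,
         aic = stats::setNames(as.list(r$aic$aic), r$aic$model),
         sigma_exo = r$thomas$exogenous$sigma,
         kappa_exo = r$thomas$exogenous$kappa,
         mad_p = list(exogenous = r$mad$exogenous$p_value,
                      endogenous = r$mad$endogenous$p_value),
         breakeven = if (is.null(r$thresholds)) NA else
           r$thresholds$breakeven$estimate)
  })
  jsonlite::write_json(digest, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
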