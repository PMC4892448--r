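#' Parameters for budding nest dynamics
#'
#' Bundles the demographic parameters of the synthetic nest simulation:
#' colony reproduction by budding (daughter nests dispersing a short Gaussian
#' distance from the mother and settling on a nearby empty tree) opposed by
#' density-dependent mortality (the "natural enemies" side of the
#' activation-repression narrative), with an optional Allee penalty for very
#' isolated nests.
#'
#' Survival is a decreasing logistic in the lagged local nest density `D`
#' (expressed as a count within a `disc_radius` disc, computed from a 20 m
#' Gaussian kernel):
#' `survival(D) = s_max / (1 + exp((D - d0) / width))`, multiplied by
#' `1 - allee_penalty` where `D < allee_floor`.
#'
#' @param initial_nests Nests placed on random trees in the first year.
#' @param bud_rate Expected daughter nests per surviving nest per year.
#' @param disperse_sd Standard deviation of the isotropic Gaussian budding
#'   displacement (m).
#' @param s_max Survival at zero density (upper asymptote).
#' @param d0 Density (count in the disc) at which survival is half `s_max`.
#' @param width Logistic width of the survival decline (counts).
#' @param allee_floor Density floor below which the Allee penalty applies;
#'   `0` disables it.
#' @param allee_penalty Proportional extra mortality below the floor.
#' @param bandwidth Gaussian kernel bandwidth for the lagged density (m).
#' @param disc_radius Disc radius used to express density as a count (m).
#' @return A list of class `"dynamics_params"`.
#' @export
dynamics_params <- function(initial_nests = 250, bud_rate = 0.35,
                            disperse_sd = 8, s_max = 0.95, d0 = 40,
                            width = 8, allee_floor = 2, allee_penalty = 0.35,
                            bandwidth = 20, disc_radius = 40) {
  stopifnot(bud_rate >= 0, disperse_sd > 0, s_max >= 0, s_max <= 1,
            width > 0, allee_penalty >= 0, allee_penalty <= 1,
            bandwidth > 0, disc_radius > 0)
  structure(list(initial_nests = initial_nests, bud_rate = bud_rate,
                 disperse_sd = disperse_sd, s_max = s_max, d0 = d0,
                 width = width, allee_floor = allee_floor,
                 allee_penalty = allee_penalty, bandwidth = bandwidth,
                 disc_radius = disc_radius),
            class = "dynamics_params")
}

survival_prob <- function(d_count, params) {
  p <- params$s_max / (1 + exp((d_count - params$d0) / params$width))
  if (params$allee_floor > 0)
    p <- p * ifelse(d_count < params$allee_floor, 1 - params$allee_penalty, 1)
  p
}

# Gaussian kernel density of a pattern evaluated at arbitrary points
# (points per m^2), no edge correction.
kernel_density_at <- function(pattern, x, y, bandwidth) {
  n <- n_points(pattern)
  if (n == 0) return(rep(0, length(x)))
  h2 <- bandwidth^2
  out <- numeric(length(x))
  for (i in seq_len(n)) {
    d2 <- (x - pattern$x[i])^2 + (y - pattern$y[i])^2
    out <- out + exp(-d2 / (2 * h2))
  }
  out / (2 * pi * h2)
}

#' Simulate budding nest dynamics on a tree census
#'
#' Places an initial cohort of nests on random trees, then iterates the
#' annual cycle: (a) each nest survives with probability
#' `survival(D)` where `D` is last year's Gaussian-kernel nest density at the
#' nest's location (as a count within the 40 m disc); (b) each survivor
#' produces `Poisson(bud_rate)` daughters, each proposed at the mother's
#' location plus an isotropic Gaussian displacement and snapped to the
#' nearest unoccupied tree within `2 * disperse_sd`, or discarded if no such
#' tree exists; nests on trees removed by thinning die with their tree.
#' With decreasing survival this produces endogenously clustered patterns.
#'
#' @param trees A tree census series from [gen_tree_series()].
#' @param params A [dynamics_params()].
#' @param seed Integer seed.
#' @return The census with the `nest` column filled in (class
#'   `"tree_census"`).
#' @export
simulate_nest_dynamics <- function(trees, params = dynamics_params(),
                                   seed = 1) {
  stopifnot(inherits(params, "dynamics_params"))
  window <- attr(trees, "window")
  if (is.null(window)) stop("census must carry its window attribute")
  years <- census_years(trees)
  census <- trees
  census$nest <- 0L
  disc_area <- pi * params$disc_radius^2
  with_seed(seed, {
    yr1 <- census$year == years[1]
    ids1 <- census$tree_id[yr1]
    if (params$initial_nests > length(ids1))
      stop("initial_nests exceeds the first-year tree count")
    occupied <- sample(ids1, params$initial_nests)
    census$nest[yr1][match(occupied, ids1)] <- 1L
    for (k in seq_along(years)[-1]) {
      prev <- census[census$year == years[k - 1] & census$nest == 1L, ,
                     drop = FALSE]
      rows <- census$year == years[k]
      cur <- census[rows, , drop = FALSE]
      if (nrow(prev) == 0) next
      prev_pat <- point_pattern(prev$x, prev$y, window, id = prev$tree_id)
      # carried-over nests: tree must still stand
      cand <- prev[prev$tree_id %in% cur$tree_id, , drop = FALSE]
      occ_ids <- character(0)
      if (nrow(cand) > 0) {
        d_cnt <- kernel_density_at(prev_pat, cand$x, cand$y,
                                   params$bandwidth) * disc_area
        surv <- stats::runif(nrow(cand)) < survival_prob(d_cnt, params)
        occ_ids <- cand$tree_id[surv]
      }
      # budding from survivors
      if (length(occ_ids) > 0 && params$bud_rate > 0) {
        mothers <- cand[match(occ_ids, cand$tree_id), , drop = FALSE]
        n_d <- stats::rpois(nrow(mothers), params$bud_rate)
        for (m in seq_len(nrow(mothers))) {
          if (n_d[m] == 0) next
          for (dd in seq_len(n_d[m])) {
            px <- mothers$x[m] + stats::rnorm(1, sd = params$disperse_sd)
            py <- mothers$y[m] + stats::rnorm(1, sd = params$disperse_sd)
            free <- !(cur$tree_id %in% occ_ids)
            if (!any(free)) next
            dist2 <- (cur$x - px)^2 + (cur$y - py)^2
            dist2[!free] <- Inf
            jbest <- which.min(dist2)
            if (dist2[jbest] <= (2 * params$disperse_sd)^2)
              occ_ids <- c(occ_ids, cur$tree_id[jbest])
          }
        }
      }
      census$nest[rows] <- as.integer(cur$tree_id %in% occ_ids)
    }
    census
  })
}
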