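#' Generate a multi-year shade-tree census
#'
#' Simulates the tree side of an annual census: a fixed initial population of
#' mapped trees, followed from year to year, with an optional thinning
#' schedule that removes a fixed fraction of the surviving trees each year
#' from `thin_start` onwards (emulating a shift to intensified shade
#' management mid-series). Tree identifiers are stable across years and
#' removed trees never return.
#'
#' @param window A [plot_window()].
#' @param n_trees Number of trees in the first year.
#' @param years Integer vector of census years (ascending).
#' @param thin_start Year in which thinning management begins; the first
#'   reduced census appears the following year. `Inf` disables thinning.
#' @param thin_frac Fraction of trees removed per thinning year, in `[0, 1)`.
#'   Each thinning year keeps `round(count * (1 - thin_frac))` trees, the
#'   removed ones chosen uniformly at random (occupied trees are not
#'   protected).
#' @param pattern `"random"` for uniform locations or `"regular-jitter"` for
#'   a jittered planting grid.
#' @param seed Integer seed.
#' @return A tree census series: a `data.frame` of class `"tree_census"`
#'   with columns `year`, `tree_id`, `x`, `y`, `nest` (all 0 here; nests are
#'   added by [simulate_nest_dynamics()]).
#' @export
gen_tree_series <- function(window, n_trees, years, thin_start = Inf,
                            thin_frac = 0, pattern = c("random", "regular-jitter"),
                            seed = 1) {
  stopifnot(inherits(window, "plot_window"), n_trees > 0)
  if (length(years) == 0) stop("years must be a non-empty vector")
  if (thin_frac < 0 || thin_frac >= 1) stop("thin_frac must be in [0, 1)")
  pattern <- match.arg(pattern)
  years <- sort(as.integer(years))
  with_seed(seed, {
    if (pattern == "random") {
      x <- stats::runif(n_trees, 0, window$width)
      y <- stats::runif(n_trees, 0, window$height)
    } else {
      sp <- sqrt(window_area(window) / n_trees)
      gx <- seq(sp / 2, window$width, by = sp)
      gy <- seq(sp / 2, window$height, by = sp)
      g <- expand.grid(x = gx, y = gy)
      g <- g[sample.int(nrow(g), min(n_trees, nrow(g))), ]
      x <- pmin(pmax(g$x + stats::rnorm(nrow(g), sd = sp / 4), 0), window$width)
      y <- pmin(pmax(g$y + stats::rnorm(nrow(g), sd = sp / 4), 0), window$height)
      n_trees <- nrow(g)
    }
    ids <- sprintf("t%05d", seq_len(n_trees))
    alive <- ids
    out <- vector("list", length(years))
    for (k in seq_along(years)) {
      yr <- years[k]
      if (k > 1 && yr > thin_start && thin_frac > 0) {
        keep <- round(length(alive) * (1 - thin_frac))
        alive <- sort(sample(alive, keep))
      }
      sel <- match(alive, ids)
      out[[k]] <- data.frame(year = yr, tree_id = alive, x = x[sel],
                             y = y[sel], nest = 0L,
                             stringsAsFactors = FALSE)
    }
    census <- do.call(rbind, out)
    rownames(census) <- NULL
    class(census) <- c("tree_census", "data.frame")
    attr(census, "window") <- window
    census
  })
}

#' Extract one census year as point patterns
#'
#' @param census A tree census series (`data.frame` with columns
#'   `year`, `tree_id`, `x`, `y`, `nest`).
#' @param year Census year to extract.
#' @param window A [plot_window()]; defaults to the one attached to the
#'   census.
#' @param what `"trees"` for all trees, `"nests"` for nest-bearing trees.
#' @return A [point_pattern()] with tree ids attached.
#' @export
census_pattern <- function(census, year, window = attr(census, "window"),
                           what = c("trees", "nests")) {
  what <- match.arg(what)
  if (is.null(window)) stop("no window attached to census; supply one")
  rows <- census[census$year == year, , drop = FALSE]
  if (nrow(rows) == 0) stop(sprintf("year %s not present in census", year))
  if (what == "nests") rows <- rows[rows$nest != 0, , drop = FALSE]
  point_pattern(rows$x, rows$y, window, id = rows$tree_id)
}

census_years <- function(census) sort(unique(census$year))
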