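#' Planar point pattern
#'
#' A set of point locations inside a rectangular window, optionally carrying
#' stable identifiers (tree ids) so that nest patterns can be matched back to
#' the census record they were observed on.
#'
#' @param x,y Numeric coordinate vectors (metres).
#' @param window A [plot_window()].
#' @param id Optional character vector of identifiers, one per point.
#' @return An object of class `"point_pattern"`.
#' @export
point_pattern <- function(x, y, window, id = NULL) {
  stopifnot(inherits(window, "plot_window"), length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) > 0 && !all(inside_window(x, y, window)))
    stop("all points must lie inside the window")
  if (!is.null(id)) stopifnot(length(id) == length(x))
  structure(list(x = x, y = y, window = window, id = id),
            class = "point_pattern")
}

#' Number of points in a pattern
#' @param pattern A `point_pattern`.
#' @export
n_points <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  length(pattern$x)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("planar point pattern: %d points in [0, %g] x [0, %g] m\n",
              n_points(x), x$window$width, x$window$height))
  invisible(x)
}

# Pairwise distances and translation edge-correction weights for all
# unordered pairs. The translation correction for a W x H rectangle is
# e_ij = |A| / ((W - |dx|)(H - |dy|)), exact for rectangles.
pair_data <- function(pattern) {
  n <- n_points(pattern)
  if (n < 2)
    return(list(d = numeric(0), e = numeric(0), i = integer(0), j = integer(0)))
  x <- pattern$x; y <- pattern$y
  w <- pattern$window
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ut[, 1]; j <- ut[, 2]
  dx <- abs(x[i] - x[j]); dy <- abs(y[i] - y[j])
  d <- sqrt(dx^2 + dy^2)
  e <- window_area(w) / ((w$width - dx) * (w$height - dy))
  list(d = d, e = e, i = i, j = j)
}
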