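#' Rectangular observation window
#'
#' The plot over which all patterns are observed and all areas and edge
#' corrections are computed. Coordinates are planar metres with the origin at
#' the south-west corner, so points live in `[0, width] x [0, height]`.
#' The default is a 670 m square, approximately the 45 ha of a typical
#' permanent study plot.
#'
#' @param width,height Side lengths in metres; both must be positive.
#' @return An object of class `"plot_window"` with fields `width` and
#'   `height`.
#' @examples
#' w <- plot_window()
#' window_area(w) / 1e4  # hectares
#' @export
plot_window <- function(width = 670, height = 670) {
  stopifnot(is.numeric(width), is.numeric(height), length(width) == 1,
            length(height) == 1, is.finite(width), is.finite(height))
  if (width <= 0 || height <= 0)
    stop("window sides must be positive")
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "plot_window")
}

#' @rdname plot_window
#' @param window A `plot_window`.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "plot_window"))
  window$width * window$height
}

#' @export
print.plot_window <- function(x, ...) {
  cat(sprintf("rectangular window [0, %g] x [0, %g] m (%.2f ha)\n",
              x$width, x$height, window_area(x) / 1e4))
  invisible(x)
}

inside_window <- function(x, y, window) {
  x >= 0 & x <= window$width & y >= 0 & y <= window$height
}
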