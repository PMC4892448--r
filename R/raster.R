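#' Regular raster grid
#'
#' A regular square-celled grid of values covering the observation window,
#' used for terrain covariates, kernel density surfaces and fitted intensity
#' surfaces. Values are stored as a matrix whose rows run south to north
#' (row 1 is the southernmost row) and whose columns run west to east, with
#' cell-centre registration: the centre of cell `[i, j]` is at
#' `origin + cell * (j - 1/2, i - 1/2)`. Cells are half-open (lower-left
#' closed), so a point on a shared boundary belongs to the cell to its
#' north-east.
#'
#' @param values Numeric matrix (rows = y, cols = x).
#' @param origin Length-2 numeric, x and y of the lower-left corner (m).
#' @param cell Cell side length in metres (default 20).
#' @param name Optional label for the variable the grid holds.
#' @return An object of class `"raster_grid"`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell = 20, name = "") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), length(origin) == 2, cell > 0)
  structure(list(values = values, origin = as.numeric(origin),
                 cell = as.numeric(cell), n_rows = nrow(values),
                 n_cols = ncol(values), name = as.character(name)),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("raster grid '%s': %d x %d cells of %g m, origin (%g, %g)\n",
              x$name, x$n_rows, x$n_cols, x$cell, x$origin[1], x$origin[2]))
  invisible(x)
}

#' @rdname raster_grid
#' @param grid A `raster_grid`.
#' @export
cell_centres <- function(grid) {
  stopifnot(inherits(grid, "raster_grid"))
  list(x = grid$origin[1] + grid$cell * (seq_len(grid$n_cols) - 0.5),
       y = grid$origin[2] + grid$cell * (seq_len(grid$n_rows) - 0.5))
}

# Geometry of the grid that covers a window at the given cell size.
grid_spec_for_window <- function(window, cell = 20) {
  list(origin = c(0, 0), cell = cell,
       n_cols = as.integer(ceiling(window$width / cell - 1e-9)),
       n_rows = as.integer(ceiling(window$height / cell - 1e-9)))
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) && isTRUE(all.equal(a$cell, b$cell)) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Bilinear interpolation of a raster grid
#'
#' Evaluates the grid at arbitrary coordinates by bilinear interpolation
#' between the four surrounding cell centres; coordinates beyond the outermost
#' cell centres are clamped to the edge, so the surface is defined on the
#' whole window.
#'
#' @param grid A [raster_grid()].
#' @param x,y Coordinates (metres) at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
interp_bilinear <- function(grid, x, y) {
  stopifnot(inherits(grid, "raster_grid"))
  cc <- cell_centres(grid)
  # fractional column/row index relative to cell centres, clamped
  fx <- (x - cc$x[1]) / grid$cell
  fy <- (y - cc$y[1]) / grid$cell
  fx <- pmin(pmax(fx, 0), grid$n_cols - 1)
  fy <- pmin(pmax(fy, 0), grid$n_rows - 1)
  j0 <- pmin(floor(fx), grid$n_cols - 2); j0 <- pmax(j0, 0)
  i0 <- pmin(floor(fy), grid$n_rows - 2); i0 <- pmax(i0, 0)
  if (grid$n_cols == 1) j0 <- rep(0, length(fx))
  if (grid$n_rows == 1) i0 <- rep(0, length(fy))
  tx <- fx - j0; ty <- fy - i0
  v <- grid$values
  idx <- function(i, j) v[cbind(i + 1, j + 1)]
  j1 <- pmin(j0 + 1, grid$n_cols - 1)
  i1 <- pmin(i0 + 1, grid$n_rows - 1)
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0, j1) +
    (1 - tx) * ty * idx(i1, j0) + tx * ty * idx(i1, j1)
}

#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange with the usual six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`).
#' Rows are stored north-to-south in the file and flipped on read so that the
#' in-memory matrix runs south-to-north.
#'
#' @param path File path.
#' @param grid A [raster_grid()] to write.
#' @param nodata NODATA sentinel written in the header.
#' @return `read_ascii_grid` returns a [raster_grid()];
#'   `write_ascii_grid` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  for (k in 1:6) {
    ln <- strsplit(trimws(readLines(con, n = 1)), "\\s+")[[1]]
    hdr[[tolower(ln[1])]] <- as.numeric(ln[2])
  }
  vals <- scan(con, what = numeric(), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  raster_grid(m, origin = c(hdr$xllcorner, hdr$yllcorner),
              cell = hdr$cellsize)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "raster_grid"))
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.10g", grid$origin[1]),
           sprintf("yllcorner %.10g", grid$origin[2]),
           sprintf("cellsize %.10g", grid$cell),
           sprintf("NODATA_value %g", nodata))
  m <- grid$values
  m[is.na(m)] <- nodata
  rows <- apply(m[rev(seq_len(nrow(m))), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
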