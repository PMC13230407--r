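#' Analysis grid specification
#'
#' A `grid_spec` describes the regular analysis grid every raster layer lives
#' on: a projected equal-area CRS (coordinates in metres), the coordinate of
#' the upper-left corner, the square cell size and the grid dimensions. Cells
#' are half-open, `[x, x + s)` in easting and `(y - s, y]` in northing, so a
#' point on a shared edge belongs to exactly one cell. Rasters themselves are
#' plain matrices (row 1 = northernmost row) carrying this spec alongside.
#'
#' @param origin_x,origin_y Easting/northing of the upper-left grid corner (m).
#' @param cell_size_m Cell edge length in metres; 100 m cells are 1 ha.
#' @param n_rows,n_cols Grid dimensions.
#' @param crs Identifier of the projected equal-area CRS; the default is the
#'   standard European Lambert azimuthal equal-area grid (see [laea_europe()]).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size_m, n_rows, n_cols,
                      crs = "laea_europe") {
  stopifnot(is.numeric(cell_size_m), cell_size_m > 0,
            n_rows >= 1, n_cols >= 1)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size_m = as.numeric(cell_size_m),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs = crs),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g m (%s), UL corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size_m, x$crs,
              x$origin_x, x$origin_y))
  invisible(x)
}

#' Cell area in hectares
#' @param grid A [grid_spec()].
#' @return Area of one cell in ha.
#' @export
cell_area_ha <- function(grid) grid$cell_size_m^2 / 1e4

same_grid <- function(a, b) {
  isTRUE(all.equal(a[c("origin_x", "origin_y", "cell_size_m")],
                   b[c("origin_x", "origin_y", "cell_size_m")])) &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-centre coordinates
#'
#' @param grid A [grid_spec()].
#' @param rows,cols Optional row/column indices (recycled together); the
#'   default returns centres for the full grid in row-major order.
#' @return A tibble with columns `row`, `col`, `x`, `y`.
#' @export
cell_centers <- function(grid, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    rows <- rep(seq_len(grid$n_rows), each = grid$n_cols)
    cols <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  }
  tibble::tibble(
    row = as.integer(rows), col = as.integer(cols),
    x = grid$origin_x + (cols - 0.5) * grid$cell_size_m,
    y = grid$origin_y - (rows - 0.5) * grid$cell_size_m)
}

#' Locate points on the grid
#'
#' Maps projected coordinates to (row, col) under the half-open cell
#' convention; points off the grid get NA.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors (m).
#' @return A tibble with columns `row`, `col` (NA outside the grid).
#' @export
locate_cells <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size_m) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size_m) + 1
  # upper/left edges belong to the first cell inside
  row[grid$origin_y - y == 0] <- 1L
  bad <- row < 1 | row > grid$n_rows | col < 1 | col > grid$n_cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Convert a raster matrix to a tidy tibble
#'
#' @param m A matrix (numeric, logical or character/factor).
#' @param grid The [grid_spec()] the matrix lives on.
#' @param value Name of the value column.
#' @param drop_na Drop no-data cells?
#' @return A tibble with `row`, `col`, `x`, `y` and the value column.
#' @export
raster_to_tibble <- function(m, grid, value = "value", drop_na = TRUE) {
  stopifnot(nrow(m) == grid$n_rows, ncol(m) == grid$n_cols)
  out <- cell_centers(grid)
  out[[value]] <- as.vector(t(m))  # row-major to match cell_centers order
  if (drop_na) out <- out[!is.na(out[[value]]), , drop = FALSE]
  out
}

#' Raster I/O in the Esri ASCII grid format
#'
#' Plain-text raster exchange: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, north to
#' south. Categorical layers are written through an integer encoding supplied
#' by `levels`.
#'
#' @param m Matrix to write (numeric, or character if `levels` given).
#' @param grid A [grid_spec()].
#' @param path Output/input file path.
#' @param nodata No-data sentinel written for NA cells.
#' @param levels Optional character vector: category labels encoded as their
#'   integer index in this vector.
#' @return `write_ascii_grid()` returns `path` invisibly; `read_ascii_grid()`
#'   a list with elements `matrix` and `grid`.
#' @export
write_ascii_grid <- function(m, grid, path, nodata = -9999, levels = NULL) {
  stopifnot(nrow(m) == grid$n_rows, ncol(m) == grid$n_cols)
  if (!is.null(levels)) m <- matrix(match(m, levels), nrow(m), ncol(m))
  if (is.logical(m)) m <- m + 0L
  hdr <- c(sprintf("ncols %d", grid$n_cols),
           sprintf("nrows %d", grid$n_rows),
           sprintf("xllcorner %.6f", grid$origin_x),
           sprintf("yllcorner %.6f",
                   grid$origin_y - grid$n_rows * grid$cell_size_m),
           sprintf("cellsize %.6f", grid$cell_size_m),
           sprintf("NODATA_value %s", format(nodata)))
  m[is.na(m)] <- nodata
  fmt <- if (is.double(m) && any(m != round(m))) {
    function(v) sprintf("%.17g", v)  # exact double round-trip
  } else {
    function(v) format(v, scientific = FALSE, trim = TRUE)
  }
  body <- apply(m, 1, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param crs CRS identifier to attach on read (the format itself carries none).
#' @export
read_ascii_grid <- function(path, levels = NULL, crs = "laea_europe") {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:6], "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- vapply(hdr, `[`, "", 2)
  h <- stats::setNames(as.numeric(val), tolower(key))
  m <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  m[m == h[["nodata_value"]]] <- NA
  grid <- grid_spec(
    origin_x = h[["xllcorner"]],
    origin_y = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]],
    cell_size_m = h[["cellsize"]], n_rows = h[["nrows"]],
    n_cols = h[["ncols"]], crs = crs)
  if (!is.null(levels)) {
    m2 <- matrix(levels[m], nrow(m), ncol(m))
    m <- m2
  }
  list(matrix = m, grid = grid)
}
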