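#' Lightweight geographic grid
#'
#' A minimal regular-grid container used for predictor surfaces, masks and
#' label rasters: a numeric matrix on a WGS84 lon/lat grid with square cells,
#' cell-center registered. Row 1 of the matrix is the southernmost row;
#' column 1 the westernmost column.
#'
#' @param values numeric (or integer) matrix, `values[row, col]` with rows
#'   indexing latitude (south to north) and columns longitude (west to east).
#' @param xmin,ymin coordinates of the grid's lower-left *corner* (degrees).
#' @param res cell size in degrees (default 0.025, ca. 1 km near the equator).
#' @param labels optional named integer-to-label map (character vector whose
#'   names are the integer codes) for categorical grids.
#' @return an object of class `p_grid`.
#' @export
p_grid <- function(values, xmin = 0, ymin = 0, res = 0.025, labels = NULL) {
  stopifnot(is.matrix(values), is.numeric(res), res > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, res = res,
         nx = ncol(values), ny = nrow(values), labels = labels),
    class = "p_grid")
}

#' @export
print.p_grid <- function(x, ...) {
  cat(sprintf("<p_grid> %d x %d cells, %.4g deg, extent [%.4g, %.4g] x [%.4g, %.4g]\n",
              x$ny, x$nx, x$res,
              x$xmin, x$xmin + x$nx * x$res,
              x$ymin, x$ymin + x$ny * x$res))
  invisible(x)
}

#' @export
dim.p_grid <- function(x) dim(x$values)

#' Extract grid values at point locations
#'
#' Nearest-cell (point-in-cell) extraction: a point is assigned the value of
#' the cell whose center is nearest, i.e. the cell containing it. Points
#' outside the grid extent return `NA`.
#'
#' @param grid a [p_grid].
#' @param lon,lat numeric vectors of equal length (degrees, WGS84).
#' @param as_label if `TRUE` and the grid carries a label map, return the
#'   label strings instead of the integer codes.
#' @return vector of values (NA outside the extent).
#' @export
grid_extract <- function(grid, lon, lat, as_label = FALSE) {
  stopifnot(inherits(grid, "p_grid"), length(lon) == length(lat))
  ix <- floor((lon - grid$xmin) / grid$res) + 1L
  iy <- floor((lat - grid$ymin) / grid$res) + 1L
  ok <- !is.na(ix) & !is.na(iy) & ix >= 1L & ix <= grid$nx & iy >= 1L & iy <= grid$ny
  out <- rep(NA_real_, length(lon))
  out[ok] <- grid$values[cbind(iy[ok], ix[ok])]
  if (as_label && !is.null(grid$labels)) {
    lab <- rep(NA_character_, length(out))
    lab[!is.na(out)] <- unname(grid$labels[as.character(out[!is.na(out)])])
    return(lab)
  }
  out
}

#' Cell-center coordinates and values of a grid
#'
#' @param grid a [p_grid].
#' @return data.frame with `lon`, `lat`, `value`, one row per cell
#'   (row-major, south to north).
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "p_grid"))
  lon <- grid$xmin + (seq_len(grid$nx) - 0.5) * grid$res
  lat <- grid$ymin + (seq_len(grid$ny) - 0.5) * grid$res
  data.frame(
    lon = rep(lon, each = grid$ny),
    lat = rep(lat, times = grid$nx),
    value = as.vector(grid$values))
}

#' Approximate cell area of a lon/lat grid cell
#'
#' Spherical-rectangle area of a `res` x `res` degree cell centered at a
#' given latitude, in square meters (authalic Earth radius 6371.0072 km).
#'
#' @param lat latitude of the cell center (degrees).
#' @param res cell size (degrees).
#' @return area in m^2.
#' @export
cell_area_m2 <- function(lat, res = 0.025) {
  R <- 6371007.2
  dlam <- res * pi / 180
  phi1 <- (lat - res / 2) * pi / 180
  phi2 <- (lat + res / 2) * pi / 180
  R^2 * dlam * abs(sin(phi2) - sin(phi1))
}

#' Read / write a grid as plain CSV
#'
#' The on-disk dialect is a plain CSV with a one-line `#` header carrying the
#' georeferencing (`xmin`, `ymin`, `res`, `nrow`, `ncol`) followed by the
#' matrix in row-major order (southern row first), so grids survive a
#' text-only round trip.
#'
#' @param grid a [p_grid].
#' @param path file path.
#' @return `write_grid_csv` returns `path` invisibly; `read_grid_csv` a
#'   [p_grid].
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "p_grid"))
  hdr <- sprintf("# xmin=%.10g ymin=%.10g res=%.10g nrow=%d ncol=%d",
                 grid$xmin, grid$ymin, grid$res, grid$ny, grid$nx)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(grid$values, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[-0-9.eE+]+", hdr))[[1]]
  meta <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  vals <- as.matrix(utils::read.csv(path, skip = 1, header = FALSE))
  dimnames(vals) <- NULL
  stopifnot(nrow(vals) == meta[["nrow"]], ncol(vals) == meta[["ncol"]])
  p_grid(vals, xmin = meta[["xmin"]], ymin = meta[["ymin"]],
         res = meta[["res"]])
}
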