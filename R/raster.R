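#' Single-band elevation raster on a regular planar grid
#'
#' The minimal raster container used throughout the package: a numeric
#' matrix of elevations (m) on a square-pixel grid in local planar
#' coordinates. Row 1 of the matrix is the southernmost row (smallest y);
#' column 1 is the westernmost. The center of pixel `[r, c]` is at
#' `origin + (c - 0.5, r - 0.5) * pixel_size`.
#'
#' @param values numeric matrix of elevations; `nodata` marks missing
#'   cells.
#' @param origin `c(x, y)` of the grid's south-west corner (m).
#' @param pixel_size pixel edge length (m), > 0.
#' @param nodata sentinel value for missing cells.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), pixel_size, nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  structure(list(
    values = values,
    origin = as.numeric(origin),
    pixel_size = pixel_size,
    nodata = nodata
  ), class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[x$values != x$nodata]
  cat(sprintf(
    "raster_grid: %d x %d pixels of %.3g m, origin (%.2f, %.2f)\n",
    nrow(x$values), ncol(x$values), x$pixel_size, x$origin[1], x$origin[2]))
  if (length(v))
    cat(sprintf("  elevation range %.3f .. %.3f m\n", min(v), max(v)))
  invisible(x)
}

#' @export
plot.raster_grid <- function(x, ...) {
  v <- x$values
  v[v == x$nodata] <- NA
  graphics::image(pixel_centers_x(x), pixel_centers_y(x), t(v),
                  asp = 1, xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::gray.colors(64), ...)
  invisible(x)
}

#' Pixel-center coordinates of a raster
#' @param raster a [raster_grid()].
#' @return numeric vector of x (or y) coordinates of pixel centers.
#' @export
pixel_centers_x <- function(raster) {
  raster$origin[1] + (seq_len(ncol(raster$values)) - 0.5) * raster$pixel_size
}

#' @rdname pixel_centers_x
#' @export
pixel_centers_y <- function(raster) {
  raster$origin[2] + (seq_len(nrow(raster$values)) - 0.5) * raster$pixel_size
}

# error unless two rasters share origin, pixel size and shape
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$values), dim(b$values)) ||
      any(abs(a$origin - b$origin) > 1e-9) ||
      abs(a$pixel_size - b$pixel_size) > 1e-12)
    stop("raster grids are not aligned (origin, pixel size and shape must match)")
  invisible(TRUE)
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange (`.asc`): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed
#' by rows of elevations, northernmost row first.
#'
#' @param raster a [raster_grid()].
#' @param path file path.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a [raster_grid()].
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "raster_grid"))
  v <- raster$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", raster$origin[2]),
    sprintf("cellsize %.10g", raster$pixel_size),
    sprintf("NODATA_value %.10g", raster$nodata)
  ), con)
  # ASCII grids are stored north-to-south
  utils::write.table(v[rev(seq_len(nrow(v))), , drop = FALSE], con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  val <- as.numeric(kv[, 2])
  names(val) <- tolower(kv[, 1])
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(val["nrows"], val["ncols"])))
    stop("ASCII grid body does not match its header")
  raster_grid(m[rev(seq_len(nrow(m))), , drop = FALSE],
              origin = unname(val[c("xllcorner", "yllcorner")]),
              pixel_size = unname(val["cellsize"]),
              nodata = unname(val["nodata_value"]))
}
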