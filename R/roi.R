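#' Rectangular regions of interest
#'
#' ROIs are axis-aligned rectangles in field coordinates, stored one per
#' line of a data frame with columns `id`, `kind` (`"inner"` rectangles
#' over crop rows, `"outer"` bare-ground rectangles ringing the field),
#' `xmin`, `xmax`, `ymin`, `ymax`, and for inner ROIs the originating
#' `row_id`, `block`, spatial `group` and a `measured` flag marking the
#' block that contains the measured plants.
#'
#' @name roi_set
NULL

#' Build inner ROIs over the measured rows of a layout
#'
#' One ROI per measured row and block: the rectangle is one row spacing
#' wide (centered on the row) and spans the block's plant positions plus
#' half a plant spacing at each end. The central block of each row is
#' flagged `measured`; its 98th-percentile height is the row's
#' photogrammetric height sample. Each ROI carries its row's spatial
#' group label for cross-validation.
#'
#' @param layout a [field_layout()].
#' @return data frame of `n_measured_rows(layout) * blocks_per_row` ROIs.
#' @export
build_inner_rois <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  rows <- layout$rows[layout$rows$measured, ]
  half_w <- layout$row_spacing / 2
  mid_block <- ceiling(layout$blocks_per_row / 2)
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j) {
    row <- rows[j, ]
    do.call(rbind, lapply(seq_len(layout$blocks_per_row), function(b) {
      ye <- block_extent(layout, row, b)
      data.frame(
        id = sprintf("row%04d_block%d", row$row_id, b),
        kind = "inner",
        xmin = row$x - half_w, xmax = row$x + half_w,
        ymin = ye[1], ymax = ye[2],
        row_id = row$row_id, block = b,
        group = row$group, measured = b == mid_block
      )
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Measurement-block ROIs of an inner ROI set
#' @param rois output of [build_inner_rois()].
#' @return the subset of ROIs whose block holds the measured plants.
#' @export
measurement_rois <- function(rois) rois[rois$kind == "inner" & rois$measured, ]

#' Build a ring of bare-ground ROIs around a region
#'
#' Tiles a closed ring just outside the region boundary: one
#' `ring_depth` x `ring_depth` square diagonally off each corner, and
#' `edge_unit` x `ring_depth` rectangles along each side (the last piece
#' of a side is shortened to fit). The ring has no gaps and never
#' overlaps the region interior.
#'
#' `jitter_sd > 0` displaces each rectangle by a Gaussian offset,
#' emulating ROIs digitized by hand on an orthomosaic. Exactly tiled
#' rectangles put every ROI centroid on one of four lines, which makes a
#' degree-4 surface fit rank deficient; hand-placed ROIs are the reason
#' real degree-4 fits run — and overfit (see [fit_polynomial_dtm()]).
#'
#' @param region `c(width, length)` of the field region (m), corner at
#'   the origin.
#' @param edge_unit nominal length (m) of a side rectangle.
#' @param ring_depth depth (m) of the ring.
#' @param jitter_sd standard deviation (m) of rectangle displacement.
#' @param seed seed for the jitter (required when `jitter_sd > 0`).
#' @return data frame of outer ROIs (columns as in [roi_set]).
#' @export
build_outer_rois <- function(region, edge_unit = 1.0, ring_depth = 0.5,
                             jitter_sd = 0, seed = NULL) {
  region <- as.numeric(region)
  W <- region[1]; H <- region[2]
  if (W <= 0 || H <= 0 || ring_depth <= 0 || edge_unit <= 0)
    stop("degenerate region or ring: dimensions must be positive")
  d <- ring_depth; u <- edge_unit

  side_pieces <- function(L) {
    # tile [0, L] with unit pieces, last shortened
    starts <- seq(0, L - 1e-9, by = u)
    cbind(starts, pmin(starts + u, L))
  }
  rect <- function(xmin, xmax, ymin, ymax)
    data.frame(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)

  pieces <- list(
    # corners, diagonally outside
    rect(-d, 0, -d, 0), rect(W, W + d, -d, 0),
    rect(-d, 0, H, H + d), rect(W, W + d, H, H + d)
  )
  sx <- side_pieces(W)
  for (j in seq_len(nrow(sx))) {
    pieces[[length(pieces) + 1]] <- rect(sx[j, 1], sx[j, 2], -d, 0)      # south
    pieces[[length(pieces) + 1]] <- rect(sx[j, 1], sx[j, 2], H, H + d)   # north
  }
  sy <- side_pieces(H)
  for (j in seq_len(nrow(sy))) {
    pieces[[length(pieces) + 1]] <- rect(-d, 0, sy[j, 1], sy[j, 2])      # west
    pieces[[length(pieces) + 1]] <- rect(W, W + d, sy[j, 1], sy[j, 2])   # east
  }
  out <- do.call(rbind, pieces)
  if (jitter_sd > 0) {
    if (is.null(seed)) stop("seed is required when jitter_sd > 0")
    set.seed(seed)
    dx <- stats::rnorm(nrow(out), 0, jitter_sd)
    dy <- stats::rnorm(nrow(out), 0, jitter_sd)
    out$xmin <- out$xmin + dx; out$xmax <- out$xmax + dx
    out$ymin <- out$ymin + dy; out$ymax <- out$ymax + dy
  }
  out$id <- sprintf("ring%03d", seq_len(nrow(out)))
  out$kind <- "outer"
  out$row_id <- NA_integer_; out$block <- NA_integer_
  out$group <- NA_integer_; out$measured <- FALSE
  out[, c("id", "kind", "xmin", "xmax", "ymin", "ymax",
          "row_id", "block", "group", "measured")]
}

#' Extract raster values inside a rectangular ROI
#'
#' A pixel belongs to the ROI when its center lies inside the rectangle;
#' the rule is half-open on the max edges (`xmin <= x < xmax`), so
#' adjacent ROIs never share a pixel.
#'
#' @param raster a [raster_grid()].
#' @param roi one ROI (a one-line data frame or list with `xmin`, `xmax`,
#'   `ymin`, `ymax`).
#' @param max_nodata_fraction error threshold on the nodata fraction.
#' @return numeric vector of elevations with nodata removed; attribute
#'   `nodata_fraction` reports the excluded share.
#' @export
extract_pixels <- function(raster, roi, max_nodata_fraction = 0.5) {
  stopifnot(inherits(raster, "raster_grid"))
  ix <- which(pixel_centers_x(raster) >= roi$xmin &
              pixel_centers_x(raster) <  roi$xmax)
  iy <- which(pixel_centers_y(raster) >= roi$ymin &
              pixel_centers_y(raster) <  roi$ymax)
  if (!length(ix) || !length(iy))
    stop("empty ROI: no pixel centers fall inside the rectangle")
  vals <- as.vector(raster$values[iy, ix])
  bad <- vals == raster$nodata
  frac <- mean(bad)
  if (frac > max_nodata_fraction)
    stop(sprintf("degraded ROI: %.0f%% of pixels are nodata", 100 * frac))
  out <- vals[!bad]
  attr(out, "nodata_fraction") <- frac
  out
}

#' Linear-interpolation percentile
#'
#' The percentile at rank position `q/100 * (N - 1)` on the sorted
#' sample, interpolating linearly between order statistics (the common
#' default of scientific numerics, `quantile(type = 7)`).
#'
#' @param values non-empty numeric vector.
#' @param q percent in `[0, 100]`.
#' @return elevation value.
#' @export
percentile_value <- function(values, q) {
  if (!length(values)) stop("percentile of an empty sample is undefined")
  if (q < 0 || q > 100) stop("q must be in [0, 100]")
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

#' Median elevation and centroid of an ROI
#'
#' The bare-ground sample point a ring ROI contributes to terrain
#' fitting: z is the median of the ROI's pixels, (x, y) the rectangle's
#' center of gravity.
#'
#' @param raster a [raster_grid()].
#' @param roi one ROI.
#' @return named numeric `c(x, y, z)`.
#' @export
median_center <- function(raster, roi) {
  vals <- extract_pixels(raster, roi)
  c(x = (roi$xmin + roi$xmax) / 2,
    y = (roi$ymin + roi$ymax) / 2,
    z = percentile_value(vals, 50))
}

#' Write / read ROI sets as GeoJSON
#'
#' Rectangles become Polygon features with `id`, `kind`, `group`,
#' `row_id`, `block` and `measured` properties.
#'
#' @param rois an ROI data frame.
#' @param path file path.
#' @return `write_rois_geojson` returns `path` invisibly;
#'   `read_rois_geojson` returns the ROI data frame.
#' @export
write_rois_geojson <- function(rois, path) {
  features <- lapply(seq_len(nrow(rois)), function(j) {
    r <- rois[j, ]
    ring <- list(
      c(r$xmin, r$ymin), c(r$xmax, r$ymin), c(r$xmax, r$ymax),
      c(r$xmin, r$ymax), c(r$xmin, r$ymin))
    list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(id = r$id, kind = r$kind, group = r$group,
                        row_id = r$row_id, block = r$block,
                        measured = r$measured))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_rois_geojson
#' @export
read_rois_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  out <- do.call(rbind, lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
    p <- f$properties
    gv <- function(v, cast) if (is.null(v)) cast(NA) else cast(v)
    data.frame(id = p$id, kind = p$kind,
               xmin = min(xs), xmax = max(xs),
               ymin = min(ys), ymax = max(ys),
               row_id = gv(p$row_id, as.integer),
               block = gv(p$block, as.integer),
               group = gv(p$group, as.integer),
               measured = gv(p$measured, as.logical))
  }))
  rownames(out) <- NULL
  out
}
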