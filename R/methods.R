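#' Crop height by off-season DSM differencing (method M1)
#'
#' Uses a bare-field (pre-germination) DSM as the terrain model and
#' subtracts it from the on-season DSM. The two rasters must share grid
#' geometry and should come from the same acquisition condition and
#' repetition. Nodata propagates. Because each flight's reconstruction
#' floats on its own vertical datum, the difference inherits the datum
#' gap between the two flights — the method's known weakness without
#' ground control.
#'
#' @param on_season,off_season aligned [raster_grid()]s.
#' @return crop height model as a [raster_grid()].
#' @export
method_m1 <- function(on_season, off_season) {
  check_same_geometry(on_season, off_season)
  v <- on_season$values - off_season$values
  bad <- on_season$values == on_season$nodata |
    off_season$values == off_season$nodata
  v[bad] <- on_season$nodata
  raster_grid(v, origin = on_season$origin,
              pixel_size = on_season$pixel_size,
              nodata = on_season$nodata)
}

#' Plant height from within-ROI soil and apex percentiles (method M2)
#'
#' Takes the 2nd percentile of the ROI's elevations as the soil altitude
#' and the 98th as the apex altitude; their difference is the
#' photogrammetric plant height. The percentile band excludes small
#' noise blobs (under 2 percent of the ROI) at both ends. The method
#' needs visible soil inside the ROI: when less than about 2 percent of
#' pixels are at ground level, the lower percentile lands on canopy and
#' the height collapses.
#'
#' @param dsm a [raster_grid()] (on-season DSM or CHM).
#' @param roi one inner ROI.
#' @param upper,lower apex and soil percentiles (percent).
#' @return plant height (m), >= 0 by percentile monotonicity.
#' @export
method_m2 <- function(dsm, roi, upper = 98, lower = 2) {
  vals <- extract_pixels(dsm, roi)
  percentile_value(vals, upper) - percentile_value(vals, lower)
}

#' Crop height via a polynomial terrain surface (method M3)
#'
#' Samples bare ground in the ring ROIs around the field (median
#' elevation at each rectangle centroid), fits a degree-`degree`
#' polynomial surface to the ring points by least squares, and subtracts
#' the surface from the DSM. Any constant datum shift of the DSM is
#' absorbed by the surface's constant term, so the result is datum
#' invariant — the method needs neither a second flight nor ground
#' control.
#'
#' @param dsm a [raster_grid()] covering the ring.
#' @param outer_rois ring ROIs from [build_outer_rois()].
#' @param degree polynomial degree of the terrain surface.
#' @return crop height model as a [raster_grid()]; the fitted surface is
#'   attached as attribute `surface`, the ring points as `points`.
#' @export
method_m3 <- function(dsm, outer_rois, degree = 3) {
  pts <- ring_points(dsm, outer_rois)
  surf <- fit_polynomial_dtm(pts, degree)
  dtm <- surface_raster(surf, dsm)
  v <- dsm$values - dtm$values
  v[dsm$values == dsm$nodata] <- dsm$nodata
  chm <- raster_grid(v, origin = dsm$origin, pixel_size = dsm$pixel_size,
                     nodata = dsm$nodata)
  attr(chm, "surface") <- surf
  attr(chm, "points") <- pts
  chm
}

#' Bare-ground sample points from ring ROIs
#'
#' @param dsm a [raster_grid()].
#' @param outer_rois ring ROIs.
#' @return data frame `x`, `y`, `z`: one [median_center()] per ROI.
#' @export
ring_points <- function(dsm, outer_rois) {
  pts <- t(vapply(seq_len(nrow(outer_rois)),
                  function(j) median_center(dsm, outer_rois[j, ]),
                  c(x = 0, y = 0, z = 0)))
  as.data.frame(pts)
}

#' Row heights from a crop height model
#'
#' The 98th percentile of the CHM inside each measurement-block ROI: the
#' row's photogrammetric plant height for methods M1 and M3.
#'
#' @param chm a [raster_grid()] of crop heights.
#' @param rois inner ROIs; only measurement blocks are used.
#' @param percentile apex percentile (percent).
#' @return data frame `row_id`, `group`, `ph_sfm` (m).
#' @export
chm_row_heights <- function(chm, rois, percentile = 98) {
  m <- measurement_rois(rois)
  data.frame(
    row_id = m$row_id,
    group = m$group,
    ph_sfm = vapply(seq_len(nrow(m)), function(j)
      percentile_value(extract_pixels(chm, m[j, ]), percentile), 0)
  )
}

#' Row heights by within-ROI percentile differencing
#'
#' Applies [method_m2()] to each measurement-block ROI of an on-season
#' DSM.
#'
#' @param dsm a [raster_grid()].
#' @param rois inner ROIs; only measurement blocks are used.
#' @param upper,lower apex and soil percentiles (percent).
#' @return data frame `row_id`, `group`, `ph_sfm` (m).
#' @export
m2_row_heights <- function(dsm, rois, upper = 98, lower = 2) {
  m <- measurement_rois(rois)
  data.frame(
    row_id = m$row_id,
    group = m$group,
    ph_sfm = vapply(seq_len(nrow(m)), function(j)
      method_m2(dsm, m[j, ], upper, lower), 0)
  )
}

#' Select the terrain-surface degree by correlation
#'
#' Given the mean (over flight repetitions) correlation between measured
#' and photogrammetric height for each candidate degree, returns the
#' degree with the strongest correlation; ties break toward the lowest
#' degree.
#'
#' @param r_by_degree named numeric vector, names = candidate degrees.
#' @return selected degree (integer).
#' @export
select_degree <- function(r_by_degree) {
  if (!length(r_by_degree)) stop("empty correlation table")
  degs <- as.integer(names(r_by_degree))
  if (anyNA(degs)) stop("r_by_degree must be named by integer degrees")
  o <- order(degs)
  degs <- degs[o]; r <- unname(r_by_degree[o])
  degs[which.max(r)]   # which.max takes the first (lowest degree) on ties
}
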