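#' Render a synthetic photogrammetric DSM
#'
#' Composes one flight's digital surface model on a regular grid covering
#' the layout's region plus a margin (so the bare-ground ring outside the
#' field is on the raster):
#'
#' ```
#' DSM = true terrain
#'     + doming bulge   (camera-angle scaled, slight flight-to-flight jitter)
#'     + micro-relief   (two sinusoid products, flight-specific phases)
#'     + datum offset   (per flight; zeroed when gcp is set)
#'     + canopy         (on-season only)
#'     + pixel noise and high blobs
#' ```
#'
#' The canopy of a row strip is the maximum over flat-topped conical
#' plant crowns (apex = true row height minus `apex_shrinkage`, flat
#' within 40 percent of the footprint radius, tapering linearly to the
#' rim). Within each strip a `soil_visible_fraction` of pixels (after
#' camera-angle scaling) is left at ground level; everywhere else the
#' reconstructed surface closes over the inter-plant space at a
#' row-specific random fraction (0.25-0.75, plus per-pixel jitter) of
#' plant height, the way photogrammetry interpolates across foliage when
#' the soil is not seen.
#'
#' @param layout a [field_layout()].
#' @param terrain a [terrain_spec()].
#' @param canopy a [canopy_spec()] or `NULL` for a bare field; must be
#'   `NULL` when `flight$season == "pre_germination"`.
#' @param flight a [flight_scenario()].
#' @param noise a [noise_spec()].
#' @param pixel_size pixel edge (m).
#' @param heights true height table from [generate_true_heights()];
#'   required with a canopy (heights are a property of the field, shared
#'   by all flights over it).
#' @param margin raster margin (m) beyond the region on every side.
#' @param datum_offset optional override of the drawn datum offset (m);
#'   used to probe datum additivity.
#' @return a [raster_grid()] with attributes `datum_offset` (realized,
#'   after any GCP zeroing) and `flight` (the scenario).
#' @export
render_dsm <- function(layout, terrain, canopy = NULL, flight,
                       noise = noise_spec(), pixel_size = 0.03,
                       heights = NULL, margin = 1, datum_offset = NULL) {
  stopifnot(inherits(layout, "field_layout"),
            inherits(terrain, "terrain_spec"),
            inherits(flight, "flight_scenario"),
            inherits(noise, "noise_spec"))
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (flight$season == "pre_germination" && !is.null(canopy))
    stop("pre-germination flight cannot carry a canopy")
  if (!is.null(canopy) && is.null(heights))
    stop("heights table is required when rendering a canopy")

  set.seed(flight$seed)
  W <- layout$region[1]; H <- layout$region[2]
  origin <- c(-margin, -margin)
  nx <- ceiling((W + 2 * margin) / pixel_size)
  ny <- ceiling((H + 2 * margin) / pixel_size)
  xc <- origin[1] + (seq_len(nx) - 0.5) * pixel_size
  yc <- origin[2] + (seq_len(ny) - 0.5) * pixel_size

  # true terrain at pixel centers
  ref <- raster_grid(matrix(0, ny, nx), origin, pixel_size)
  v <- surface_raster(terrain$true_dtm, ref)$values

  # doming: radially symmetric quadratic bulge over the region center
  amp_jit <- stats::rnorm(1, 0, terrain$doming_jitter_sd)
  amp <- terrain$doming_amplitude * doming_factor(flight$camera_angle) *
    max(0, 1 + amp_jit)
  if (amp > 0) {
    cx <- W / 2; cy <- H / 2
    R2 <- cx^2 + cy^2
    v <- v + amp * (1 - outer((yc - cy)^2, (xc - cx)^2, `+`) / R2)
  }

  # micro-relief with flight-specific phases
  ph <- stats::runif(4, 0, 2 * pi)
  mr <- function(a, lam, p1, p2)
    a * outer(sin(2 * pi * yc / lam + p2), sin(2 * pi * xc / lam + p1))
  if (terrain$microrelief_amplitude > 0)
    v <- v + mr(terrain$microrelief_amplitude,
                terrain$microrelief_wavelength, ph[1], ph[2])
  if (terrain$microrelief_fine_amplitude > 0)
    v <- v + mr(terrain$microrelief_fine_amplitude,
                terrain$microrelief_fine_wavelength, ph[3], ph[4])

  # per-flight vertical datum offset
  u <- stats::rnorm(1)
  off_sd <- if (flight$rtk) terrain$rtk_offset_sd
            else terrain$per_flight_vertical_offset_sd
  off <- if (is.null(datum_offset)) u * off_sd else datum_offset
  if (flight$gcp) off <- 0   # ground control anchors the datum
  v <- v + off

  if (!is.null(canopy))
    v <- v + render_canopy(layout, canopy, flight, heights, xc, yc)

  if (noise$pixel_noise_sd > 0)
    v <- v + matrix(stats::rnorm(length(v), 0, noise$pixel_noise_sd), ny, nx)
  if (noise$blob_count_per_raster > 0 && noise$blob_height != 0)
    v <- add_blobs(v, noise)

  out <- raster_grid(v, origin, pixel_size)
  attr(out, "datum_offset") <- off
  attr(out, "flight") <- flight
  out
}

# canopy elevation field over the full grid (0 where bare)
render_canopy <- function(layout, canopy, flight, heights, xc, yc) {
  nx <- length(xc); ny <- length(yc)
  px <- xc[2] - xc[1]
  cv <- matrix(0, ny, nx)
  svf <- canopy$soil_visible_fraction *
    soil_visibility_factor(flight$camera_angle)
  r <- canopy$plant_footprint_radius
  r_flat <- 0.4 * r
  h_by_row <- heights$true_height[order(heights$row_id)]
  half_w <- layout$row_spacing / 2
  rows <- layout$rows

  for (j in seq_len(nrow(rows))) {
    row <- rows[j, ]
    h_apex <- max(h_by_row[row$row_id] - canopy$apex_shrinkage, 0)
    ix <- which(xc >= row$x - half_w & xc < row$x + half_w)
    iy <- which(yc >= row$y0 & yc < row$y1)
    if (!length(ix) || !length(iy)) next
    strip <- matrix(0, length(iy), length(ix))

    # plant crowns: flat-topped cones, max-composed
    py <- row$y0 + (seq_len(layout$plants_per_row) - 0.5) * layout$plant_spacing
    for (p in py) {
      jy <- which(yc[iy] >= p - r & yc[iy] <= p + r)
      jx <- which(xc[ix] >= row$x - r & xc[ix] <= row$x + r)
      if (!length(jy) || !length(jx)) next
      d <- sqrt(outer((yc[iy][jy] - p)^2, (xc[ix][jx] - row$x)^2, `+`))
      crown <- h_apex * pmin(1, pmax(0, (r - d) / (r - r_flat)))
      strip[jy, jx] <- pmax(strip[jy, jx], crown)
    }

    # soil visibility: a svf share of strip pixels stays at ground level,
    # the rest is closed over by the reconstructed surface
    n_px <- length(strip)
    soil <- stats::runif(n_px) < svf
    closure <- (stats::runif(1, 0.25, 0.75) +
                stats::runif(n_px, -0.05, 0.05)) * h_apex
    strip_v <- as.vector(strip)
    strip_v[!soil] <- pmax(strip_v[!soil], closure[!soil])
    strip_v[soil] <- 0
    cv[iy, ix] <- matrix(strip_v, length(iy), length(ix))
  }
  cv
}

# inject connected high blobs; total altered pixels <= count * max_pixels
add_blobs <- function(v, noise) {
  ny <- nrow(v); nx <- ncol(v)
  for (b in seq_len(noise$blob_count_per_raster)) {
    k <- sample.int(noise$blob_max_pixels, 1)
    cr <- sample.int(ny, 1); cc <- sample.int(nx, 1)
    # k nearest pixels to the seed form a connected digital disc
    rad <- ceiling(sqrt(k)) + 1
    rr <- max(1, cr - rad):min(ny, cr + rad)
    cc2 <- max(1, cc - rad):min(nx, cc + rad)
    cand <- expand.grid(r = rr, c = cc2)
    d2 <- (cand$r - cr)^2 + (cand$c - cc)^2
    pick <- cand[order(d2)[seq_len(min(k, nrow(cand)))], ]
    v[cbind(pick$r, pick$c)] <- v[cbind(pick$r, pick$c)] + noise$blob_height
  }
  v
}
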