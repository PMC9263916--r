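#' Terrain and reconstruction-artifact specification
#'
#' Describes the true bare-ground surface of a synthetic scene and the
#' systematic artifacts a structure-from-motion (SfM) reconstruction
#' superimposes on it:
#'
#' * a central "doming" bulge (radially symmetric, quadratic in x and y)
#'   whose amplitude depends on the camera angle of the flight;
#' * a per-flight vertical datum offset (each reconstruction floats on its
#'   own vertical datum unless anchored by ground control points);
#' * smooth non-polynomial micro-relief, modeled as two sinusoid products
#'   with flight-specific random phases. The long-wavelength component
#'   stands for gentle soil undulation; the short-wavelength component
#'   for reconstruction ripple, and it is what makes bare-ground medians
#'   noisy from flight to flight.
#'
#' @param true_dtm a [poly_surface()] giving ground elevation (m).
#' @param doming_amplitude bulge height (m) at the region center for a
#'   nadir (-90 degree) flight; scaled down for diagonal views.
#' @param per_flight_vertical_offset_sd standard deviation (m) of the
#'   per-flight datum offset when RTK positioning is off.
#' @param rtk_offset_sd datum offset standard deviation (m) with RTK on.
#' @param doming_jitter_sd relative flight-to-flight variation of the
#'   doming amplitude (fraction of the amplitude).
#' @param microrelief_amplitude,microrelief_wavelength amplitude (m) and
#'   wavelength (m) of the long micro-relief component.
#' @param microrelief_fine_amplitude,microrelief_fine_wavelength amplitude
#'   (m) and wavelength (m) of the short component.
#' @return object of class `terrain_spec`.
#' @export
terrain_spec <- function(true_dtm,
                         doming_amplitude = 0.15,
                         per_flight_vertical_offset_sd = 0.5,
                         rtk_offset_sd = 0.03,
                         doming_jitter_sd = 0.1,
                         microrelief_amplitude = 0.012,
                         microrelief_wavelength = 7,
                         microrelief_fine_amplitude = 0.01,
                         microrelief_fine_wavelength = 1.7) {
  stopifnot(inherits(true_dtm, "poly_surface"))
  if (doming_amplitude < 0) stop("doming_amplitude must be >= 0")
  if (per_flight_vertical_offset_sd < 0 || rtk_offset_sd < 0)
    stop("offset standard deviations must be >= 0")
  structure(list(
    true_dtm = true_dtm,
    doming_amplitude = doming_amplitude,
    per_flight_vertical_offset_sd = per_flight_vertical_offset_sd,
    rtk_offset_sd = rtk_offset_sd,
    doming_jitter_sd = doming_jitter_sd,
    microrelief_amplitude = microrelief_amplitude,
    microrelief_wavelength = microrelief_wavelength,
    microrelief_fine_amplitude = microrelief_fine_amplitude,
    microrelief_fine_wavelength = microrelief_fine_wavelength
  ), class = "terrain_spec")
}

#' Default tilted cubic terrain for a region
#'
#' A gently inclined ground surface (one corner low, the opposite corner
#' high, about 0.7 m of relief across the region) with mild quadratic and
#' cubic structure, expressed as a degree-3 polynomial surface on
#' coordinates conditioned to the region.
#'
#' @param region `c(width, length)` in meters.
#' @param base mean ground elevation (m).
#' @return a [poly_surface()] of degree 3.
#' @export
default_terrain <- function(region, base = 100) {
  poly_surface(
    degree = 3L,
    coefficients = c(
      a00 = base,
      a10 = 0.25, a11 = -0.35,          # tilt
      a20 = -0.05, a21 = 0.08, a22 = 0.03,
      a30 = 0.04, a31 = 0.05, a32 = -0.02, a33 = -0.03
    ),
    center = region / 2,
    scale = region / 2
  )
}

#' Canopy specification for one growth stage
#'
#' Row-level true heights are drawn from a clipped normal distribution
#' (see [generate_true_heights()]). The rendered canopy underestimates
#' the true apex by `apex_shrinkage`, the systematic attenuation of thin
#' plant tops (leaf tips, tassels) in photogrammetric surfaces; this is
#' what the linear calibration later has to absorb.
#'
#' `soil_visible_fraction` is the fraction of within-row pixels left at
#' ground level under a nadir view. Where the soil is not visible the
#' reconstructed surface closes over the inter-plant space at a
#' substantial fraction of plant height, which is what defeats the
#' within-plot soil-percentile method when the fraction drops below the
#' percentile's exclusion band.
#'
#' @param stage `"vegetative"` or `"reproductive"`.
#' @param height_mean,height_sd mean and standard deviation (m) of
#'   row-level true plant height.
#' @param height_min,height_max clipping bounds (m).
#' @param apex_shrinkage systematic apex underestimation (m), >= 0.
#' @param soil_visible_fraction fraction in `[0, 1]` of within-row pixels
#'   at ground level for a nadir view.
#' @param plant_footprint_radius crown radius (m) of one plant.
#' @return object of class `canopy_spec`.
#' @export
canopy_spec <- function(stage = c("vegetative", "reproductive"),
                        height_mean,
                        height_sd,
                        height_min,
                        height_max,
                        apex_shrinkage = 0.08,
                        soil_visible_fraction = 0.4,
                        plant_footprint_radius = 0.22) {
  stage <- match.arg(stage)
  if (soil_visible_fraction < 0 || soil_visible_fraction > 1)
    stop("soil_visible_fraction must be in [0, 1]")
  if (!(height_min <= height_mean && height_mean <= height_max))
    stop("need height_min <= height_mean <= height_max")
  if (apex_shrinkage < 0) stop("apex_shrinkage must be >= 0")
  if (height_sd < 0) stop("height_sd must be >= 0")
  structure(list(
    stage = stage,
    height_mean = height_mean, height_sd = height_sd,
    height_min = height_min, height_max = height_max,
    apex_shrinkage = apex_shrinkage,
    soil_visible_fraction = soil_visible_fraction,
    plant_footprint_radius = plant_footprint_radius
  ), class = "canopy_spec")
}

#' Stage presets for a maize variety trial
#'
#' Height distributions follow the descriptive statistics of the
#' emulated trial (vegetative stage: mean 0.898 m, sd 0.102 m, range
#' 0.632-1.190 m; reproductive stage: mean 2.68 m, sd 0.181 m, range
#' 2.18-3.14 m; `field = 1` uses the sibling trial's slightly narrower
#' distributions). Apex shrinkage defaults reproduce the observed
#' negative bias of photogrammetric height: about -0.08 m on leaf apices
#' and about -0.23 m on tassels. Soil visibility is high between young
#' plants and nearly nil under a closed reproductive canopy.
#'
#' @param field 1 or 2; which trial's height statistics to use.
#' @return a [canopy_spec()].
#' @export
canopy_vegetative <- function(field = 2) {
  if (field == 1)
    canopy_spec("vegetative", 0.809, 0.075, 0.634, 0.982,
                apex_shrinkage = 0.08, soil_visible_fraction = 0.4,
                plant_footprint_radius = 0.22)
  else
    canopy_spec("vegetative", 0.898, 0.102, 0.632, 1.190,
                apex_shrinkage = 0.08, soil_visible_fraction = 0.4,
                plant_footprint_radius = 0.22)
}

#' @rdname canopy_vegetative
#' @export
canopy_reproductive <- function(field = 2) {
  if (field == 1)
    canopy_spec("reproductive", 2.73, 0.126, 2.47, 3.05,
                apex_shrinkage = 0.23, soil_visible_fraction = 0.015,
                plant_footprint_radius = 0.35)
  else
    canopy_spec("reproductive", 2.68, 0.181, 2.18, 3.14,
                apex_shrinkage = 0.23, soil_visible_fraction = 0.015,
                plant_footprint_radius = 0.35)
}

#' One simulated flight
#'
#' Encodes the acquisition condition of a single flight. The camera angle
#' drives two mechanisms: a diagonal (-60 degree) view suppresses the
#' doming distortion but widens apparent plant areas so that soil is
#' rarely visible inside rows, while a nadir (-90 degree) view shows the
#' soil but doms more. RTK shrinks the per-flight vertical datum offset
#' to centimeter scale; the GCP flag zeroes the realized offset after
#' rendering, emulating datum anchoring by surveyed ground control.
#'
#' @param camera_angle -60 or -90 (degrees from horizontal).
#' @param rtk logical, RTK positioning on.
#' @param gcp logical, ground-control-point correction applied.
#' @param season `"on_season"` or `"pre_germination"` (bare field).
#' @param repetition flight repetition index, >= 1.
#' @param seed integer seed making the flight deterministic.
#' @return object of class `flight_scenario`.
#' @export
flight_scenario <- function(camera_angle = -90,
                            rtk = FALSE,
                            gcp = FALSE,
                            season = c("on_season", "pre_germination"),
                            repetition = 1L,
                            seed = 1L) {
  season <- match.arg(season)
  if (!camera_angle %in% c(-60, -90))
    stop("camera_angle must be -60 or -90")
  if (repetition < 1) stop("repetition must be >= 1")
  structure(list(
    camera_angle = camera_angle,
    rtk = isTRUE(rtk),
    gcp = isTRUE(gcp),
    season = season,
    repetition = as.integer(repetition),
    seed = as.integer(seed)
  ), class = "flight_scenario")
}

# camera-angle response of the two view-dependent mechanisms
doming_factor <- function(camera_angle) {
  if (camera_angle == -90) 1 else 0.25
}
soil_visibility_factor <- function(camera_angle) {
  if (camera_angle == -90) 1 else 0.04
}

#' Raster noise specification
#'
#' Small connected blobs of spuriously high pixels (floating points in
#' the photogrammetric point cloud) plus per-pixel Gaussian elevation
#' noise. Blob sizes are kept at or below `blob_max_pixels`; percentile
#' extraction with a 98th/2nd band is robust to them as long as the blob
#' budget stays under 2 percent of a region of interest.
#'
#' @param blob_count_per_raster number of blobs injected per raster.
#' @param blob_max_pixels maximum pixels per blob (>= 1).
#' @param blob_height elevation added inside a blob (m).
#' @param pixel_noise_sd per-pixel Gaussian noise sd (m).
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(blob_count_per_raster = 3L,
                       blob_max_pixels = 12L,
                       blob_height = 2,
                       pixel_noise_sd = 0.01) {
  if (blob_max_pixels < 1) stop("blob_max_pixels must be >= 1")
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0")
  structure(list(
    blob_count_per_raster = as.integer(blob_count_per_raster),
    blob_max_pixels = as.integer(blob_max_pixels),
    blob_height = blob_height,
    pixel_noise_sd = pixel_noise_sd
  ), class = "noise_spec")
}

#' Silent noise specification (no blobs, no pixel noise)
#' @return a [noise_spec()] with everything zeroed.
#' @export
noise_none <- function() {
  noise_spec(blob_count_per_raster = 0L, blob_max_pixels = 1L,
             blob_height = 0, pixel_noise_sd = 0)
}

# deterministic seed derivation: fold integers into a 31-bit stream seed
derive_seed <- function(base, ...) {
  s <- as.numeric(base) %% 2147483647
  for (v in c(...)) s <- (s * 48271 + as.numeric(v) + 1) %% 2147483647
  as.integer(s)
}
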