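#' Configure a simulated acquisition-and-analysis experiment
#'
#' Bundles everything one run needs: the field, its terrain, per-stage
#' canopies, raster noise, the condition grid (camera angles x RTK x GCP
#' x ground-altitude methods), flight repetitions, the terrain-surface
#' degree for method M3, the ring-ROI geometry, pixel size and seeds.
#'
#' @param layout a [field_layout()].
#' @param terrain a [terrain_spec()]; default [default_terrain()] on the
#'   layout's region.
#' @param canopies named list of [canopy_spec()]s, one per growth stage.
#' @param noise a [noise_spec()].
#' @param camera_angles,rtk_options,gcp_options,methods the condition
#'   grid.
#' @param n_repetitions flight repetitions per acquisition condition.
#' @param degree polynomial degree for method M3.
#' @param pixel_size raster pixel edge (m).
#' @param edge_unit,ring_depth,outer_jitter_sd ring-ROI geometry (see
#'   [build_outer_rois()]).
#' @param seed master seed; all flight and jitter seeds derive from it.
#' @param outdir output directory for CSV products, or `NULL` to skip
#'   writing.
#' @param write_rasters also write every rendered DSM as an ASCII grid.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(layout,
                              terrain = NULL,
                              canopies = list(vegetative = canopy_vegetative()),
                              noise = noise_spec(),
                              camera_angles = c(-60, -90),
                              rtk_options = c(TRUE, FALSE),
                              gcp_options = c(TRUE, FALSE),
                              methods = c("M1", "M2", "M3"),
                              n_repetitions = 3L,
                              degree = 3L,
                              pixel_size = 0.03,
                              edge_unit = 1.0,
                              ring_depth = 0.5,
                              outer_jitter_sd = 0.02,
                              seed = 1L,
                              outdir = NULL,
                              write_rasters = FALSE) {
  stopifnot(inherits(layout, "field_layout"))
  if (is.null(terrain)) terrain <- terrain_spec(default_terrain(layout$region))
  if (!length(canopies) || is.null(names(canopies)))
    stop("canopies must be a named list of canopy specs")
  if (!length(camera_angles) || !length(methods))
    stop("condition grid must be non-empty")
  structure(list(
    layout = layout, terrain = terrain, canopies = canopies, noise = noise,
    camera_angles = camera_angles, rtk_options = rtk_options,
    gcp_options = gcp_options, methods = methods,
    n_repetitions = as.integer(n_repetitions), degree = as.integer(degree),
    pixel_size = pixel_size, edge_unit = edge_unit, ring_depth = ring_depth,
    outer_jitter_sd = outer_jitter_sd, seed = as.integer(seed),
    outdir = outdir, write_rasters = isTRUE(write_rasters)
  ), class = "experiment_config")
}

#' Run a simulated experiment end to end
#'
#' For every growth stage: draws the field's true heights once; renders,
#' per acquisition condition (camera angle x RTK) and flight repetition,
#' one pre-germination and one on-season DSM; applies each
#' ground-altitude method (with and without GCP correction) to get a
#' photogrammetric height per measured row; joins with the measured
#' heights; and runs the different-targets-and-different-flight
#' cross-validation per condition. Deterministic given the config seed.
#'
#' GCP correction is applied as post-hoc zeroing of the simulated datum
#' offset. Methods M2 and M3 are datum invariant, so their heights are
#' shared between the GCP variants; M1 inherits the datum gap between
#' the paired flights unless corrected.
#'
#' @param config an [experiment_config()].
#' @return object of class `run_manifest`: list with `stages` (per stage:
#'   `samples`, `reports`, `table`), `config`, `products` (paths of
#'   written files) and `elapsed` (seconds).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()["elapsed"]
  layout <- config$layout
  inner <- build_inner_rois(layout)
  outer <- build_outer_rois(layout$region, config$edge_unit,
                            config$ring_depth, config$outer_jitter_sd,
                            seed = derive_seed(config$seed, 9999))
  products <- character()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_rois_geojson(inner, file.path(config$outdir, "inner_rois.geojson"))
    write_rois_geojson(outer, file.path(config$outdir, "outer_rois.geojson"))
    products <- c(products,
                  file.path(config$outdir, c("inner_rois.geojson",
                                             "outer_rois.geojson")))
  }

  stages <- list()
  for (si in seq_along(config$canopies)) {
    stage <- names(config$canopies)[si]
    canopy <- config$canopies[[si]]
    heights <- generate_true_heights(layout, canopy,
                                     derive_seed(config$seed, si, 0))
    measured <- heights[heights$measured, c("row_id", "group", "true_height")]
    names(measured)[3] <- "ph_measured"

    samples <- list()
    for (ai in seq_along(config$camera_angles)) {
      angle <- config$camera_angles[ai]
      for (ri in seq_along(config$rtk_options)) {
        rtk <- config$rtk_options[ri]
        for (rep in seq_len(config$n_repetitions)) {
          fl_on <- flight_scenario(angle, rtk, gcp = FALSE, "on_season", rep,
                                   derive_seed(config$seed, si, ai, ri, rep, 1))
          fl_off <- flight_scenario(angle, rtk, gcp = FALSE,
                                    "pre_germination", rep,
                                    derive_seed(config$seed, si, ai, ri, rep, 2))
          on <- render_dsm(layout, config$terrain, canopy, fl_on,
                           config$noise, config$pixel_size, heights)
          off <- render_dsm(layout, config$terrain, NULL, fl_off,
                            config$noise, config$pixel_size)
          if (config$write_rasters && !is.null(config$outdir)) {
            for (nm in c("on", "off")) {
              p <- file.path(config$outdir, sprintf(
                "dsm_%s_%s_a%d_rtk%d_rep%d.asc", stage, nm, abs(angle),
                as.integer(rtk), rep))
              write_ascii_grid(get(nm), p)
              products <- c(products, p)
            }
          }

          # datum-invariant methods: shared by both GCP variants
          ph <- list()
          if ("M3" %in% config$methods) {
            chm3 <- method_m3(on, outer, config$degree)
            ph$M3 <- chm_row_heights(chm3, inner)
          }
          if ("M2" %in% config$methods) ph$M2 <- m2_row_heights(on, inner)
          if ("M1" %in% config$methods) {
            chm1 <- method_m1(on, off)
            ph$M1 <- chm_row_heights(chm1, inner)
            # GCP zeroes both datum offsets: a constant shift of the CHM
            gap <- attr(on, "datum_offset") - attr(off, "datum_offset")
            ph$M1_gcp <- ph$M1
            ph$M1_gcp$ph_sfm <- ph$M1$ph_sfm - gap
          }

          for (gcp in config$gcp_options) for (method in config$methods) {
            tab <- if (method == "M1" && gcp) ph$M1_gcp else ph[[method]]
            s <- merge(measured, tab, by = c("row_id", "group"))
            s$repetition <- rep
            s$camera_angle <- angle
            s$rtk <- rtk
            s$gcp <- gcp
            s$method <- method
            samples[[length(samples) + 1]] <- s
          }
        }
      }
    }
    samples <- do.call(rbind, samples)
    samples$stage <- stage

    conds <- unique(samples[, c("camera_angle", "rtk", "gcp", "method")])
    reports <- do.call(rbind, lapply(seq_len(nrow(conds)), function(j) {
      cd <- conds[j, ]
      s <- samples[samples$camera_angle == cd$camera_angle &
                     samples$rtk == cd$rtk & samples$gcp == cd$gcp &
                     samples$method == cd$method, ]
      cbind(cd, run_condition(s))
    }))
    tab <- condition_table(reports)

    if (!is.null(config$outdir)) {
      ps <- file.path(config$outdir, sprintf("samples_%s.csv", stage))
      pr <- file.path(config$outdir, sprintf("report_%s.csv", stage))
      utils::write.csv(samples, ps, row.names = FALSE)
      utils::write.csv(tab, pr, row.names = FALSE)
      products <- c(products, ps, pr)
    }
    stages[[stage]] <- list(samples = samples, reports = reports, table = tab)
  }

  manifest <- structure(list(
    stages = stages,
    products = products,
    n_conditions = length(config$camera_angles) * length(config$rtk_options) *
      length(config$gcp_options) * length(config$methods),
    seed = config$seed,
    version = as.character(utils::packageVersion("uavph")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    elapsed = unname(proc.time()["elapsed"] - t0)
  ), class = "run_manifest")
  if (!is.null(config$outdir)) {
    mp <- file.path(config$outdir, "manifest.yaml")
    yaml::write_yaml(list(
      products = manifest$products, seed = manifest$seed,
      n_conditions = manifest$n_conditions, version = manifest$version,
      timestamp = manifest$timestamp), mp)
    manifest$products <- c(manifest$products, mp)
  }
  manifest
}

#' Select the terrain-surface degree on a reference field
#'
#' Mirrors the calibration-field procedure: render `n_repetitions`
#' on-season flights over the layout, apply method M3 with every
#' candidate degree, correlate photogrammetric with measured height per
#' repetition, average the correlations per degree and pick the degree
#' with the strongest mean correlation ([select_degree()]).
#'
#' @param layout a [field_layout()].
#' @param canopy a [canopy_spec()].
#' @param terrain a [terrain_spec()]; default terrain when `NULL`.
#' @param noise a [noise_spec()].
#' @param degrees candidate degrees.
#' @param n_repetitions flight repetitions.
#' @param camera_angle,rtk acquisition condition of the flights.
#' @param pixel_size raster pixel edge (m).
#' @param edge_unit,ring_depth,outer_jitter_sd ring-ROI geometry.
#' @param seed master seed.
#' @return list with `r_by_degree` (named mean correlations),
#'   `selected_degree`, and the per-repetition correlation matrix `r`.
#' @export
run_degree_selection <- function(layout, canopy, terrain = NULL,
                                 noise = noise_spec(), degrees = 0:4,
                                 n_repetitions = 3L, camera_angle = -90,
                                 rtk = FALSE, pixel_size = 0.03,
                                 edge_unit = 1.0, ring_depth = 0.5,
                                 outer_jitter_sd = 0.02, seed = 1L) {
  if (is.null(terrain)) terrain <- terrain_spec(default_terrain(layout$region))
  inner <- build_inner_rois(layout)
  outer <- build_outer_rois(layout$region, edge_unit, ring_depth,
                            outer_jitter_sd,
                            seed = derive_seed(seed, 8888))
  heights <- generate_true_heights(layout, canopy, derive_seed(seed, 1, 0))
  measured <- heights[heights$measured, ]

  r <- matrix(NA_real_, nrow = n_repetitions, ncol = length(degrees),
              dimnames = list(NULL, as.character(degrees)))
  for (rep in seq_len(n_repetitions)) {
    fl <- flight_scenario(camera_angle, rtk, gcp = FALSE, "on_season", rep,
                          derive_seed(seed, 7, rep))
    dsm <- render_dsm(layout, terrain, canopy, fl, noise, pixel_size, heights)
    pts <- ring_points(dsm, outer)
    for (di in seq_along(degrees)) {
      surf <- fit_polynomial_dtm(pts, degrees[di])
      dtm <- surface_raster(surf, dsm)
      chm <- raster_grid(dsm$values - dtm$values, dsm$origin, dsm$pixel_size,
                         dsm$nodata)
      ph <- chm_row_heights(chm, inner)
      s <- merge(measured, ph, by = "row_id")
      r[rep, di] <- pearson_r(s$true_height, s$ph_sfm)
    }
  }
  r_mean <- colMeans(r)
  list(r_by_degree = r_mean, selected_degree = select_degree(r_mean), r = r)
}

#' Scaled reference-field and calibration-field layouts
#'
#' Compact versions of the two emulated trial fields, keeping the plot
#' geometry (4 rows x 18 plants per plot, 0.75 m x 0.18 m spacing, middle
#' two rows measured, three blocks per row) while reducing the plot
#' count so a full condition grid renders in minutes: 12 plots for the
#' reference field (24 measured rows) and 18 plots in three contiguous
#' groups for the calibration field (36 measured rows, so each
#' validation set trains on 24 and validates on 12 samples).
#'
#' @return a [field_layout()].
#' @export
preset_field1_layout <- function() {
  field_layout(n_plots = 12, plot_cols = 4)
}

#' @rdname preset_field1_layout
#' @export
preset_field2_layout <- function() {
  field_layout(n_plots = 18, plot_cols = 6)
}

#' Full-scale calibration-field layout
#'
#' The emulated trial's real dimensions: 84 plots (11 plots per column)
#' inside a 35.5 m x 54 m analysis region, 168 measured rows in three
#' spatial groups of 56, so each validation set trains on 112 samples
#' and validates on 56.
#'
#' @return a [field_layout()].
#' @export
field2_layout_fullscale <- function() {
  field_layout(n_plots = 84, plot_cols = 11, region = c(35.5, 54))
}

#' Replicate the two-field study structure on synthetic scenes
#'
#' Runs the complete analysis the way the emulated study was organized:
#' first the reference-field degree selection (method M3 with candidate
#' degrees 0-4, nadir flights, three repetitions) per growth stage, then
#' the calibration-field comparison of all 24 conditions (2 camera
#' angles x RTK on/off x GCP on/off x 3 methods) with the selected
#' degree, cross-validated per condition.
#'
#' @param seed master seed.
#' @param outdir optional output directory for CSV products.
#' @param stages growth stages to run.
#' @param pixel_size raster pixel edge (m).
#' @return list with `degree_selection` (per stage), `field2` (the
#'   [run_experiment()] manifest) and `selected_degrees`.
#' @export
replicate_study_structure <- function(seed = 1L, outdir = NULL,
                                      stages = c("vegetative",
                                                 "reproductive"),
                                      pixel_size = 0.03) {
  f1 <- preset_field1_layout()
  canopies_f1 <- list(vegetative = canopy_vegetative(field = 1),
                      reproductive = canopy_reproductive(field = 1))
  degree_selection <- list()
  for (stage in stages) {
    degree_selection[[stage]] <- run_degree_selection(
      f1, canopies_f1[[stage]], pixel_size = pixel_size,
      seed = derive_seed(seed, match(stage, stages), 11))
  }
  selected <- vapply(degree_selection, `[[`, 0L, "selected_degree")

  canopies_f2 <- list(vegetative = canopy_vegetative(field = 2),
                      reproductive = canopy_reproductive(field = 2))
  # one experiment per stage so each uses its own selected degree
  f2_stages <- list()
  for (stage in stages) {
    cfg <- experiment_config(
      preset_field2_layout(),
      canopies = canopies_f2[stage],
      degree = selected[[stage]],
      pixel_size = pixel_size,
      seed = derive_seed(seed, 100 + match(stage, stages)),
      outdir = outdir)
    f2_stages[[stage]] <- run_experiment(cfg)
  }
  list(degree_selection = degree_selection,
       selected_degrees = selected,
       field2 = f2_stages)
}
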