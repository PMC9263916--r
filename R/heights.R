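#' Draw true row-level plant heights
#'
#' One true plant height per crop row, composed of a plot-level variety
#' effect and a row-level deviation (each contributing half of the
#' specified height variance), clipped to the canopy's height range. The
#' value stands for the row's measured plant height: the mean over the
#' consecutively placed plants of the row's measurement block, which all
#' share the row height in this generator.
#'
#' @param layout a [field_layout()].
#' @param canopy a [canopy_spec()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return data frame with one line per row of the layout: `row_id`,
#'   `plot`, `row_in_plot`, `group`, `measured`, `true_height` (m).
#' @export
generate_true_heights <- function(layout, canopy, seed) {
  stopifnot(inherits(layout, "field_layout"), inherits(canopy, "canopy_spec"))
  set.seed(as.integer(seed))
  sd_part <- canopy$height_sd * sqrt(0.5)
  plot_eff <- stats::rnorm(layout$n_plots, 0, sd_part)
  rows <- layout$rows
  h <- canopy$height_mean + plot_eff[rows$plot] +
    stats::rnorm(nrow(rows), 0, sd_part)
  h <- pmin(pmax(h, canopy$height_min), canopy$height_max)
  data.frame(
    row_id = rows$row_id,
    plot = rows$plot,
    row_in_plot = rows$row_in_plot,
    group = rows$group,
    measured = rows$measured,
    true_height = h
  )
}
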