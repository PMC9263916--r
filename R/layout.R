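#' Define a row-crop field layout
#'
#' Builds the planar geometry of a variety-trial field: a grid of plots,
#' each containing `rows_per_plot` crop rows with `plants_per_row` plants.
#' All coordinates are local planar meters with the origin at the
#' south-west corner of the analysis region. Rows run along the y axis;
#' plots are tiled column-major from the origin, `plot_cols` plots across.
#'
#' Height is measured in a subset of rows per plot (`measured_rows`,
#' 1-based row positions within the plot; the default is the middle two of
#' four). Each row is divided lengthwise into `blocks_per_row` blocks of
#' equal plant count; the central block holds the consecutively placed
#' plants whose mean height defines the row's measured plant height.
#'
#' Plots are assigned to `n_groups` spatially contiguous groups (south to
#' north) used by the cross-flight validation scheme; an explicit
#' per-plot assignment can be supplied via `group_of_plot`.
#'
#' @param n_plots number of plots.
#' @param rows_per_plot crop rows per plot.
#' @param plants_per_row plants in each row; must be divisible by
#'   `blocks_per_row`.
#' @param row_spacing distance between adjacent rows (m).
#' @param plant_spacing in-row distance between adjacent plants (m).
#' @param blocks_per_row number of equal blocks each row is divided into.
#' @param measured_rows 1-based positions of the measured rows in a plot.
#' @param plot_cols plots per west-east column of the tiling; default
#'   `ceiling(sqrt(n_plots))`.
#' @param region optional `c(width, length)` of the analysis region (m).
#'   When given, the plot tiling must fit inside it; when omitted the
#'   region is the tight bounding box of the tiling.
#' @param n_groups number of contiguous spatial groups.
#' @param group_of_plot optional integer vector (length `n_plots`) of
#'   group labels overriding the contiguous assignment.
#'
#' @return An object of class `field_layout`: a list with the call
#'   parameters plus `region`, a `plots` data frame (plot origin and
#'   group) and a `rows` data frame (one line per crop row with its x
#'   position, y extent, measured flag and group).
#' @export
field_layout <- function(n_plots,
                         rows_per_plot = 4L,
                         plants_per_row = 18L,
                         row_spacing = 0.75,
                         plant_spacing = 0.18,
                         blocks_per_row = 3L,
                         measured_rows = c(2L, 3L),
                         plot_cols = NULL,
                         region = NULL,
                         n_groups = 3L,
                         group_of_plot = NULL) {
  stopifnot(n_plots >= 1, rows_per_plot >= 1, plants_per_row >= 1)
  if (row_spacing <= 0 || plant_spacing <= 0)
    stop("row_spacing and plant_spacing must be positive")
  if (plants_per_row %% blocks_per_row != 0)
    stop("plants_per_row must be divisible by blocks_per_row")
  measured_rows <- sort(unique(as.integer(measured_rows)))
  if (any(measured_rows < 1L) || any(measured_rows > rows_per_plot))
    stop("measured_rows must lie within 1..rows_per_plot")

  plot_w <- rows_per_plot * row_spacing
  plot_l <- plants_per_row * plant_spacing
  if (is.null(plot_cols)) plot_cols <- ceiling(sqrt(n_plots))
  plot_cols <- as.integer(plot_cols)
  plot_rows <- ceiling(n_plots / plot_cols)

  need <- c(plot_cols * plot_w, plot_rows * plot_l)
  if (is.null(region)) {
    region <- need
  } else {
    region <- as.numeric(region)
    if (length(region) != 2 || any(region < need - 1e-9))
      stop(sprintf(
        "region too small for requested plots: need at least %.2f x %.2f m",
        need[1], need[2]))
  }

  plot_id <- seq_len(n_plots)
  col <- ((plot_id - 1L) %% plot_cols) + 1L
  prow <- ((plot_id - 1L) %/% plot_cols) + 1L
  plots <- data.frame(
    plot = plot_id,
    x0 = (col - 1L) * plot_w,
    y0 = (prow - 1L) * plot_l
  )

  if (is.null(group_of_plot)) {
    # contiguous south-to-north thirds (plots are numbered row-major)
    group_of_plot <- as.integer(cut(plot_id, breaks = n_groups, labels = FALSE))
  }
  stopifnot(length(group_of_plot) == n_plots)
  plots$group <- as.integer(group_of_plot)

  rows <- do.call(rbind, lapply(plot_id, function(p) {
    r <- seq_len(rows_per_plot)
    data.frame(
      plot = p,
      row_in_plot = r,
      x = plots$x0[p] + (r - 0.5) * row_spacing,
      y0 = plots$y0[p],
      y1 = plots$y0[p] + plot_l,
      measured = r %in% measured_rows,
      group = plots$group[p]
    )
  }))
  rows$row_id <- seq_len(nrow(rows))
  rows <- rows[, c("row_id", "plot", "row_in_plot", "x", "y0", "y1",
                   "measured", "group")]

  structure(
    list(
      n_plots = as.integer(n_plots),
      rows_per_plot = as.integer(rows_per_plot),
      plants_per_row = as.integer(plants_per_row),
      row_spacing = row_spacing,
      plant_spacing = plant_spacing,
      blocks_per_row = as.integer(blocks_per_row),
      measured_rows = measured_rows,
      plot_cols = plot_cols,
      region = region,
      n_groups = as.integer(n_groups),
      plots = plots,
      rows = rows
    ),
    class = "field_layout"
  )
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf(
    "field_layout: %d plots (%d x %d rows x %d plants), region %.2f x %.2f m\n",
    x$n_plots, x$rows_per_plot, x$n_plots, x$plants_per_row,
    x$region[1], x$region[2]))
  cat(sprintf("  spacing %.2f m between rows, %.2f m in-row; %d measured rows\n",
              x$row_spacing, x$plant_spacing, n_measured_rows(x)))
  invisible(x)
}

#' Number of measured rows in a layout
#'
#' One measured row yields one height sample (the mean height of the
#' consecutively placed plants in its measurement block).
#'
#' @param layout a [field_layout()].
#' @return integer count, `n_plots * length(measured_rows)`.
#' @export
n_measured_rows <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  sum(layout$rows$measured)
}

#' Planting density of a layout
#'
#' @param layout a [field_layout()].
#' @return plants per square meter, `1 / (row_spacing * plant_spacing)`.
#' @export
planting_density <- function(layout) {
  stopifnot(inherits(layout, "field_layout"))
  if (layout$row_spacing <= 0 || layout$plant_spacing <= 0)
    stop("spacings must be positive")
  1 / (layout$row_spacing * layout$plant_spacing)
}

#' Y extent of one block within a row
#'
#' @param layout a [field_layout()].
#' @param row one line of `layout$rows`.
#' @param block block index, 1-based from the south end.
#' @return `c(y_start, y_end)` in meters.
#' @keywords internal
block_extent <- function(layout, row, block) {
  ppb <- layout$plants_per_row / layout$blocks_per_row
  y0 <- row$y0 + (block - 1L) * ppb * layout$plant_spacing
  c(y0, y0 + ppb * layout$plant_spacing)
}
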