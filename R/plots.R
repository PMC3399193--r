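raster_plot_df <- function(values, grid, name) {
  df <- raster_to_tibble(values, grid, name)
  df[!is.na(df[[name]]), ]
}

#' Plot a suitability map
#'
#' @param object A `suitability_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot suitability_map
#' @export
autoplot.suitability_map <- function(object, ...) {
  df <- raster_plot_df(object$values, object$grid, "suitability")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0(object$species_id, " (", object$provenance, ")"),
      x = "x (km)", y = "y (km)", fill = "suitability"
    )
}

#' Plot a binary range
#'
#' @param object A `binary_range`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot binary_range
#' @export
autoplot.binary_range <- function(object, ...) {
  df <- raster_plot_df(object$presence, object$grid, "presence")
  df$presence <- factor(df$presence, c(0, 1), c("absent", "present"))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$presence)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(absent = "grey90", present = "forestgreen")) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste0(
        object$species_id, " ", format(object$decade), " (",
        format(object$scenario), ")"
      ),
      x = "x (km)", y = "y (km)", fill = NULL
    )
}

#' Plot a species-richness grid
#'
#' @param object A `richness_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot richness_grid
#' @export
autoplot.richness_grid <- function(object, ...) {
  df <- raster_plot_df(object$counts, object$grid, "richness")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$richness)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf(
        "Species richness, %s (%s)", format(object$decade),
        format(object$scenario)
      ),
      x = "x (km)", y = "y (km)"
    )
}

#' Histogram of proportional range change across species
#'
#' Proportional change of 1 is no change, 0 complete loss, values above 1 an
#' expansion; one panel per dispersal scenario when several are present.
#'
#' @param records Change-record tibble (columns `proportion_of_current`,
#'   optionally `scenario`).
#' @param binwidth Histogram bin width on the ratio scale.
#' @return A ggplot.
#' @export
plot_change_histogram <- function(records, binwidth = 0.1) {
  p <- ggplot2::ggplot(records, ggplot2::aes(.data$proportion_of_current)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
      colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(
      x = "proportional change in range area (future / current)",
      y = "species"
    )
  if ("scenario" %in% names(records)) {
    p <- p + ggplot2::facet_wrap(~scenario)
  }
  p
}

#' Boxplots of proportional range change by species group
#'
#' @param records Change-record tibble with `proportion_of_current` and the
#'   grouping column.
#' @param grouping Grouping column name (e.g. `"movement_class"`).
#' @return A ggplot.
#' @export
plot_group_comparison <- function(records, grouping) {
  stopifnot(grouping %in% names(records))
  ggplot2::ggplot(records, ggplot2::aes(
    .data[[grouping]], .data$proportion_of_current
  )) +
    ggplot2::geom_boxplot(fill = "goldenrod") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = grouping, y = "proportional change (future / current)")
}

#' Map of richness change between two decades
#'
#' @param change Signed change matrix from [richness_change()].
#' @param grid The shared [grid_spec()].
#' @return A ggplot.
#' @export
plot_richness_change <- function(change, grid) {
  df <- raster_plot_df(change, grid, "change")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$change)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
      high = "navy") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)", fill = "richness\nchange")
}
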