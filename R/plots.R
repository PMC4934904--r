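#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot annual pattern-index trajectories
#'
#' One faceted panel per index, one line per landscape.
#'
#' @param object A `fp_index_table`.
#' @param indices Index columns to show.
#' @param alpha Line transparency.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_index_table
#' @export
autoplot.fp_index_table <- function(object,
                                    indices = c("forest_cover", "lpi",
                                                "edge_density", "core_cover"),
                                    alpha = 0.4, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::all_of(indices), names_to = "index",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value,
                                     group = .data$landscape_id)) +
    ggplot2::geom_line(alpha = alpha) +
    ggplot2::facet_wrap(~index, scales = "free_y") +
    ggplot2::labs(x = "Year", y = NULL,
                  title = "Landscape pattern indices over time") +
    ggplot2::theme_minimal()
}

#' Plot a Moran's I spatial correlogram
#'
#' Observed I per lag bin with the +/- 2 SE large-lag band around the null
#' expectation.
#'
#' @param object A `fp_correlogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_correlogram
#' @export
autoplot.fp_correlogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$expected - 2 * .data$se,
                                      ymax = .data$expected + 2 * .data$se),
                         fill = "grey80") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$expected[1L]),
                        linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed,
                                     colour = .data$significant)) +
    ggplot2::labs(x = "Lag distance (m)", y = "Moran's I",
                  colour = "Significant") +
    ggplot2::theme_minimal()
}

#' Plot per-landscape trend slopes by change class
#'
#' @param object A `fp_trend_table` with a `class` column (see
#'   [classify_change()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_trend_table
#' @export
autoplot.fp_trend_table <- function(object, ...) {
  if (is.null(object$class)) object$class <- factor("unclassified")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sen_slope,
                                       fill = .data$class)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = expression("Theil-Sen slope (units " * y^-1 * ")"),
                  y = "Landscapes", fill = "Change class") +
    ggplot2::theme_minimal()
}

#' Plot cross-landscape temporal autocorrelation by lag
#'
#' @param object A `fp_acf_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fp_acf_summary
#' @export
autoplot.fp_acf_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$lag))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = -2 * .data$se,
                                        ymax = 2 * .data$se),
                           width = 0.4, colour = "red", linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$mean_r, ymin = .data$q25,
                                          ymax = .data$q75,
                                          colour = .data$significant)) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Lag (years)", y = "Autocorrelation",
                  colour = "Significant") +
    ggplot2::theme_minimal()
}

#' Map one year of a forest map series
#'
#' @param maps A `fp_maps`.
#' @param year Calendar year to draw (default: first).
#' @return A ggplot raster map (forest / non-forest / background).
#' @export
plot_forest_map <- function(maps, year = NULL) {
  stopifnot(inherits(maps, "fp_maps"))
  if (is.null(year)) year <- maps$years[1L]
  t <- match(year, maps$years)
  if (is.na(t)) stop_input("year not in the series")
  m <- maps$maps[, , t]
  df <- tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)),
    cover = factor(ifelse(is.na(as.vector(m)), "background",
                          ifelse(as.vector(m) == 1L, "forest", "non-forest")),
                   levels = c("forest", "non-forest", "background"))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$cover)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(forest = "#2d6a2d",
                                          `non-forest` = "#e8d8a8",
                                          background = "grey70")) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste("Forest cover,", year), x = NULL, y = NULL,
                  fill = NULL) +
    ggplot2::theme_void()
}
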