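#' Plot a simulation result
#'
#' `what = "biomass"` draws every colony's biomass trajectory coloured by
#' role (log scale); `what = "toxin"` and `what = "carbon"` draw the final
#' lattice field with founder colony positions overlaid.
#'
#' @param object a `toxsim_result`.
#' @param what `"biomass"`, `"toxin"` or `"carbon"`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.toxsim_result <- function(object, what = c("biomass", "toxin",
                                                    "carbon"), ...) {
  what <- match.arg(what)
  if (what == "biomass") {
    df <- tidy(object)
    return(
      ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$biomass,
                                       group = .data$colony,
                                       colour = .data$role)) +
        ggplot2::geom_line(alpha = 0.7) +
        ggplot2::scale_y_log10() +
        ggplot2::labs(x = "time (hr)", y = "colony biomass (gDW)",
                      colour = "role")
    )
  }
  field <- object$final[[what]]
  df <- tidyr::expand_grid(row = seq_len(nrow(field)) - 1L,
                           col = seq_len(ncol(field)) - 1L)
  df$value <- as.vector(field)[df$row + 1L + nrow(field) * df$col]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_point(data = object$registry,
                        ggplot2::aes(.data$col, .data$row,
                                     shape = .data$role),
                        inherit.aes = FALSE, colour = "white", size = 2) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = sprintf("%s (mmol/box)", what),
                  x = "column", y = "row")
}

#' Heatmap of producer fitness over a parameter sweep
#'
#' Averages a fitness column of a [run_sweep()] table over replicate seeds
#' and draws the growth-rate-by-axis heatmap.
#'
#' @param sweep_table output of [run_sweep()].
#' @param axis the swept parameter column (y axis).
#' @param fill fitness column to average (default
#'   `"producer_fraction_total"`).
#' @return a ggplot object.
#' @export
plot_sweep_heatmap <- function(sweep_table, axis,
                               fill = "producer_fraction_total") {
  agg <- sweep_table |>
    dplyr::group_by(.data$growth_rate, .data[[axis]]) |>
    dplyr::summarise(value = mean(.data[[fill]]), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(factor(.data$growth_rate),
                                    factor(.data[[axis]]),
                                    fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "growth rate (1/hr)", y = axis, fill = fill)
}
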