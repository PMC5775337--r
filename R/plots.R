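#' Plot per-date trait trends (mean and standard deviation)
#'
#' Summarises a per-plant, per-date trait table to a mean +/- SD trajectory
#' per trait, the standard way canopy development over the season is shown.
#'
#' @param table Trait table with a `dap` column and the trait columns.
#' @param traits Character vector of trait columns (default the five
#'   morphological traits plus `tc_minus_ta_c` when present).
#' @return A ggplot object (one facet per trait).
#' @export
plot_trait_trends <- function(table,
                              traits = intersect(c("h_m", "wir_m", "war_m",
                                                   "pla_m2", "cv_m3",
                                                   "tc_minus_ta_c"),
                                                 names(table))) {
  stopifnot("dap" %in% names(table), length(traits) >= 1L)
  long <- tidyr::pivot_longer(table[c("dap", traits)], -"dap",
                              names_to = "trait", values_to = "value")
  summ <- dplyr::summarise(dplyr::group_by(long, .data$trait, .data$dap),
                           mean = mean(.data$value, na.rm = TRUE),
                           sd = sd(.data$value, na.rm = TRUE),
                           .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$dap, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 1.5, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(shape = 8) +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "Days after planting", y = "Trait value") +
    ggplot2::theme_minimal()
}

#' Plot a thermal frame with its extracted plant mask outline
#'
#' @param img Temperature matrix (deg C).
#' @param mask Optional logical mask (e.g. from
#'   [extract_canopy_temperature()]'s `mask` attribute).
#' @return A ggplot object.
#' @export
plot_thermal_mask <- function(img, mask = NULL) {
  df <- tidyr::expand_grid(y = seq_len(nrow(img)), x = seq_len(ncol(img)))
  df$t_c <- img[cbind(df$y, df$x)]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t_c)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "deg C") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    df$m <- mask[cbind(df$y, df$x)]
    p <- p + ggplot2::geom_point(data = df[df$m, ], shape = ".",
                                 colour = "cyan", inherit.aes = FALSE,
                                 ggplot2::aes(.data$x, .data$y))
  }
  p
}
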