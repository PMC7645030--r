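#' Raster heatmap of stimulus-aligned epochs
#'
#' One row per epoch, colored by signal; rows ordered responsive-first and
#' by peak amplitude when a detection table is supplied.
#'
#' @param epochs A `pk_epochs`.
#' @param detection Optional [test_responsiveness()] table used for row
#'   ordering.
#' @return A ggplot object.
#' @export
plot_epoch_raster <- function(epochs, detection = NULL) {
  stopifnot(inherits(epochs, "pk_epochs"))
  ord <- seq_len(nrow(epochs$signal))
  if (!is.null(detection)) {
    key <- match(epochs$info$epoch_id, detection$epoch_id)
    ord <- order(-detection$is_test_responsive[key],
                 -detection$peak_signal_pct[key])
  }
  df <- tidyr::expand_grid(
    row = seq_len(nrow(epochs$signal)),
    col = seq_along(epochs$rel_time_s))
  df$rel_time_s <- epochs$rel_time_s[df$col]
  df$signal_pct <- epochs$signal[cbind(ord[df$row], df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rel_time_s, y = .data$row,
                                   fill = .data$signal_pct)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "% of baseline") +
    ggplot2::scale_y_reverse() +
    ggplot2::geom_vline(xintercept = 0, color = "white",
                        linetype = "dashed") +
    ggplot2::labs(x = "time from stimulation onset (s)", y = "epoch") +
    ggplot2::theme_minimal()
}

#' Mean +/- SEM trace across epochs
#'
#' @param epochs A `pk_epochs`.
#' @return A ggplot object.
#' @export
plot_mean_trace <- function(epochs) {
  pm <- pool_mean_trace(epochs)
  ggplot2::ggplot(pm, ggplot2::aes(x = .data$rel_time_s,
                                   y = .data$mean_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_pct - .data$sem_pct,
                                      ymax = .data$mean_pct + .data$sem_pct),
                         fill = "grey80") +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from stimulation onset (s)",
                  y = "signal (% of baseline)") +
    ggplot2::theme_classic()
}
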