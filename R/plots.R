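# Waveform and topography displays (ggplot2, ERP negative-up convention).

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_vline geom_hline
#'   geom_point geom_raster geom_path labs scale_y_reverse coord_fixed
#'   scale_fill_gradient2 theme_minimal theme_void element_text
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot evoked waveforms at selected channels
#'
#' Overlaid category traces, ERP convention (negative up), stimulus onset
#' marked at 0 ms.
#'
#' @param evokeds an `erp_evoked` or (possibly named) list of them.
#' @param channels electrode labels to display.
#' @return a ggplot object.
#' @export
plot_waveforms <- function(evokeds, channels = c("Fz", "Cz", "Pz")) {
  if (inherits(evokeds, "erp_evoked")) evokeds <- list(evokeds)
  ref <- evokeds[[1]]
  channels <- .match_label(channels, ref$montage)
  df <- dplyr::bind_rows(lapply(evokeds, function(ev) {
    idx <- match(channels, rownames(ev$data))
    if (anyNA(idx)) abort("unknown channel in evoked data")
    tidyr::pivot_longer(
      tibble::as_tibble(cbind(time_ms = ev$time_ms,
                              t(ev$data[idx, , drop = FALSE]))),
      -"time_ms", names_to = "channel", values_to = "amplitude_uv"
    ) |> dplyr::mutate(category = ev$category)
  }))
  ggplot(df, aes(x = .data$time_ms, y = .data$amplitude_uv,
                 color = .data$category)) +
    geom_line(linewidth = 0.4) +
    geom_vline(xintercept = 0, linetype = "dashed", linewidth = 0.3) +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    scale_y_reverse() +  # ERP convention: negative up
    ggplot2::facet_wrap(~channel) +
    labs(x = "time (ms)", y = "amplitude (uV, negative up)",
         color = "category") +
    theme_minimal()
}

#' @export
autoplot.erp_evoked <- function(object, channels = c("Fz", "Cz", "Pz"), ...) {
  plot_waveforms(object, channels)
}

#' Isocolor scalp topography of window-mean voltage
#'
#' Interpolates the mean voltage over a time window across the 2-D projected
#' montage (inverse-distance weighting on a grid clipped to the head disc),
#' with a color scale symmetric about 0 uV. EOG channels are excluded. The
#' evoked object is not modified.
#'
#' @param evoked an `erp_evoked`.
#' @param window_ms `c(start, end)` window (ms, half-open).
#' @param grid_n interpolation grid resolution.
#' @return a ggplot object.
#' @export
plot_topomap <- function(evoked, window_ms = c(200, 400), grid_n = 67) {
  fs <- evoked$fs
  cols <- .window_samples(window_ms[1], window_ms[2], fs) +
    which(evoked$time_ms >= 0)[1]
  pos <- project_2d(evoked$montage)
  idx <- match(pos$label, rownames(evoked$data))
  vals <- rowMeans(evoked$data[idx, cols, drop = FALSE])
  g <- seq(-1.05, 1.05, length.out = grid_n)
  grid <- expand.grid(x = g, y = g)
  grid <- grid[grid$x^2 + grid$y^2 <= 1.05^2, ]
  # inverse-distance-squared interpolation
  z <- vapply(seq_len(nrow(grid)), function(i) {
    d2 <- (pos$x - grid$x[i])^2 + (pos$y - grid$y[i])^2
    if (any(d2 < 1e-9)) return(vals[which.min(d2)])
    w <- 1 / d2
    sum(w * vals) / sum(w)
  }, numeric(1))
  grid$amplitude_uv <- z
  lim <- max(abs(z), 1e-9)
  circle <- tibble::tibble(t = seq(0, 2 * pi, length.out = 181))
  ggplot(grid, aes(x = .data$x, y = .data$y)) +
    geom_raster(aes(fill = .data$amplitude_uv)) +
    geom_path(data = tibble::tibble(x = cos(circle$t), y = sin(circle$t)),
              linewidth = 0.4) +
    geom_point(data = pos, size = 0.3) +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         limits = c(-lim, lim)) +
    coord_fixed() +
    labs(fill = "uV",
         title = sprintf("%s, %g-%g ms", evoked$category, window_ms[1],
                         window_ms[2])) +
    theme_void() +
    ggplot2::theme(plot.title = element_text(hjust = 0.5))
}
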