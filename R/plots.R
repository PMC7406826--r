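#' Plot a framewise-displacement trace
#'
#' FD over time with the scrubbing threshold; flagged volumes are marked.
#'
#' @param fd Framewise displacement series from [compute_fd()].
#' @param thr Scrubbing threshold (default 0.5 mm).
#' @return A ggplot object.
#' @export
plot_fd_trace <- function(fd, thr = 0.5) {
  df <- tibble(volume = seq_along(fd), fd = fd, flagged = fd > thr)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$volume, y = .data$fd)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(df, .data$flagged),
                        colour = "firebrick", size = 1.6) +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = "volume", y = "framewise displacement (mm)") +
    ggplot2::theme_minimal()
}

#' Slice view of a mediation map
#'
#' Heatmap of one axial slice of a per-voxel map (coefficients or p-values).
#'
#' @param object A `mediation_maps` result with grid geometry.
#' @param what Component to plot (default `"ab"`).
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_maps
#' @export
autoplot.mediation_maps <- function(object, what = "ab", slice = NULL, ...) {
  arr <- map_array(object, what)
  if (is.null(slice)) slice <- ceiling(dim(arr)[3] / 2)
  sl <- arr[, , slice]
  df <- tibble(x = rep(seq_len(nrow(sl)), ncol(sl)),
               y = rep(seq_len(ncol(sl)), each = nrow(sl)),
               value = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s map, slice z=%d", what, slice),
                  fill = what) +
    ggplot2::theme_minimal()
}

#' Power curve plot
#'
#' @param object A [power_curve()] tibble.
#' @param target Optional horizontal reference line (e.g. 0.8).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot power_curve
#' @export
autoplot.power_curve <- function(object, target = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$power - 2 * .data$mc_se,
                                          ymax = .data$power + 2 * .data$mc_se)) +
    ggplot2::labs(x = "sample size", y = "power (indirect effect)") +
    ggplot2::theme_minimal()
  if (!is.null(target)) p <- p + ggplot2::geom_hline(yintercept = target, linetype = 2)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
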