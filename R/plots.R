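#' Topographic scalp map of a per-electrode quantity
#'
#' Plots electrode-wise values on the flattened montage (azimuthal
#' projection of the spherical positions), colour-coded, optionally marking
#' a channel subset (e.g. a significant cluster) with black dots.
#'
#' @param values Tibble with `channel` and the column named in `value_col`.
#' @param value_col Column to map to colour (default `"t"`).
#' @param montage Montage tibble (default [montage_1010()]).
#' @param mark_channels Channels to overplot with black dots.
#' @return A ggplot object.
#' @export
plot_topomap <- function(values, value_col = "t", montage = montage_1010(),
                         mark_channels = character()) {
  pos <- flatten_montage(montage)
  df <- dplyr::inner_join(values, pos, by = "channel")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$px, y = .data$py)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[value_col]]),
                        size = 5) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "white",
                                    high = "#b2182b") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = value_col)
  if (length(mark_channels) > 0) {
    p <- p + ggplot2::geom_point(
      data = df[df$channel %in% mark_channels, , drop = FALSE],
      size = 1.2, colour = "black")
  }
  p
}

# azimuthal equidistant projection: vertex at the origin, nose up
flatten_montage <- function(montage) {
  r <- acos(pmin(pmax(montage$z, -1), 1))
  az <- atan2(montage$y, montage$x)
  tibble::tibble(channel = montage$channel,
                 px = r * sin(az), py = r * cos(az) * 1)
}

#' Plot an event-locked average waveform
#'
#' @param erp Output of [event_locked_average()].
#' @param channels Channels to draw (default up to 6 central ones present).
#' @return A ggplot object.
#' @export
plot_erp <- function(erp, channels = NULL) {
  if (is.null(channels)) {
    prefer <- c("Cz", "Fz", "Pz", "FCz", "CPz", "Oz")
    channels <- intersect(prefer, unique(erp$channel))
    if (length(channels) == 0) channels <- utils::head(unique(erp$channel), 6)
  }
  ggplot2::ggplot(erp[erp$channel %in% channels, ],
                  ggplot2::aes(x = .data$time_s, y = .data$amplitude,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event (s)", y = "amplitude (uV)") +
    ggplot2::theme_minimal()
}

#' Plot fitted drift-diffusion parameters by condition
#'
#' @param object A `ddm_fit` from [fit_ddm()].
#' @param ... Unused.
#' @return A ggplot object: one panel per parameter, conditions on the x
#'   axis.
#' @export
autoplot.ddm_fit <- function(object, ...) {
  long <- tidy(object)
  cond_cols <- setdiff(names(long), c("parameter", "estimate", "loglik",
                                      "converged", "n_trials",
                                      "n_responses"))
  long$condition_label <- if (length(cond_cols) > 0) {
    do.call(paste, c(long[cond_cols], sep = "/"))
  } else "all"
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition_label,
                                     y = .data$estimate)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
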