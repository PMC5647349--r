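#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot growth curves, optionally coloured by decoded phase
#'
#' @param curves tibble `track_id`, `day`, `area_px`.
#' @param states optional tibble `track_id`, `day`, `state` from
#'   [viterbi_phases()].
#' @return a ggplot.
#' @export
plot_growth_curves <- function(curves, states = NULL) {
  df <- curves
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$area_px,
                                        group = .data$track_id))
  if (!is.null(states)) {
    df <- dplyr::left_join(df, states, by = c("track_id", "day"))
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day, y = .data$area_px,
                                          group = .data$track_id,
                                          colour = factor(.data$state))) +
      ggplot2::labs(colour = "phase")
  }
  p + ggplot2::geom_line(alpha = 0.6) + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "day after induction", y = expression(area ~ (px^2)),
                  title = "Colony growth curves")
}

#' Plot mature-phase posteriors with the picking threshold
#'
#' @param posterior tibble from [mature_posterior()].
#' @param threshold picking threshold drawn as a horizontal line
#'   (default 0.3).
#' @return a ggplot.
#' @export
plot_mature_posterior <- function(posterior, threshold = 0.3) {
  ggplot2::ggplot(posterior,
                  ggplot2::aes(x = .data$day, y = .data$p_mature,
                               group = .data$track_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "day after induction", y = "P(mature phase)",
                  title = "Mature-phase posterior and picking threshold")
}

#' @rdname plot_mature_posterior
#' @param object a `phase_hmm`.
#' @param features feature tibble to decode and plot.
#' @param ... unused.
#' @method autoplot phase_hmm
#' @export
autoplot.phase_hmm <- function(object, features, ...) {
  plot_mature_posterior(mature_posterior(object, features))
}

#' Overlay a detection mask on a frame
#'
#' @param frame intensity matrix.
#' @param mask logical detection mask.
#' @param downsample keep every n-th pixel for plotting speed (default 2).
#' @return a ggplot raster with mask contours.
#' @export
plot_detection <- function(frame, mask, downsample = 2L) {
  ii <- seq(1, nrow(frame), by = downsample)
  jj <- seq(1, ncol(frame), by = downsample)
  df <- tidyr::expand_grid(y = ii, x = jj)
  df$intensity <- frame[cbind(df$y, df$x)]
  df$detected <- mask[cbind(df$y, df$x)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_point(data = df[df$detected, ], colour = "red",
                        size = 0.01, alpha = 0.15) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(title = "Detection overlay")
}
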