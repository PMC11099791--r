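# Optional rendering: tachograms and 2-D Poincare plots, with per-interval
# class colouring matching the conventional scheme (balanced green,
# HP/LSM blue, SND red).

class_palette <- function() {
  c(BALANCED = "#2e8b57", HPLSM = "#1f6fb4", SND = "#c23b22",
    NO_DECISION = "grey60")
}

#' Plot a tachogram
#'
#' RR interval against elapsed time, optionally coloured by per-interval
#' classification.
#'
#' @param series An [rr_series()].
#' @param interval_class Optional per-interval labels (e.g. from
#'   [classify_series()]).
#' @param ylim Interval axis range in ms (default 100-6000).
#' @return A ggplot object.
#' @export
plot_tachogram <- function(series, interval_class = NULL, ylim = c(100, 6000)) {
  td <- tachogram_data(series)
  td$hours <- td$time_ms / 3600000
  p <- if (is.null(interval_class)) {
    ggplot2::ggplot(td, ggplot2::aes(x = .data$hours, y = .data$rr)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.6)
  } else {
    td$class <- factor(interval_class, levels = names(class_palette()))
    ggplot2::ggplot(td, ggplot2::aes(x = .data$hours, y = .data$rr,
                                     colour = .data$class)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.6) +
      ggplot2::scale_colour_manual(values = class_palette(), drop = FALSE)
  }
  p + ggplot2::coord_cartesian(ylim = ylim) +
    ggplot2::labs(x = "Elapsed time (h)", y = "RR interval (ms)") +
    ggplot2::theme_minimal()
}

#' Plot a Poincaré plot
#'
#' `RR_i` against `RR_{i+1}`, optionally coloured by classification of the
#' interval on the x axis.
#'
#' @param series An [rr_series()].
#' @param interval_class Optional per-interval labels.
#' @param lim Axis range in ms for both axes (default 100-6000).
#' @return A ggplot object.
#' @export
plot_poincare <- function(series, interval_class = NULL, lim = c(100, 6000)) {
  pts <- poincare_points(series)
  p <- if (is.null(interval_class)) {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.5)
  } else {
    pts$class <- factor(interval_class[seq_len(nrow(pts))],
                        levels = names(class_palette()))
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y,
                                      colour = .data$class)) +
      ggplot2::geom_point(size = 0.3, alpha = 0.5) +
      ggplot2::scale_colour_manual(values = class_palette(), drop = FALSE)
  }
  p + ggplot2::geom_abline(slope = 1, intercept = 0,
                           linetype = "dashed", colour = "grey50") +
    ggplot2::coord_fixed(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "RR interval (ms)", y = "RR + 1 interval (ms)") +
    ggplot2::theme_minimal()
}
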