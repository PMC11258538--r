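# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_ribbon geom_line geom_col
#'   geom_vline geom_segment geom_point labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot a peri-event time histogram
#'
#' Mean trace with a +/- SEM ribbon and a vertical line at the event.
#'
#' @param object A `peth`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peth <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$rel_time, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sem,
                    ymax = .data$mean + .data$sem), alpha = 0.3) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "Time from event (s)", y = "z-scored ΔF",
         title = object$group) +
    theme_minimal()
}

#' Plot a lick session raster
#'
#' Licks as segments on their bout row, with reward times marked.
#'
#' @param object A `lick_session`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lick_session <- function(object, ...) {
  d <- object$licks
  p <- ggplot(d) +
    geom_segment(aes(x = .data$onset, xend = .data$offset,
                     y = .data$bout, yend = .data$bout)) +
    labs(x = "Session time (s)", y = "Bout") +
    theme_minimal()
  if (length(object$reward_times %||% numeric(0))) {
    p <- p + geom_point(
      data = tibble::tibble(t = object$reward_times),
      aes(x = .data$t, y = 0), shape = 17, colour = "blue"
    )
  }
  p
}

#' Plot an ILI histogram
#'
#' @param ilis Numeric vector of interlick intervals (seconds), or a
#'   histogram tibble from [ili_histogram()].
#' @param cfg A [microstructure_config()], used when `ilis` is raw.
#' @return A ggplot of the ILI distribution below the analysis ceiling.
#' @export
plot_ili_histogram <- function(ilis, cfg = microstructure_config()) {
  h <- if (is.data.frame(ilis)) ilis else ili_histogram(ilis, cfg)
  ggplot(h, aes(x = (.data$bin_lo + .data$bin_hi) / 2, y = .data$count)) +
    geom_col(width = min(h$bin_hi - h$bin_lo)) +
    labs(x = "Interlick interval (s)", y = "Count") +
    theme_minimal()
}
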