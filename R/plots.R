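#' Plot an intensity trace with its fitted bleaching staircase
#'
#' @param trace Tibble with `frame` and `intensity` (one trace).
#' @param step_fit Optional one-row step-fit tibble from [count_steps()];
#'   when given, the fitted plateau levels are overlaid.
#' @param frame_interval Frame interval in ms for the time axis (NULL keeps
#'   frames).
#' @return A ggplot object.
#' @export
plot_trace <- function(trace, step_fit = NULL, frame_interval = NULL) {
  dat <- trace
  xlab <- "frame"
  if (!is.null(frame_interval)) {
    dat <- dat %>% mutate(frame = .data$frame * frame_interval / 1000)
    xlab <- "time (s)"
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$frame, .data$intensity)) +
    ggplot2::geom_line(color = "grey40", linewidth = 0.3) +
    ggplot2::labs(x = xlab, y = "background-subtracted intensity (counts)") +
    ggplot2::theme_minimal()
  if (!is.null(step_fit) && nrow(step_fit) == 1) {
    lev <- as.numeric(strsplit(step_fit$levels, ";")[[1]])
    cp <- strsplit(step_fit$change_points, ";")[[1]]
    cp <- if (identical(cp, "")) integer(0) else as.integer(cp)
    starts <- c(min(trace$frame), cp)
    ends <- c(cp - 1L, max(trace$frame))
    seg <- tibble(x = starts, xend = ends, y = lev)
    if (!is.null(frame_interval)) {
      seg <- seg %>% mutate(x = .data$x * frame_interval / 1000,
                            xend = .data$xend * frame_interval / 1000)
    }
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$y),
      color = "firebrick", linewidth = 0.9, inherit.aes = FALSE)
  }
  p
}

#' Plot an observed bleaching-step histogram
#'
#' @param histogram Tibble with `m` and `count` (see
#'   [aggregate_histogram()]).
#' @param as_fraction Normalize counts to fractions?
#' @return A ggplot object.
#' @export
plot_step_histogram <- function(histogram, as_fraction = TRUE) {
  dat <- histogram
  if (as_fraction && sum(dat$count) > 0) {
    dat <- dat %>% mutate(count = .data$count / sum(.data$count))
  }
  ggplot2::ggplot(dat, ggplot2::aes(factor(.data$m), .data$count)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.7) +
    ggplot2::labs(x = "photobleaching steps",
                  y = if (as_fraction) "fraction of particles" else "count") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pb_report <- function(object, ...) {
  if (is.null(object$correction)) {
    return(plot_step_histogram(object$histogram))
  }
  autoplot(object$correction)
}
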