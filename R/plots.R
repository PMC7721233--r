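#' Plot condition percent-change time courses
#'
#' @param timecourses A tibble combining [percent_change_timecourse()]
#'   results for several conditions (rows bound together).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourses) {
  ggplot2::ggplot(timecourses,
                  ggplot2::aes(x = .data$time_s, y = .data$percent_change,
                               colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time from block onset (s)", y = "BOLD change (%)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.decoding_result <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$test_run),
                               y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_hline(yintercept = object$mean_accuracy,
                        colour = "firebrick") +
    ggplot2::labs(x = "Held-out run", y = "Fold accuracy",
                  title = sprintf("%s vs %s decoding", object$pair[1],
                                  object$pair[2])) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.group_permutation_test <- function(object, ...) {
  df <- tibble(null_value = object$null_values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null_value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick") +
    ggplot2::labs(x = "Group statistic under label permutation",
                  y = "Permutations",
                  title = sprintf("Observed %.3f, p = %.3g", object$observed,
                                  object$p)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rm_anova <- function(object, ...) {
  se <- cousineau_se(object$data)
  ggplot2::ggplot(se, ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey60", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Average BOLD change (%)",
                  subtitle = "Error bars: ±1 within-subject SE") +
    ggplot2::theme_minimal()
}

#' Plot a rendered stimulus frame
#'
#' @param frames A `dot_frames` tibble from [render_block()].
#' @param frame Frame index to draw (default: first frame with dots).
#' @return A ggplot object with dots shaded by direction of motion.
#' @export
plot_frame <- function(frames, frame = NULL) {
  frame <- frame %||% min(frames$frame)
  df <- frames[frames$frame == frame, ]
  geometry <- attr(frames, "geometry") %||% display_geometry()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = .data$y_px,
                                   colour = .data$direction)) +
    ggplot2::geom_point(shape = 15, size = 0.8) +
    ggplot2::coord_fixed(xlim = c(-1, 1) * geometry$resolution_x / 2,
                         ylim = c(-1, 1) * geometry$resolution_y / 2) +
    ggplot2::labs(x = "x (px)", y = "y (px)", colour = "Direction",
                  title = sprintf("%s frame %d",
                                  attr(frames, "condition") %||% "", frame)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
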