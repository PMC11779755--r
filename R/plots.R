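#' Condition means with 95% confidence intervals
#'
#' The standard results panel: mean difference statistic per condition with
#' t-based confidence intervals. Negative values mean drawings resemble the
#' transformed test more than the untransformed test.
#'
#' @param summary a `diff_summary` from [aggregate_diffs()].
#' @return a ggplot object.
#' @export
plot_condition_means <- function(summary) {
  stopifnot(inherits(summary, "diff_summary"))
  g <- summary$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean_diff)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::labs(x = NULL, y = "diff (similarity units)",
                  title = sprintf("Mean diff by %s (95%% CI)",
                                  sub("^by_", "", summary$grouping))) +
    ggplot2::theme_minimal()
}

#' Shape-space map
#'
#' Scatter of a 2D neighbor-embedding projection (see [project_2d()]),
#' typically showing drawings relative to the test and transformed-test
#' anchors.
#'
#' @param xy n x 2 coordinate matrix from [project_2d()].
#' @param labels character vector of point roles, length n.
#' @return a ggplot object.
#' @export
plot_shape_map <- function(xy, labels) {
  d <- data.frame(x = xy[, 1], y = xy[, 2], role = labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$role)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = NULL, color = NULL,
                  title = "Drawings in shape space (2D projection)") +
    ggplot2::theme_minimal()
}
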