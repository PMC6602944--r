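# ggplot2 views of the study artifacts. Plots are optional presentation on
# top of the tibble contract: every panel is drawn from a table the report
# already contains.

#' ICC panel for selected features
#'
#' Dot-and-interval panel of per-feature ICC estimates, coloured by bin
#' width, shaped by normalization mode, with an optional dashed
#' Volume-reference line.
#'
#' @param icc ICC table (typically filtered to one ROI and a feature subset).
#' @param reference Optional reference ICC drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_icc_panel <- function(icc, reference = NULL) {
  p <- ggplot2::ggplot(icc, ggplot2::aes(
    x = .data$feature, y = .data$icc,
    colour = factor(.data$bin_width), shape = .data$normalization)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.6), fatten = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ICC(1,1)", colour = "bin width",
                  shape = "normalization") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    p <- p + ggplot2::geom_hline(yintercept = reference, linetype = "dashed")
  }
  p
}

#' Density of ICC ranges over bin widths
#'
#' Kernel-density view of the per-(feature, filter) ICC range across bin
#' widths (the underlying table is [icc_range_over_binwidths()]).
#'
#' @param ranges Output of [icc_range_over_binwidths()].
#' @return A ggplot object.
#' @export
plot_binwidth_ranges <- function(ranges) {
  ggplot2::ggplot(ranges, ggplot2::aes(x = .data$icc_range)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::labs(x = "ICC range over bin widths", y = "density") +
    ggplot2::theme_minimal()
}

#' Histogram of bin-width ICC ranks
#'
#' @param rank_hist Output of [rank_histogram_over_binwidths()].
#' @return A ggplot object.
#' @export
plot_rank_histogram <- function(rank_hist) {
  ggplot2::ggplot(rank_hist, ggplot2::aes(x = factor(.data$rank),
                                          y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~bin_width, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "ICC rank (1 = best)", y = "feature-filter keys") +
    ggplot2::theme_minimal()
}

#' Filter frequency above the reference
#'
#' @param freq `filter_frequency` table of a report (or the `by_filter`
#'   element of [filter_frequency_above_reference()]).
#' @return A ggplot object.
#' @export
plot_filter_frequency <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = stats::reorder(.data$filter,
                                                        .data$n_features),
                                     y = .data$n_features)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "features above Volume reference") +
    ggplot2::theme_minimal()
}

#' Autoplot a study report
#'
#' @param object A `study_report` from [run_study()].
#' @param which One of `"ranges"`, `"ranks"`, `"filters"`, `"icc"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot study_report
#' @export
autoplot.study_report <- function(object, which = c("ranges", "ranks",
                                                    "filters", "icc"), ...) {
  which <- match.arg(which)
  switch(which,
    ranges = plot_binwidth_ranges(object$binwidth_range),
    ranks = plot_rank_histogram(object$rank_histogram),
    filters = plot_filter_frequency(object$filter_frequency),
    icc = plot_icc_panel(object$icc)
  )
}
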