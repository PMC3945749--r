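# ggplot2 views of experiment results.

#' Accuracy bar chart of an experiment report
#'
#' Per-call accuracy under the four rank-based criteria: all-trials and
#' 80-percent-threshold, each for rank 1 and rank 1+2.
#'
#' @param object An `experiment_report`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  g <- glance.experiment_report(object)
  df <- tibble(
    ranks = rep(c("Rank 1", "Rank 1+2"), each = 2L),
    criterion = rep(c("all trials", ">= 80% of trials"), times = 2L),
    accuracy = 100 * c(g$call_all_rank1, g$call_ge80_rank1,
                       g$call_all_rank12, g$call_ge80_rank12)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ranks, y = .data$accuracy,
                                   fill = .data$criterion)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7, name = NULL) +
    ggplot2::labs(x = NULL, y = "correct matches (%)",
                  title = sprintf("%s / %s", object$feature, object$metric)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Rank-count chart of a full-library analysis
#'
#' Correct matches at ranks 1-3 for each feature representation and metric.
#'
#' @param object A `library_analysis`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.library_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$rank_counts,
    cols = c("rank1", "rank2", "rank3"),
    names_to = "rank", names_prefix = "rank", values_to = "count"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$count,
                                   fill = .data$rank)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~feature) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = -1,
                               name = "rank") +
    ggplot2::labs(x = NULL, y = "correct matches") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
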