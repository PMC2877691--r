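#' Methylation pattern plot (condensed lollipop grid)
#'
#' One tile per clone x CpG site, coloured by call: methylated (black),
#' unmethylated (white), unknown (grey) — the condensed pattern display
#' conventional for clone-level bisulfite data.
#'
#' @param calls A `bs_calls` (or `bs_result`, whose final calls are used).
#' @return A ggplot object.
#' @export
plot_methylation_pattern <- function(calls) {
  if (inherits(calls, "bs_result")) calls <- calls$calls
  stopifnot(inherits(calls, "bs_calls"))
  df <- tidy(calls)
  df$clone_id <- factor(df$clone_id, levels = rev(calls$clone_ids))
  df$position <- factor(df$position, levels = calls$sites)
  df$call <- factor(df$call, levels = c("M", "U", "X"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$clone_id,
                                   fill = .data$call)) +
    ggplot2::geom_tile(colour = "grey40", linewidth = 0.3) +
    ggplot2::scale_fill_manual(
      values = c(M = "black", U = "white", X = "grey75"),
      labels = c(M = "methylated", U = "unmethylated", X = "unknown"),
      drop = FALSE, name = NULL
    ) +
    ggplot2::labs(x = "CpG position (reference)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' Per-site methylation profile plot
#'
#' @param summary A `bs_summary` (or `bs_result`).
#' @return A ggplot object; suppressed sites (fewer informative reads than
#'   the reporting threshold) are omitted.
#' @export
plot_site_profile <- function(summary) {
  if (inherits(summary, "bs_result")) summary <- summary$summary
  stopifnot(inherits(summary, "bs_summary"))
  df <- dplyr::filter(summary$per_site, !is.na(.data$pct_methylated))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$pct_methylated)) +
    ggplot2::geom_col(width = 2, fill = "grey20") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "CpG position (reference)", y = "% methylated") +
    ggplot2::theme_minimal()
}

#' Histogram of methylated-CpG counts per repeat read
#'
#' @param x A `bs_repeat_result` or the `summaries` list from
#'   [repeat_summaries()].
#' @return A ggplot object.
#' @export
plot_repeat_counts <- function(x) {
  if (inherits(x, "bs_repeat_result")) x <- x$summaries
  stopifnot(!is.null(x$histogram))
  ggplot2::ggplot(x$histogram, ggplot2::aes(x = .data$meth_count, y = .data$n_reads)) +
    ggplot2::geom_col(fill = "grey20") +
    ggplot2::labs(x = "methylated CpGs per read", y = "reads") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.bs_calls <- function(object, ...) plot_methylation_pattern(object)

#' @export
autoplot.bs_result <- function(object, ...) plot_methylation_pattern(object)

#' @export
autoplot.bs_repeat_result <- function(object, ...) plot_repeat_counts(object)
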