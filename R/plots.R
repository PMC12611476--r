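#' Plot pathway shares per period
#'
#' Bar chart of the per-pathway share of members with at least one
#' psychotherapeutic service, one panel per period.
#'
#' @param report A `pt_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_pathway_shares <- function(report) {
  stopifnot(inherits(report, "pt_report"))
  df <- dplyr::bind_rows(
    dplyr::mutate(report$pre$pathway_stats$pathways, period = "pre"),
    dplyr::mutate(report$post$pathway_stats$pathways, period = "post")
  ) %>%
    dplyr::mutate(period = factor(.data$period, levels = c("pre", "post")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathway_id, y = .data$share_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~period, scales = "free_x") +
    ggplot2::labs(
      x = "treatment pathway",
      y = "share of members with ≥ 1 pt service (%)",
      title = "Treatment pathway mix by period"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the first-contact to first-therapy gap distribution
#'
#' Overlaid histograms of the contact-to-therapy gap per period, with
#' the period means as dashed lines.
#'
#' @param report A `pt_report` from [run_pipeline()].
#' @param binwidth Histogram bin width in days.
#' @return A ggplot object.
#' @export
plot_interval_distribution <- function(report, binwidth = 14) {
  stopifnot(inherits(report, "pt_report"))
  df <- dplyr::bind_rows(
    dplyr::mutate(report$pre$intervals, period = "pre"),
    dplyr::mutate(report$post$intervals, period = "post")
  ) %>%
    dplyr::mutate(period = factor(.data$period, levels = c("pre", "post")))
  means <- df %>%
    dplyr::group_by(.data$period) %>%
    dplyr::summarise(mean_gap = mean(.data$gap_days), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gap_days, fill = .data$period)) +
    ggplot2::geom_histogram(binwidth = binwidth, alpha = 0.6,
                            position = "identity") +
    ggplot2::geom_vline(data = means,
                        ggplot2::aes(xintercept = .data$mean_gap,
                                     colour = .data$period),
                        linetype = "dashed") +
    ggplot2::labs(x = "days from first contact to first therapy service",
                  y = "members",
                  title = "Time to first therapy service") +
    ggplot2::theme_minimal()
}

#' Cumulative mean timeline along each pathway
#'
#' Step plot of the cumulative mean days (stage durations plus
#' transition gaps, summed over stages 1..k) along each matched
#' pathway, one panel per period.
#'
#' @param report A `pt_report` from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_pathway_timelines <- function(report) {
  stopifnot(inherits(report, "pt_report"))
  df <- dplyr::bind_rows(
    dplyr::mutate(report$pre$pathway_stats$stages, period = "pre"),
    dplyr::mutate(report$post$pathway_stats$stages, period = "post")
  ) %>%
    dplyr::mutate(period = factor(.data$period, levels = c("pre", "post")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$seg_index,
                                   y = .data$cumulative_mean_days,
                                   colour = .data$pathway_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~period) +
    ggplot2::labs(x = "pathway stage", y = "cumulative mean days",
                  colour = "pathway",
                  title = "Cumulative mean timeline along pathways") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot method for pipeline reports
#'
#' @param object A `pt_report`.
#' @param type `"pathways"` (default), `"intervals"` or `"timelines"`.
#' @param ... Passed to the underlying `plot_*` function.
#' @return A ggplot object.
#' @export
autoplot.pt_report <- function(object, type = c("pathways", "intervals", "timelines"),
                               ...) {
  type <- match.arg(type)
  switch(type,
         pathways = plot_pathway_shares(object),
         intervals = plot_interval_distribution(object, ...),
         timelines = plot_pathway_timelines(object))
}
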