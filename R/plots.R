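# Quick-look plots: per-trial traces, acquisition curves, contrast forests.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot normalized eyelid traces averaged per day and genotype
#'
#' @param normalized Tibble from [normalize_cohort()]; CS-only valid trials
#'   are averaged sample-wise per (day, genotype).
#' @return A ggplot.
#' @export
plot_mean_traces <- function(normalized) {
  cs <- dplyr::filter(normalized, .data$trial_type == "CS_ONLY", .data$valid)
  if (nrow(cs) == 0) abort_bad_arg("No valid CS-only trials to plot.")
  df <- cs |>
    dplyr::group_by(.data$day, .data$genotype) |>
    dplyr::summarise(nec = list(Reduce(`+`, .data$nec) / dplyr::n()),
                     fps = .data$fps[1], cs_idx = .data$cs_onset_index[1],
                     .groups = "drop") |>
    tidyr::unnest_longer("nec", values_to = "nec", indices_to = "i")
  df$t_ms <- (df$i - 1 - df$cs_idx) / df$fps * 1000
  ggplot2::ggplot(df, ggplot2::aes(.data$t_ms, .data$nec,
                                   colour = .data$genotype)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~day) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Time after CS onset (ms)",
                  y = "Normalized eye closure")
}

#' Plot an acquisition curve from session summaries
#'
#' @param summaries Tibble from [summarize_sessions()].
#' @param metric Summary column to plot (default `"cr_proportion"`).
#' @return A ggplot of per-day genotype means with SE ribbons.
#' @export
plot_acquisition <- function(summaries, metric = "cr_proportion") {
  if (!metric %in% names(summaries)) {
    abort_bad_arg(sprintf("No summary metric '%s'.", metric))
  }
  df <- summaries |>
    dplyr::group_by(.data$day, .data$genotype) |>
    dplyr::summarise(
      m = mean(.data[[metric]], na.rm = TRUE),
      se = stats::sd(.data[[metric]], na.rm = TRUE) /
        sqrt(sum(!is.na(.data[[metric]]))),
      .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$m,
                                   colour = .data$genotype,
                                   fill = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$se,
                                      ymax = .data$m + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Training day", y = metric)
}

#' Forest plot of per-timepoint genotype contrasts
#'
#' @param object An `ebc_fit`.
#' @param ... Unused.
#' @return A ggplot; estimates with 95% CIs, filled points where the
#'   Holm-adjusted p-value is below 0.05.
#' @export
autoplot.ebc_fit <- function(object, ...) {
  ct <- object$contrasts
  if (is.null(ct) || nrow(ct) == 0) {
    abort_bad_arg("Fit has no contrasts to plot.")
  }
  ct$sig <- ct$p.adjusted < 0.05
  ggplot2::ggplot(ct, ggplot2::aes(.data$estimate, .data$level)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$sig), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16),
                                guide = "none") +
    ggplot2::labs(x = sprintf("%s contrast (link scale)", object$family),
                  y = object$time_var %||% "group")
}
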