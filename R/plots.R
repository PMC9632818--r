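#' Agreement plots
#'
#' Convenience ggplot2 figures for a validation report: a Bland-Altman
#' scatter with bias and limit-of-agreement lines, a regression scatter
#' with the fitted line, and a per-digit RMSE strip chart.  ggplot2 is
#' suggested, not required; these functions error informatively when it
#' is absent.
#'
#' @param report Report list from [aggregate_report()] (or the `report`
#'   element of [run_validation()]'s result).
#' @param activity Activity to plot.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(report, activity) {
  need_ggplot2()
  pairs <- report$ba_pairs[report$ba_pairs$activity == activity, ]
  stats_ <- report$bland_altman[report$bland_altman$activity == activity, ]
  if (!nrow(pairs)) stop("no Bland-Altman pairs for ", activity)
  ggplot2::ggplot(pairs, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = stats_$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = c(stats_$loa_lower, stats_$loa_upper),
                        linetype = 2) +
    ggplot2::labs(x = "Mean TAF of methods (deg)",
                  y = "Markerless - marker-based TAF (deg)",
                  title = paste("Bland-Altman:", activity))
}

#' @rdname plot_bland_altman
#' @export
plot_taf_regression <- function(report, activity) {
  need_ggplot2()
  pairs <- report$ba_pairs[report$ba_pairs$activity == activity, ]
  if (!nrow(pairs)) stop("no TAF pairs for ", activity)
  ggplot2::ggplot(pairs, ggplot2::aes(x = taf_marker, y = taf_markerless)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Marker-based TAF (deg)", y = "Markerless TAF (deg)",
                  title = paste("TAF regression:", activity))
}

#' @rdname plot_bland_altman
#' @param rmse_df Per-series RMSE table (`rmse` element of
#'   [run_validation()]'s result).
#' @export
plot_rmse_by_digit <- function(rmse_df, activity) {
  need_ggplot2()
  df <- rmse_df[rmse_df$activity == activity, ]
  if (!nrow(df)) stop("no RMSE rows for ", activity)
  df$digit <- sub("[-_].*$", "", df$angle_name)
  ggplot2::ggplot(df, ggplot2::aes(x = angle_name, y = rmse,
                                   colour = participant)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = NULL, y = "RMSE (deg)",
                  title = paste("Per-angle RMSE:", activity)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("package 'ggplot2' is required for plotting")
}
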