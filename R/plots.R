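#' Plot a genome scan
#'
#' Draws the per-SNP statistic (points) and its fitted line along each
#' chromosome, with the significance threshold as a dashed line and any
#' called regions shaded. For `statistic = "delta"` the per-marker simulated
#' null bound (and its mirror image) is drawn when present; for
#' `statistic = "ed"` a scalar `threshold` can be supplied.
#'
#' @param object A `bsa_scan` tibble (see [compute_scan()], [fit_scan()]).
#' @param statistic `"delta"` or `"ed"`.
#' @param threshold Optional scalar ED threshold (see [ed_threshold()]).
#' @param regions Optional region tibble to shade.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bsa_scan <- function(object, statistic = c("delta", "ed"),
                              threshold = NULL, regions = NULL, ...) {
  statistic <- match.arg(statistic)
  df <- as_tibble(object)
  raw_col <- if (statistic == "delta") "delta_snp_index" else "ed"
  fit_col <- if (statistic == "delta") "fitted_delta" else "fitted_ed"
  ylab <- if (statistic == "delta") "Δ SNP-index" else
    "ED (fitted: powered + smoothed)"

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[raw_col]]),
                        colour = "grey70", size = 0.4, alpha = 0.6)
  if (!is.null(regions) && nrow(regions) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(regions),
      ggplot2::aes(xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "goldenrod", alpha = 0.25)
  }
  if (fit_col %in% names(df))
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data[[fit_col]]),
                                colour = "steelblue", linewidth = 0.6,
                                na.rm = TRUE)
  if (statistic == "delta" && "ci95" %in% names(df)) {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$ci95), colour = "firebrick",
                         linetype = "dashed", linewidth = 0.3) +
      ggplot2::geom_line(ggplot2::aes(y = -.data$ci95), colour = "firebrick",
                         linetype = "dashed", linewidth = 0.3)
  }
  if (statistic == "ed" && !is.null(threshold))
    p <- p + ggplot2::geom_hline(yintercept = threshold, colour = "firebrick",
                                 linetype = "dashed", linewidth = 0.3)
  p +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = ylab) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.bsa_scan
#' @param scan A `bsa_scan` tibble.
#' @export
plot_scan <- function(scan, statistic = c("delta", "ed"), threshold = NULL,
                      regions = NULL) {
  autoplot.bsa_scan(scan, statistic = statistic, threshold = threshold,
                    regions = regions)
}
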