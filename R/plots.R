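#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chromosome-ratio threshold sweep
#'
#' Point estimates with bootstrap CI bars against the minimum-expression
#' threshold, colored by ratio type and faceted by sex or contrast — the
#' standard view for judging whether X:A ratios sit inside the chr3:2
#' natural-variation band.
#'
#' @param object Output of [ratio_sweep()] or [mf_sweep()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.xa_ratio_sweep <- function(object, ...) {
  d <- dplyr::filter(object, is.finite(.data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$estimate,
                                  color = .data$ratio_type)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.1, na.rm = TRUE) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$sex_or_contrast)) +
    ggplot2::labs(x = "minimum expression threshold (RPKM)",
                  y = "ratio of median expression", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window profile of the X chromosome
#'
#' For [window_xa()] output, the window X:A ratio along the chromosome (gaps
#' where too few genes are expressed); for [window_density()] output, gene
#' counts per window, one line per threshold.
#'
#' @param object Output of [window_xa()] or [window_density()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.xa_window_profile <- function(object, ...) {
  mid <- (object$window_start + object$window_end) / 2
  if ("window_xa_ratio" %in% names(object)) {
    ggplot2::ggplot(dplyr::mutate(object, mid = mid),
                    ggplot2::aes(x = .data$mid / 1e6, y = .data$window_xa_ratio)) +
      ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey60") +
      ggplot2::geom_line(na.rm = TRUE) +
      ggplot2::labs(x = "position (Mb)", y = "window X:A ratio") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dplyr::mutate(object, mid = mid),
                    ggplot2::aes(x = .data$mid / 1e6, y = .data$n_genes,
                                 color = factor(.data$threshold))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "position (Mb)", y = "genes in window",
                    color = "RPKM threshold") +
      ggplot2::theme_minimal()
  }
}

#' Histogram of per-gene male:female ratios, X versus autosomes
#'
#' Bins per-gene male:female expression ratios (default 0.02-wide bins) for
#' X-linked and autosomal genes separately; a peak at 1.0 indicates equal
#' expression in both sexes, and a left shift of the X panel relative to the
#' autosomal one indicates female bias of the X.
#'
#' @param records Output of [mf_gene_ratios()].
#' @param threshold Minimum mean expression for inclusion.
#' @param bin_width Bin width on the ratio scale.
#' @param max_ratio Upper display limit on the ratio axis.
#' @return A ggplot object.
#' @export
plot_mf_histogram <- function(records, threshold = 0, bin_width = 0.02,
                              max_ratio = 3) {
  d <- dplyr::bind_rows(
    dplyr::mutate(ratio_histogram(records, "X", threshold, bin_width),
                  location = "X"),
    dplyr::mutate(ratio_histogram(records, c("chr2", "chr3"), threshold, bin_width),
                  location = "autosomes"))
  d <- dplyr::filter(d, .data$bin_start <= max_ratio)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_start + bin_width / 2,
                                  y = .data$n)) +
    ggplot2::geom_col(width = bin_width) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", color = "grey40") +
    ggplot2::facet_wrap(ggplot2::vars(.data$location), scales = "free_y") +
    ggplot2::labs(x = "male : female expression ratio", y = "genes") +
    ggplot2::theme_minimal()
}
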