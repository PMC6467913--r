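# ggplot2 visualisations for the main result types.

#' Plot a Strand-seq scan
#'
#' Read-ratio track of the candidate loci along each chromosome, coloured by
#' class; the dashed lines mark the heterozygous (0.5) and homozygous (1)
#' expectations.
#'
#' @param object A `strandseq_scan` from [call_inversions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strandseq_scan <- function(object, ...) {
  calls <- object$calls
  ggplot2::ggplot(calls) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$start, xend = .data$end, y = .data$read_ratio,
      yend = .data$read_ratio, colour = .data$cls), linewidth = 2) +
    ggplot2::geom_hline(yintercept = c(0.5, 1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1) +
    ggplot2::labs(x = "position (bp)", y = "read ratio (non-reference)",
                  colour = "class") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Sensitivity/specificity trade-off of caller combinations
#'
#' Call count against non-concordance rate for every evaluated combination,
#' with reference lines at 5% and 10% NCR.
#'
#' @param x A `combination_result` from [evaluate_combinations()].
#' @param ncr_lines NCR reference levels to draw.
#' @return A ggplot object.
#' @export
plot_combination_ncr <- function(x, ncr_lines = c(0.05, 0.10)) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$n_calls, y = .data$ncr,
                                  shape = .data$mode)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = ncr_lines,
                        linetype = c("solid", "dashed"), colour = "grey50") +
    ggplot2::labs(x = "calls in merged set", y = "non-concordance rate",
                  shape = "combination mode") +
    ggplot2::theme_minimal()
}

#' Size distribution of unified inversions by platform support
#'
#' @param unified Unified-inversion tibble from [unify_inversions()].
#' @return A ggplot object.
#' @export
plot_inversion_sizes <- function(unified) {
  df <- unified |>
    mutate(size = .data$invr_end - .data$invr_start,
           n_platforms = purrr::map_int(.data$platforms, length))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size,
                                   fill = factor(.data$n_platforms))) +
    ggplot2::geom_histogram(bins = 20) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "inversion size (bp)", y = "count",
                  fill = "platforms") +
    ggplot2::theme_minimal()
}
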