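#' Plot the span distribution of a library
#'
#' Histogram of concordant PET spans — the empirical insert-size
#' distribution after size selection.
#'
#' @param object A `pet_spans` object from [span_stats()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pet_spans <- function(object, ...) {
  h <- object$histogram[object$histogram$count > 0, , drop = FALSE]
  ggplot2::ggplot(h, ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = h$bin_end[1] - h$bin_start[1],
                      fill = "steelblue") +
    ggplot2::geom_vline(xintercept = object$median, linetype = 2) +
    ggplot2::labs(x = "PET span (bp)", y = "PETs",
                  title = sprintf("%s library span distribution (median %.0f bp)",
                                  object$library, object$median)) +
    ggplot2::theme_minimal()
}

#' Plot a physical coverage track
#'
#' Copy-number profile per chromosome from binned concordant-fragment
#' coverage.
#'
#' @param object A [coverage_track()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.coverage_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start / 1e6,
                                       y = .data$copy_number)) +
    ggplot2::geom_step(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 2, linetype = 3) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "copy number") +
    ggplot2::theme_minimal()
}

#' Span distribution of SV calls by category
#'
#' Counts of intra-chromosomal SVs per type across logarithmic span bins
#' (the standard way to contrast what different insert sizes detect).
#'
#' @param calls SV call tibble.
#' @return A ggplot.
#' @export
plot_sv_spans <- function(calls) {
  df <- calls %>%
    filter(!is.na(.data$span) & .data$span > 0) %>%
    mutate(span_bin = cut(.data$span,
                          breaks = c(0, 5e3, 2e4, 1e5, 5e5, Inf),
                          labels = c("<5k", "5-20k", "20-100k", "100-500k",
                                     ">500k")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$span_bin)) +
    ggplot2::geom_bar(fill = "firebrick") +
    ggplot2::facet_wrap(~sv_type) +
    ggplot2::labs(x = "SV span", y = "calls") +
    ggplot2::theme_minimal()
}

#' Supercluster count histogram
#'
#' @param superclusters Membership tibble from [build_superclusters()].
#' @return A ggplot.
#' @export
plot_supercluster_histogram <- function(superclusters) {
  h <- supercluster_histogram(superclusters)
  ggplot2::ggplot(h, ggplot2::aes(x = factor(.data$supercluster_count),
                                  y = .data$n_superclusters)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "supercluster count", y = "superclusters") +
    ggplot2::theme_minimal()
}
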