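#' Plot the top sub-ontology roots by FDR
#'
#' Horizontal bar chart of `-log10(FDR)` for the best-ranked roots, the
#' quick look at which functional modules separate cases from controls.
#'
#' @param object A `subgofa_result`.
#' @param n_top Number of roots shown.
#' @param fdr_threshold Reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subgofa_result <- function(object, n_top = 20L, fdr_threshold = 0.05, ...) {
  df <- tidy(object)
  df <- head(filter(df, .data$status == "tested"), n_top)
  df$label <- paste0(df$root, " (", df$root_name, ")")
  ggplot2::ggplot(df, ggplot2::aes(
      x = -log10(pmax(.data$fdr, 1e-300)),
      y = stats::reorder(.data$label, -.data$fdr))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = -log10(fdr_threshold), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL,
                  title = "Sub-ontology roots separating cases from controls") +
    ggplot2::theme_minimal()
}

#' Plot a detection-ratio threshold sweep
#'
#' One line per method: detection ratio of disease-list genes as the
#' significance threshold varies. Methods with empty selections (`NA`
#' ratio) simply drop those points, mirroring a "not applicable" outcome.
#'
#' @param sweep Tibble from [threshold_sweep()].
#' @return A ggplot object.
#' @export
plot_detection_sweep <- function(sweep) {
  ggplot2::ggplot(filter(sweep, !is.na(.data$ratio)),
    ggplot2::aes(x = .data$threshold, y = .data$ratio, colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("threshold (", sweep$mode[1], ")"),
                  y = "detection ratio", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the sample-frequency distribution of significant terms
#'
#' Histogram (fixed-width bins) with a density overlay of how many samples
#' carry each significant term. Mass in the low bins means the method is
#' retaining rare functions.
#'
#' @param dist Tibble from [term_frequency_distribution()], or a named
#'   list of them for side-by-side comparison.
#' @param bin_width Bin width in samples (should match the distribution).
#' @return A ggplot object.
#' @export
plot_term_frequency <- function(dist, bin_width = 20L) {
  if (is.data.frame(dist)) dist <- list(result = dist)
  df <- bind_rows(lapply(names(dist), function(m) mutate(dist[[m]], method = m)))
  if (nrow(df) == 0L) abort("no significant terms to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_samples, fill = .data$method,
                                   colour = .data$method)) +
    ggplot2::geom_histogram(binwidth = bin_width, boundary = 0,
                            position = "identity", alpha = 0.4) +
    ggplot2::geom_density(ggplot2::aes(y = ggplot2::after_stat(.data$count) * bin_width),
                          fill = NA) +
    ggplot2::labs(x = "samples carrying the term", y = "terms") +
    ggplot2::theme_minimal()
}
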