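#' @method autoplot uvclap_ma
#' @export
autoplot.uvclap_ma <- function(object, ...) {
  libs <- attr(object, "libraries")
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$mean_log2, y = .data$log2fc)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.6) +
    ggplot2::geom_hline(yintercept = attr(object, "median_log2fc"),
                        colour = "blue") +
    ggplot2::labs(
      x = "mean log2 event count",
      y = sprintf("log2 fold change (%s / %s)", libs[["a"]], libs[["b"]]),
      title = "Replicate MA plot",
      subtitle = sprintf("median log2 fold change %.3f",
                         attr(object, "median_log2fc"))
    )
}

#' @method autoplot uvclap_profile
#' @export
autoplot.uvclap_profile <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$distance, y = .data$count)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance to exon-exon junction (nt, transcript direction)",
                  y = "crosslinking events",
                  title = "Junction metaprofile")
}

#' Duplication-by-length diagnostic plot
#'
#' Read and event counts per alignment-length bin with the duplicate
#' fraction overlaid, the standard diagnostic for length-biased PCR
#' amplification.
#'
#' @param dup Table from [duplication_by_length()].
#' @return A ggplot object.
#' @export
plot_duplication <- function(dup) {
  long <- tidyr::pivot_longer(dup, c("reads", "events"),
                              names_to = "unit", values_to = "n")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$length_bin, y = .data$n,
                                     fill = .data$unit)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6, width = 1) +
    ggplot2::labs(x = "alignment length (nt)", y = "count",
                  fill = NULL, title = "Reads vs events by cDNA length")
}

#' Target-class composition plot
#'
#' Bar chart of peak counts per genomic target class in priority order.
#'
#' @param assigned Peaks with a `target_class` column
#'   ([assign_target_class()]).
#' @return A ggplot object.
#' @export
plot_target_classes <- function(assigned) {
  ggplot2::ggplot(assigned, ggplot2::aes(x = .data$target_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "peaks",
                  title = "Peaks per genomic target class") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
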