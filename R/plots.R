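#' Plot an FST track with called segments
#'
#' Raw per-site FST as points, the smoothed spline as a line, optional
#' called segments as shaded rectangles, faceted by chromosome.
#'
#' @param object An `fst_track` (from [fst_scan()]).
#' @param segments Optional segment tibble from [call_segments()].
#' @param threshold Optional horizontal threshold line.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.fst_track <- function(object, segments = NULL, threshold = NULL,
                               ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$raw_fst),
                        size = 0.3, alpha = 0.3, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed_fst),
                       colour = "#1f6fb4", linewidth = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(F[ST])) +
    ggplot2::theme_minimal()
  if (!is.null(segments) && nrow(segments)) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6),
      ymin = -Inf, ymax = Inf, inherit.aes = FALSE,
      fill = "#2b6cb0", alpha = 0.15)
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Plot assortative-mating percentages from an assay summary
#'
#' Bar chart of the percentage of assortative matings per replicate and
#' mating combination (see [summarize_assay()]).
#'
#' @param summary Output of [summarize_assay()].
#' @return A ggplot object.
#' @export
plot_mating_summary <- function(summary) {
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = interaction(.data$chooser, .data$replicate, sep = " / "),
                 y = .data$pct_assortative, fill = .data$chooser)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 50, linetype = 2) +
    ggplot2::labs(x = "chooser genotype / replicate",
                  y = "% assortative mating") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the introgressed-ancestry structure of simulated strains
#'
#' Horizontal bars of ancestry blocks along the X chromosome for each
#' individual, coloured by M/S origin.
#'
#' @param object An `introgression_sim` (from
#'   [run_introgression_design()]).
#' @param strain `"rbss"` or `"rbmm"`.
#' @param n_individuals How many individuals to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.introgression_sim <- function(object, strain = "rbss",
                                       n_individuals = 20, ...) {
  inds <- object[[strain]][seq_len(min(n_individuals, length(object[[strain]])))]
  blocks <- strain_blocks(inds, prefix = toupper(strain)) |>
    filter(.data$chrom == "X")
  ggplot2::ggplot(blocks) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start / 1e6, xend = .data$end / 1e6,
                   y = interaction(.data$individual_id, .data$haplotype),
                   yend = interaction(.data$individual_id, .data$haplotype),
                   colour = .data$origin),
      linewidth = 2) +
    ggplot2::scale_colour_manual(values = c(M = "#d95f02", S = "#1b9e77")) +
    ggplot2::labs(x = "X position (Mb)", y = NULL, colour = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
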