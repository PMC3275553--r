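#' Plot allele share against chromosome length share
#'
#' Scatter of each chromosome's percentage of alleles against its
#' percentage of the genome; proportional insertion lands on the diagonal.
#'
#' @param x A `mos_chrom_dist` from [chromosome_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot mos_chrom_dist
#' @export
autoplot.mos_chrom_dist <- function(x, ...) {
  ggplot2::ggplot(tibble::as_tibble(x),
                  ggplot2::aes(.data$length_pct, .data$allele_pct)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$chrom),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      x = "chromosome length (% of genome)",
      y = "alleles (% of collection)",
      title = "Chromosome share of insertions vs length",
      subtitle = sprintf("chi-square GoF p = %.3g", attr(x, "p_value"))
    )
}

#' Plot the cumulative distribution of inter-allele gaps
#'
#' Cumulative percentage of nearest-neighbour gaps below each distance,
#' on a log distance axis.
#'
#' @param x A `mos_gap_stats` from [gap_statistics()].
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @method autoplot mos_gap_stats
#' @export
autoplot.mos_gap_stats <- function(x, ...) {
  ggplot2::ggplot(x$gaps, ggplot2::aes(.data$gap)) +
    ggplot2::stat_ecdf(ggplot2::aes(y = ggplot2::after_stat(y) * 100)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance to next allele (bp)",
                  y = "cumulative % of gaps",
                  title = "Nearest-neighbour gap distribution")
}

#' Plot genome coverage by merged contigs
#'
#' One horizontal track per chromosome with the merged reachable intervals
#' drawn as segments — a desk-scale rendering of the genome-coverage
#' ideogram.
#'
#' @param contigs Output of [merge_windows()].
#' @param dataset The `mos_dataset`.
#' @return A ggplot.
#' @export
plot_genome_coverage <- function(contigs, dataset) {
  chroms <- dataset$chroms
  chroms$chrom <- factor(chroms$chrom, levels = rev(chroms$chrom))
  ctg <- contigs
  ctg$chrom <- factor(ctg$chrom, levels = levels(chroms$chrom))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = chroms,
      ggplot2::aes(x = 1, xend = .data$length, y = .data$chrom,
                   yend = .data$chrom),
      linewidth = 1, colour = "grey80") +
    ggplot2::geom_segment(
      data = ctg,
      ggplot2::aes(x = .data$start, xend = .data$end, y = .data$chrom,
                   yend = .data$chrom),
      linewidth = 4, colour = "firebrick") +
    ggplot2::labs(x = "position (bp)", y = NULL,
                  title = "Regions reachable from an insertion allele")
}
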