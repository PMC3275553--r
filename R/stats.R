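#' Per-chromosome distribution of alleles versus chromosome length
#'
#' Tests whether insertions land on each chromosome in proportion to its
#' length, as observed for the full Mos1 collection. Expected counts are
#' proportional to chromosome length; the goodness-of-fit chi-square has
#' `n_chrom - 1` degrees of freedom.
#'
#' @param alleles Allele tibble (normally the unique set).
#' @param dataset A `mos_dataset` (supplies chromosome lengths).
#' @return A tibble of class `mos_chrom_dist` with columns `chrom`,
#'   `length`, `n_alleles`, `length_pct`, `allele_pct`; the chi-square
#'   result is attached as attributes (`statistic`, `df`, `p_value`) and
#'   available via [generics::glance()].
#' @export
chromosome_distribution <- function(alleles, dataset) {
  if (nrow(alleles) == 0) stop("no alleles", call. = FALSE)
  if (sum(dataset$chroms$length) == 0) stop("zero-length genome", call. = FALSE)
  tbl <- dataset$chroms |>
    dplyr::left_join(dplyr::count(alleles, .data$chrom, name = "n_alleles"),
                     by = "chrom") |>
    dplyr::mutate(
      n_alleles = dplyr::coalesce(.data$n_alleles, 0L),
      length_pct = 100 * .data$length / sum(.data$length),
      allele_pct = 100 * .data$n_alleles / sum(.data$n_alleles)
    )
  if (nrow(tbl) == 1) {
    stat <- 0; df <- 0L; p <- 1
  } else {
    ct <- suppressWarnings(
      stats::chisq.test(tbl$n_alleles, p = tbl$length / sum(tbl$length)))
    stat <- unname(ct$statistic); df <- unname(ct$parameter); p <- ct$p.value
  }
  structure(tbl, class = c("mos_chrom_dist", class(tbl)),
            statistic = stat, df = df, p_value = p)
}

#' @importFrom generics glance
#' @method glance mos_chrom_dist
#' @export
glance.mos_chrom_dist <- function(x, ...) {
  tibble::tibble(
    statistic = attr(x, "statistic"),
    df = attr(x, "df"),
    p_value = attr(x, "p_value")
  )
}

#' Nearest-neighbour gap statistics
#'
#' Distances from each allele to the next in the 5' to 3' direction along
#' each chromosome. Gaps are pooled across chromosomes for the mean; a
#' chromosome with fewer than two alleles contributes no gaps. For the
#' published non-redundant collection the pooled mean is 9,230 bp, with
#' 33%, 67% and 95% of gaps below 3.2, 10 and 30 kb.
#'
#' @param alleles Allele tibble (normally the unique set).
#' @return Object of class `mos_gap_stats`: `gaps` tibble (`chrom`, `gap`),
#'   `mean_gap`, `max_gap`, `n_gaps` (`mean_gap`/`max_gap` are `NA` when
#'   there are no gaps). [gap_fraction_below()] gives cumulative fractions;
#'   [generics::tidy()] returns the gaps, [generics::glance()] the summary.
#' @export
gap_statistics <- function(alleles) {
  gaps <- alleles |>
    dplyr::arrange(.data$chrom, .data$position) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(gap = dplyr::lead(.data$position) - .data$position) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$gap)) |>
    dplyr::select("chrom", "gap")
  structure(list(
    gaps = gaps,
    mean_gap = if (nrow(gaps) == 0) NA_real_ else mean(gaps$gap),
    max_gap = if (nrow(gaps) == 0) NA_integer_ else max(gaps$gap),
    n_gaps = nrow(gaps)
  ), class = "mos_gap_stats")
}

#' @rdname gap_statistics
#' @param x A `mos_gap_stats`.
#' @param threshold Gap threshold(s) in bp; the comparison is strict
#'   (`gap < threshold`).
#' @return For `gap_fraction_below()`: percentage(s) of gaps below each
#'   threshold.
#' @export
gap_fraction_below <- function(x, threshold) {
  vapply(threshold, function(t) 100 * mean(x$gaps$gap < t), numeric(1))
}

#' @export
print.mos_gap_stats <- function(x, ...) {
  cat("<mos_gap_stats>\n")
  if (x$n_gaps == 0) {
    cat("  no gaps (fewer than 2 alleles per chromosome)\n")
  } else {
    cat(sprintf("  %d gaps; mean %.0f bp; max %d bp\n",
                x$n_gaps, x$mean_gap, x$max_gap))
    cat(sprintf("  %% below 3.2/10/30 kb: %.1f / %.1f / %.1f\n",
                gap_fraction_below(x, 3200), gap_fraction_below(x, 10000),
                gap_fraction_below(x, 30000)))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy mos_gap_stats
#' @export
tidy.mos_gap_stats <- function(x, ...) x$gaps

#' @importFrom generics glance
#' @method glance mos_gap_stats
#' @export
glance.mos_gap_stats <- function(x, ...) {
  tibble::tibble(n_gaps = x$n_gaps, mean_gap = x$mean_gap,
                 max_gap = x$max_gap)
}

#' Coding-sequence context fractions
#'
#' An insertion counts as in-CDS iff at least one base of its 2-bp TA span
#' lies in the merged CDS union; the genome baseline is the CDS fraction of
#' total genome length, and the motif baseline is the fraction of motif
#' occurrences (default the TA insertion target; `motifs = c("TA", "AT")`
#' is also meaningful) with at least one base in CDS. Comparing the three
#' percentages asks whether insertions show any intragenic/intergenic
#' preference beyond the availability of their target site.
#'
#' @param alleles Allele tibble.
#' @param dataset A `mos_dataset` with sequences and CDS annotation.
#' @param motifs Character vector of dinucleotide (or longer) motifs.
#' @return One-row tibble: `insertions_in_cds_pct`, `genome_cds_pct`,
#'   `motif_in_cds_pct`, `n_insertions`, `n_motif_sites`.
#' @export
context_fractions <- function(alleles, dataset, motifs = "TA") {
  cu <- cds_union(dataset)
  cu_gr <- intervals_to_granges(cu)
  genome_cds_pct <- 100 * attr(cu, "genome_cds_fraction")

  ins_pct <- if (nrow(alleles) == 0) 0 else {
    hits <- GenomicRanges::countOverlaps(alleles_to_granges(alleles), cu_gr)
    100 * mean(hits > 0)
  }

  motif_pos <- purrr::map_dfr(motifs, function(m) {
    purrr::imap_dfr(
      stats::setNames(seq_along(dataset$seqs), names(dataset$seqs)),
      function(i, chrom) {
        st <- BiocGenerics::start(
          Biostrings::matchPattern(m, dataset$seqs[[i]]))
        tibble::tibble(chrom = chrom, start = as.integer(st),
                       end = as.integer(st) + nchar(m) - 1L)
      })
  })
  motif_pct <- if (nrow(motif_pos) == 0) 0 else {
    hits <- GenomicRanges::countOverlaps(intervals_to_granges(motif_pos), cu_gr)
    100 * mean(hits > 0)
  }

  tibble::tibble(
    insertions_in_cds_pct = ins_pct,
    genome_cds_pct = genome_cds_pct,
    motif_in_cds_pct = motif_pct,
    n_insertions = nrow(alleles),
    n_motif_sites = nrow(motif_pos)
  )
}

#' Exact binomial test for gene-set enrichment
#'
#' Two-sided exact binomial test of whether a gene subset (e.g.
#' germline-expressed genes) contains insertion-hit genes more or less
#' often than expected by chance. The null proportion is
#' `hit_genes_n / gene_universe_n`; the p-value sums the probabilities of
#' all outcomes no more likely than the observed one,
#' `p = sum over j of P(j) for P(j) <= P(k)`.
#'
#' @param gene_universe_n Size of the gene universe.
#' @param hit_genes_n Genes in the universe containing an insertion.
#' @param subset_n Size of the queried subset.
#' @param subset_hits_n Subset genes containing an insertion.
#' @return Object of class `mos_binom`: `n`, `k`, `p0`, `expected`,
#'   `observed_pct`, `p_value`; [generics::tidy()]/[generics::glance()]
#'   return it as a one-row tibble.
#' @examples
#' # the collection's germline test: 74 of 373 germline genes hit, against
#' # 4,586 hit protein-coding genes out of 20,414
#' germline_enrichment(20414, 4586, 373, 74)
#' @export
germline_enrichment <- function(gene_universe_n, hit_genes_n,
                                subset_n, subset_hits_n) {
  if (hit_genes_n > gene_universe_n || subset_hits_n > subset_n ||
      min(gene_universe_n, hit_genes_n, subset_n, subset_hits_n) < 0 ||
      gene_universe_n == 0 || subset_n == 0) {
    stop("invalid counts for the binomial test", call. = FALSE)
  }
  p0 <- hit_genes_n / gene_universe_n
  structure(list(
    n = as.integer(subset_n),
    k = as.integer(subset_hits_n),
    p0 = p0,
    expected = subset_n * p0,
    observed_pct = 100 * subset_hits_n / subset_n,
    p_value = binom_two_sided(subset_hits_n, subset_n, p0)
  ), class = "mos_binom")
}

# Exact two-sided binomial p-value: total probability of outcomes no more
# likely than the observed count (with the customary 1 + 1e-7 relative
# tolerance for floating-point ties).
binom_two_sided <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1] * (1 + 1e-7)]))
}

#' @export
print.mos_binom <- function(x, ...) {
  cat("<mos_binom> exact two-sided binomial test\n")
  cat(sprintf("  observed %d / %d (%.1f%%); expected %.1f under p0 = %.4f\n",
              x$k, x$n, x$observed_pct, x$expected, x$p0))
  cat(sprintf("  p-value = %.4g\n", x$p_value))
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy mos_binom
#' @export
tidy.mos_binom <- function(x, ...) {
  tibble::tibble(n = x$n, k = x$k, p0 = x$p0, expected = x$expected,
                 observed_pct = x$observed_pct, p_value = x$p_value)
}

#' @importFrom generics glance
#' @method glance mos_binom
#' @export
glance.mos_binom <- function(x, ...) tidy(x)
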