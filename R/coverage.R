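#' Merge flanking windows around alleles into contigs
#'
#' MosTIC gene conversion can modify targets up to ~1.5 kb from an
#' insertion, so each allele defines a reachable window of `flank` bp on
#' either side of its 2-bp TA span, clamped to the chromosome. Overlapping
#' or bookended (end + 1 == next start) windows are merged, giving maximal
#' contiguous reachable intervals.
#'
#' @param alleles Allele tibble (normally the unique set).
#' @param dataset A `mos_dataset`.
#' @param flank Window half-width in bp (default 1500).
#' @return Tibble of contigs: `chrom`, `start`, `end`, `n_alleles`,
#'   `members` (list-column of allele names), sorted and disjoint per
#'   chromosome.
#' @examples
#' ds <- mos_dataset(chrom_lengths = c(I = 10000))
#' al <- tibble::tibble(allele_name = c("ttTi1", "ttTi2"),
#'   allele_number = 1:2, chrom = "I", position = c(1000L, 3500L),
#'   precise = TRUE, strain_id = NA_character_, plate_id = NA_character_)
#' merge_windows(al, ds)  # windows [1,2501] and [2000,5001] merge
#' @export
merge_windows <- function(alleles, dataset, flank = 1500L) {
  if (nrow(alleles) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_alleles = integer(),
                          members = list()))
  }
  len <- stats::setNames(dataset$chroms$length, dataset$chroms$chrom)
  win <- tibble::tibble(
    chrom = alleles$chrom,
    start = pmax(1L, alleles$position - as.integer(flank)),
    end = pmin(len[alleles$chrom], alleles$position + 1L + as.integer(flank)),
    allele_name = alleles$allele_name
  )
  win_gr <- intervals_to_granges(win)
  contigs <- GenomicRanges::reduce(win_gr)  # merges overlapping + bookended
  hit <- GenomicRanges::findOverlaps(win_gr, contigs)
  members <- split(win$allele_name[S4Vectors::queryHits(hit)],
                   S4Vectors::subjectHits(hit))
  out <- granges_to_tibble(contigs)
  out$n_alleles <- lengths(members)[as.character(seq_len(nrow(out)))]
  out$members <- members[as.character(seq_len(nrow(out)))]
  dplyr::arrange(out, match(.data$chrom, dataset$chroms$chrom), .data$start)
}

#' MosTIC coverage table
#'
#' Counts, per chromosome, the protein-coding genes whose span is contained
#' within or overlaps (by at least 1 bp) a merged allele contig — the genes
#' reachable by MosTIC from the collection. A totals row sums the counts
#' and recomputes the percentage.
#'
#' @param contigs Output of [merge_windows()].
#' @param dataset A `mos_dataset` with annotation.
#' @return Tibble with one row per chromosome plus a `Total` row: `chrom`,
#'   `length`, `n_protein_coding_genes`, `n_alleles`, `n_genes_within`,
#'   `pct_within` (1 decimal).
#' @export
coverage_table <- function(contigs, dataset) {
  genes <- dplyr::filter(dataset$genes, .data$biotype == "protein_coding")
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  n_within <- if (nrow(genes) == 0 || nrow(contigs) == 0) {
    stats::setNames(integer(0), character(0))
  } else {
    hit <- GenomicRanges::countOverlaps(gene_gr, intervals_to_granges(contigs),
                                        minoverlap = 1L)
    tapply(hit > 0, genes$chrom, sum)
  }
  counts <- dataset$chroms |>
    dplyr::mutate(
      n_protein_coding_genes = dplyr::coalesce(
        as.integer(table(genes$chrom)[.data$chrom]), 0L),
      n_alleles = dplyr::coalesce(
        as.integer(tapply(contigs$n_alleles, contigs$chrom, sum)[.data$chrom]), 0L),
      n_genes_within = dplyr::coalesce(as.integer(n_within[.data$chrom]), 0L)
    )
  coverage_percentages(counts)
}

#' Percentage columns and totals row for a coverage table
#'
#' Separated from [coverage_table()] so that the same arithmetic can be
#' applied to externally supplied per-chromosome counts (e.g. the published
#' genome-wide distribution table): adds the per-chromosome allele share
#' and the percentage of genes within reach, then appends a totals row in
#' which both are recomputed from the column sums.
#'
#' @param counts Tibble with columns `chrom`, `length`,
#'   `n_protein_coding_genes`, `n_alleles`, `n_genes_within`.
#' @return The table with `length_pct`, `allele_pct` and `pct_within`
#'   columns (1 decimal) and a final `Total` row.
#' @export
coverage_percentages <- function(counts) {
  tot <- tibble::tibble(
    chrom = "Total",
    length = sum(counts$length),
    n_protein_coding_genes = sum(counts$n_protein_coding_genes),
    n_alleles = sum(counts$n_alleles),
    n_genes_within = sum(counts$n_genes_within)
  )
  dplyr::bind_rows(counts, tot) |>
    dplyr::mutate(
      length_pct = round(100 * .data$length / tot$length, 1),
      allele_pct = round(100 * .data$n_alleles / tot$n_alleles, 1),
      pct_within = round(100 * .data$n_genes_within /
                           .data$n_protein_coding_genes, 1)
    )
}

#' Write contigs as BED
#'
#' BED uses 0-based, half-open coordinates; the 1-based closed contig
#' intervals are converted on write.
#'
#' @param contigs Output of [merge_windows()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_contigs_bed <- function(contigs, path) {
  bed <- tibble::tibble(
    chrom = contigs$chrom,
    start = contigs$start - 1L,
    end = contigs$end,
    name = vapply(contigs$members, function(m) paste(m, collapse = ","),
                  character(1))
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
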