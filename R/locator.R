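#' Find alleles within and near query genes
#'
#' Batch gene-proximity query over the allele table: for each query
#' identifier (gene sequence name first, transcript name second), counts
#' the alleles whose 2-bp TA span overlaps the gene span and those within
#' `distance` bp of it (span extended by `distance` on both sides). With
#' `exon_only = TRUE` the same tests run against the gene's exon intervals
#' instead of its span. Unresolved identifiers yield a row with
#' `resolved_gene = "not found"` and do not abort the batch.
#'
#' @param gene_ids Character vector of gene sequence or transcript names.
#' @param dataset A `mos_dataset` with annotation and alleles.
#' @param distance Proximity distance in bp (default 1500).
#' @param exon_only Restrict to (the neighbourhood of) exons.
#' @param alleles Optional allele tibble; defaults to `dataset$alleles`.
#' @return Tibble with one row per query: `query`, `resolved_gene`,
#'   `n_within_gene`, `n_within_distance`, `alleles_within_gene`,
#'   `alleles_within_distance` (list-columns of allele names).
#' @export
locate_alleles <- function(gene_ids, dataset, distance = 1500L,
                           exon_only = FALSE, alleles = NULL) {
  stopifnot(distance >= 0)
  alleles <- alleles %||% dataset$alleles
  al_gr <- alleles_to_granges(alleles)
  purrr::map_dfr(gene_ids, function(q) {
    gid <- if (q %in% dataset$genes$gene_id) {
      q
    } else if (q %in% dataset$transcripts$transcript_id) {
      dataset$transcripts$gene_id[match(q, dataset$transcripts$transcript_id)]
    } else {
      NA_character_
    }
    if (is.na(gid)) {
      return(tibble::tibble(
        query = q, resolved_gene = "not found",
        n_within_gene = NA_integer_, n_within_distance = NA_integer_,
        alleles_within_gene = list(character(0)),
        alleles_within_distance = list(character(0))
      ))
    }
    g <- dataset$genes[dataset$genes$gene_id == gid, ]
    iv <- if (exon_only) {
      ex <- dataset$exons[dataset$exons$gene_id == gid, ]
      if (nrow(ex) == 0) g[, c("chrom", "start", "end")] else
        ex[, c("chrom", "start", "end")]
    } else {
      g[, c("chrom", "start", "end")]
    }
    within <- overlapping_alleles(al_gr, alleles, iv, 0L)
    near <- overlapping_alleles(al_gr, alleles, iv, as.integer(distance))
    tibble::tibble(
      query = q, resolved_gene = gid,
      n_within_gene = length(within),
      n_within_distance = length(near),
      alleles_within_gene = list(within),
      alleles_within_distance = list(near)
    )
  })
}

overlapping_alleles <- function(al_gr, alleles, iv, pad) {
  if (nrow(alleles) == 0 || nrow(iv) == 0) return(character(0))
  gr <- GenomicRanges::GRanges(
    iv$chrom,
    IRanges::IRanges(pmax(1L, iv$start - pad), iv$end + pad)
  )
  hits <- GenomicRanges::countOverlaps(al_gr, gr)
  sort(alleles$allele_name[hits > 0])
}
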