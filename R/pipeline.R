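#' Run the full simulation-to-analysis pipeline
#'
#' End-to-end, seeded run: synthetic genome -> plate-structured insertion
#' library -> artifact injection -> per-strain inverse PCR (MboI first;
#' strains without a passing band are retried with HaeIII, as in the
#' published protocol) -> band selection -> flank sequencing -> genome
#' mapping -> allele table -> redundancy collapse -> distribution
#' statistics -> MosTIC coverage. Deterministic under a fixed seed; all
#' stage streams derive from `sc$seed`.
#'
#' For inverse PCR, each strain's well contributes every template present
#' in it: the strain's own insertions plus any resident insertion and any
#' contaminating template copied in from a plate neighbour.
#'
#' @param sc A [sim_config()].
#' @param config A [mos_config()].
#' @param q_jitter,q_fail Sequencing noise probabilities (defaults 0).
#' @param out_dir Optional directory; when given, FASTA/GFF3/allele tables
#'   and the coverage TSV are written there.
#' @return Object of class `mos_pipeline`: `dataset`, `sim` (with
#'   artifacts), `amplicons`, `bands`, `reads`, `mapped`, `alleles`,
#'   `collapsed`, `redundancy`, `gap_stats`, `chrom_dist`, `contigs`,
#'   `coverage`, and a `funnel` tibble of per-stage counts.
#'   [generics::glance()] returns the funnel in wide form.
#' @examples
#' \donttest{
#' run <- run_pipeline(sim_config(chrom_lengths = c(chrI = 2e5),
#'                                n_genes = 40, n_strains = 48, seed = 7))
#' run$funnel
#' }
#' @export
run_pipeline <- function(sc, config = mos_config(),
                         q_jitter = 0, q_fail = 0, out_dir = NULL) {
  dataset <- simulate_genome(sc)
  sim <- simulate_insertions(dataset, sc)
  sim <- inject_artifacts(sim, dataset, sc)

  templates <- dplyr::distinct(
    sim$truth, .data$strain_id, .data$chrom, .data$position)

  amp_mboi <- predict_amplicons(dataset, templates, "MboI", config)
  band_mboi <- select_band(amp_mboi)
  retry_ids <- setdiff(templates$strain_id, band_mboi$strain_id)
  amp_hae <- predict_amplicons(
    dataset, dplyr::filter(templates, .data$strain_id %in% retry_ids),
    "HaeIII", config)
  band_hae <- select_band(amp_hae)
  bands <- dplyr::bind_rows(band_mboi, band_hae)
  amplicons <- dplyr::bind_rows(amp_mboi, amp_hae)

  reads <- extract_flanks(bands, dataset, q_jitter = q_jitter,
                          q_fail = q_fail, seed = sc$seed)
  mapped <- map_flanks(reads, dataset, config)
  alleles <- alleles_from_mapping(mapped, sim$strains)
  collapsed <- collapse_alleles(alleles, config$dedupe_max_sep)
  redundancy <- classify_redundant(collapsed, config$allele_number_proximity)
  uniq <- dplyr::filter(collapsed, .data$is_unique)

  gap_stats <- gap_statistics(uniq)
  chrom_dist <- if (nrow(uniq) > 0) chromosome_distribution(uniq, dataset) else NULL
  contigs <- merge_windows(uniq, dataset, config$mostic_flank)
  coverage <- coverage_table(contigs, dataset)

  status_counts <- function(s) sum(mapped$status == s)
  funnel <- tibble::tibble(
    stage = c("strains", "strains_with_insertion", "templates",
              "amplicons_predicted", "strains_with_band",
              "reads_ok", "reads_failed",
              "mapped", "ambiguous", "unmapped", "too_short",
              "alleles_recorded", "alleles_unique", "alleles_redundant"),
    n = c(nrow(sim$strains),
          dplyr::n_distinct(sim$truth$strain_id),
          nrow(templates),
          nrow(amplicons),
          dplyr::n_distinct(bands$strain_id),
          sum(!reads$failed),
          sum(reads$failed),
          status_counts("mapped"), status_counts("ambiguous"),
          status_counts("unmapped"), status_counts("too_short"),
          nrow(alleles),
          redundancy$n_unique, redundancy$n_redundant)
  )
  conserved <- sum(funnel$n[funnel$stage %in%
                              c("mapped", "ambiguous", "unmapped", "too_short")])
  if (conserved != funnel$n[funnel$stage == "reads_ok"]) {
    stop("pipeline funnel not conserved: mapping outcomes (", conserved,
         ") != usable reads (", funnel$n[funnel$stage == "reads_ok"], ")",
         call. = FALSE)
  }

  run <- structure(list(
    dataset = dataset, sim = sim, amplicons = amplicons, bands = bands,
    reads = reads, mapped = mapped, alleles = alleles,
    collapsed = collapsed, redundancy = redundancy,
    gap_stats = gap_stats, chrom_dist = chrom_dist,
    contigs = contigs, coverage = coverage, funnel = funnel,
    sim_config = sc, config = config
  ), class = "mos_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset, file.path(out_dir, "genome.fa"),
                  file.path(out_dir, "genes.gff3"))
    write_allele_table(alleles, file.path(out_dir, "alleles.tsv"))
    write_allele_table(dplyr::filter(collapsed, .data$is_unique),
                       file.path(out_dir, "alleles_unique.tsv"))
    readr::write_tsv(dplyr::select(collapsed, -dplyr::any_of("members")),
                     file.path(out_dir, "alleles_collapsed.tsv"),
                     progress = FALSE)
    readr::write_tsv(coverage, file.path(out_dir, "coverage.tsv"),
                     progress = FALSE)
    write_contigs_bed(contigs, file.path(out_dir, "contigs.bed"))
    readr::write_tsv(funnel, file.path(out_dir, "funnel.tsv"),
                     progress = FALSE)
  }
  run
}

#' @export
print.mos_pipeline <- function(x, ...) {
  cat("<mos_pipeline>\n")
  f <- stats::setNames(x$funnel$n, x$funnel$stage)
  cat(sprintf("  %d strains -> %d with band -> %d mapped -> %d alleles (%d unique)\n",
              f["strains"], f["strains_with_band"], f["mapped"],
              f["alleles_recorded"], f["alleles_unique"]))
  invisible(x)
}

#' @importFrom generics glance
#' @method glance mos_pipeline
#' @export
glance.mos_pipeline <- function(x, ...) {
  tidyr::pivot_wider(x$funnel, names_from = "stage", values_from = "n")
}
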