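#' Simulation configuration
#'
#' Parameters of the synthetic genome and insertion-library generator. The
#' defaults emulate the production conditions of the published Mos1
#' collection at desk scale: insertion counts per strain average 2.0 (the
#' figure measured for the pooled library), strains are produced in 24-well
#' plates and numbered sequentially in production order, and the target
#' space is the genome's TA dinucleotides. Artifact parameters reproduce
#' the two redundancy mechanisms reported for the collection: a resident
#' insertion already fixed in the starting strain, and plate-local
#' cross-contamination during molecular characterization.
#'
#' @param chrom_lengths Named vector of chromosome lengths (bp, each >= 1 kb).
#' @param gc_content Genome GC fraction (default 0.36, nematode-like).
#' @param n_genes Number of gene models to place (non-overlapping).
#' @param exon_count_range,exon_len_range,intron_len_range Integer ranges
#'   `[min, max]` for exons per gene and exon/intron lengths (bp).
#' @param prop_noncoding Fraction of genes given biotype `other` (no CDS).
#' @param n_strains Number of strains produced.
#' @param mean_insertions_per_strain Poisson mean of true insertions per
#'   strain (default 2.0).
#' @param plate_size Wells per production plate (default 24).
#' @param hotspot_sites Optional tibble `chrom`, `position`, `weight`
#'   multiplying the draw probability of individual TA sites.
#' @param germline_genes,germline_weight Optional gene-id vector and weight
#'   multiplier for TA sites inside those genes (default weight 1: no
#'   preference, matching the absence of germline enrichment in the data).
#' @param resident_site Optional `list(chrom =, position =)` TA site of a
#'   resident insertion in the starting strain; `NULL` for none.
#' @param resident_fraction Fraction of strains carrying the resident
#'   insertion (default 0.03).
#' @param contamination_rate Per-recorded-allele probability of being
#'   duplicated into another well of the same plate (default 0.05).
#' @param seed Integer seed; all stages derive independent streams from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chrI = 1e6, chrII = 1e6, chrIII = 1e6),
                       gc_content = 0.36,
                       n_genes = 200 * length(chrom_lengths),
                       exon_count_range = c(3L, 8L),
                       exon_len_range = c(50L, 300L),
                       intron_len_range = c(40L, 400L),
                       prop_noncoding = 0.05,
                       n_strains = 500,
                       mean_insertions_per_strain = 2.0,
                       plate_size = 24L,
                       hotspot_sites = NULL,
                       germline_genes = NULL,
                       germline_weight = 1.0,
                       resident_site = NULL,
                       resident_fraction = 0.03,
                       contamination_rate = 0.05,
                       seed = 1L) {
  stopifnot(
    all(chrom_lengths >= 1000),
    gc_content >= 0, gc_content <= 1,
    prop_noncoding >= 0, prop_noncoding <= 1,
    mean_insertions_per_strain > 0,
    resident_fraction >= 0, resident_fraction <= 1,
    contamination_rate >= 0, contamination_rate <= 1,
    plate_size >= 2
  )
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", utils::as.roman(seq_along(chrom_lengths)))
  }
  structure(list(
    chrom_lengths = chrom_lengths,
    gc_content = gc_content,
    n_genes = as.integer(n_genes),
    exon_count_range = as.integer(exon_count_range),
    exon_len_range = as.integer(exon_len_range),
    intron_len_range = as.integer(intron_len_range),
    prop_noncoding = prop_noncoding,
    n_strains = as.integer(n_strains),
    mean_insertions_per_strain = mean_insertions_per_strain,
    plate_size = as.integer(plate_size),
    hotspot_sites = hotspot_sites,
    germline_genes = germline_genes,
    germline_weight = germline_weight,
    resident_site = resident_site,
    resident_fraction = resident_fraction,
    contamination_rate = contamination_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic genome with gene models
#'
#' Random nucleotide sequence at the configured GC content; gene models
#' with exon/intron structure drawn from the configured ranges, placed
#' without overlap and allocated to chromosomes in proportion to length.
#' Coding exons equal exons for protein-coding genes (a deliberate
#' simplification; UTR structure is not modelled). Deterministic under a
#' fixed seed.
#'
#' @param sc A [sim_config()].
#' @return A `mos_dataset` (TA index built).
#' @examples
#' ds <- simulate_genome(sim_config(chrom_lengths = c(chrI = 50000),
#'                                  n_genes = 10, seed = 42))
#' ds
#' @export
simulate_genome <- function(sc) {
  stopifnot(inherits(sc, "sim_config"))
  set.seed(derive_seed(sc$seed, "genome"))
  gc <- sc$gc_content
  seqs <- vapply(sc$chrom_lengths, function(len) {
    paste(sample(c("A", "T", "G", "C"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  }, character(1))

  genes <- transcripts <- exons <- cds <- NULL
  if (sc$n_genes > 0) {
    n_per_chrom <- stats::rmultinom(
      1, sc$n_genes, sc$chrom_lengths / sum(sc$chrom_lengths))[, 1]
    parts <- vector("list", length(sc$chrom_lengths))
    gene_counter <- 0L
    for (ci in seq_along(sc$chrom_lengths)) {
      g <- n_per_chrom[ci]
      if (g == 0) next
      chrom <- names(sc$chrom_lengths)[ci]
      len <- sc$chrom_lengths[[ci]]
      structs <- lapply(seq_len(g), function(i) {
        k <- sample(sc$exon_count_range[1]:sc$exon_count_range[2], 1)
        ex <- sample(sc$exon_len_range[1]:sc$exon_len_range[2], k, replace = TRUE)
        iv <- if (k > 1) {
          sample(sc$intron_len_range[1]:sc$intron_len_range[2], k - 1,
                 replace = TRUE)
        } else {
          integer(0)
        }
        list(exon_len = ex, intron_len = iv, span = sum(ex) + sum(iv))
      })
      spans <- vapply(structs, `[[`, numeric(1), "span")
      free <- len - sum(spans)
      if (free < g) {
        stop("cannot place ", g, " non-overlapping genes on a ", len,
             "-bp chromosome; lower the gene density", call. = FALSE)
      }
      gaps_at <- sort(sample.int(free, g))
      starts <- gaps_at + c(0, cumsum(spans[-g]))
      parts[[ci]] <- purrr::map_dfr(seq_len(g), function(i) {
        st <- structs[[i]]
        ex_start <- starts[i] +
          cumsum(c(0L, st$exon_len[-length(st$exon_len)] +
                     c(st$intron_len, integer(0))))
        tibble::tibble(
          gene_id = sprintf("gene%05d", gene_counter + i),
          chrom = chrom,
          strand = sample(c("+", "-"), 1),
          gstart = as.integer(starts[i]),
          gend = as.integer(starts[i] + st$span - 1L),
          exon_start = list(as.integer(ex_start)),
          exon_end = list(as.integer(ex_start + st$exon_len - 1L))
        )
      })
      gene_counter <- gene_counter + g
    }
    flat <- dplyr::bind_rows(parts)
    n_nc <- round(nrow(flat) * sc$prop_noncoding)
    nc_ids <- if (n_nc > 0) sample(flat$gene_id, n_nc) else character(0)
    genes <- tibble::tibble(
      gene_id = flat$gene_id, chrom = flat$chrom, strand = flat$strand,
      start = flat$gstart, end = flat$gend,
      biotype = ifelse(flat$gene_id %in% nc_ids, "other", "protein_coding")
    )
    transcripts <- tibble::tibble(
      transcript_id = paste0(flat$gene_id, ".1"), gene_id = flat$gene_id
    )
    exons <- tidyr::unnest(
      tibble::tibble(
        gene_id = flat$gene_id,
        transcript_id = paste0(flat$gene_id, ".1"),
        chrom = flat$chrom,
        start = flat$exon_start, end = flat$exon_end
      ),
      cols = c("start", "end")
    )
    cds <- exons[exons$gene_id %in% genes$gene_id[genes$biotype == "protein_coding"], ]
  }
  mos_dataset(seqs = seqs, genes = genes, transcripts = transcripts,
              exons = exons, cds = cds)
}

#' Simulate a plate-structured insertion library
#'
#' Strains are numbered sequentially in plate production order and packed
#' into plates of `plate_size` wells. Each strain receives a Poisson number
#' of true insertions drawn without replacement from the genome's TA sites
#' (uniformly by default; hotspot and germline weights multiply). As in the
#' real protocol, molecular characterization records a single allele per
#' productive strain, named `ttTi<serial>` — so plate locality implies
#' allele-number locality.
#'
#' @param dataset A `mos_dataset` with non-empty TA index.
#' @param sc A [sim_config()].
#' @return A list of class `mos_simulation`:
#'   * `alleles` — recorded allele table (one row per productive strain);
#'   * `truth` — every true insertion with `strain_id`, `plate_id`, `well`,
#'     `serial`, `chrom`, `position`, `source`;
#'   * `strains` — per-strain record incl. strains with zero insertions.
#' @export
simulate_insertions <- function(dataset, sc) {
  stopifnot(inherits(sc, "sim_config"))
  ta <- ta_sites(dataset)
  if (nrow(ta) == 0) {
    stop("genome contains no TA sites; Mos1 insertion cannot be simulated",
         call. = FALSE)
  }
  set.seed(derive_seed(sc$seed, "insertions"))

  w <- rep(1, nrow(ta))
  if (!is.null(sc$hotspot_sites) && nrow(sc$hotspot_sites) > 0) {
    key <- paste(ta$chrom, ta$position)
    hkey <- paste(sc$hotspot_sites$chrom, sc$hotspot_sites$position)
    idx <- match(hkey, key)
    if (anyNA(idx)) {
      stop("hotspot site not at a TA dinucleotide: ",
           hkey[is.na(idx)][1], call. = FALSE)
    }
    w[idx] <- w[idx] * sc$hotspot_sites$weight
  }
  if (!is.null(sc$germline_genes) && sc$germline_weight != 1) {
    g <- dataset$genes[dataset$genes$gene_id %in% sc$germline_genes, ]
    if (nrow(g) > 0) {
      hits <- GenomicRanges::findOverlaps(
        alleles_to_granges(tibble::tibble(chrom = ta$chrom, position = ta$position)),
        GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
      )
      w[unique(S4Vectors::queryHits(hits))] <-
        w[unique(S4Vectors::queryHits(hits))] * sc$germline_weight
    }
  }

  serial <- seq_len(sc$n_strains)
  strains <- tibble::tibble(
    serial = serial,
    strain_id = sprintf("S%05d", serial),
    plate_id = sprintf("P%04d", (serial - 1L) %/% sc$plate_size + 1L),
    well = (serial - 1L) %% sc$plate_size + 1L,
    n_insertions = stats::rpois(sc$n_strains, sc$mean_insertions_per_strain)
  )
  strains$n_insertions <- pmin(strains$n_insertions, nrow(ta))

  empty_truth <- tibble::tibble(
    strain_id = character(), plate_id = character(), well = integer(),
    serial = integer(), chrom = character(), position = integer(),
    source = character()
  )
  truth <- purrr::map_dfr(seq_len(nrow(strains)), function(i) {
    k <- strains$n_insertions[i]
    if (k == 0) return(NULL)
    idx <- sample.int(nrow(ta), k, prob = w)
    tibble::tibble(
      strain_id = strains$strain_id[i], plate_id = strains$plate_id[i],
      well = strains$well[i], serial = strains$serial[i],
      chrom = ta$chrom[idx], position = ta$position[idx],
      source = "transposition"
    )
  })

  if (nrow(truth) == 0) truth <- empty_truth

  alleles <- if (nrow(truth) == 0) empty_allele_table() else truth |>
    dplyr::group_by(.data$strain_id) |>
    dplyr::slice_sample(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$serial) |>
    dplyr::transmute(
      allele_name = sprintf("ttTi%d", .data$serial),
      allele_number = .data$serial,
      chrom = .data$chrom, position = .data$position,
      precise = TRUE,
      strain_id = .data$strain_id, plate_id = .data$plate_id
    )

  structure(list(alleles = alleles, truth = truth, strains = strains,
                 config = sc),
            class = "mos_simulation")
}

#' Inject redundancy artifacts into a simulated library
#'
#' Reproduces the two artifact mechanisms observed in the real collection:
#' * a **resident insertion** fixed in the starting strain — added to a
#'   Bernoulli(`resident_fraction`) subset of strains, whose recorded
#'   allele then becomes the resident coordinate (its amplicon dominates
#'   characterization), yielding many alleles at one site;
#' * **plate-local cross-contamination** — with probability
#'   `contamination_rate` per recorded allele, the allele's template is
#'   copied into a different random well of the same plate, whose strain
#'   then records the contaminant coordinate under its own serial number.
#'   Because strains are numbered sequentially within plates of
#'   `plate_size` wells, such duplicate pairs always differ by fewer than
#'   `plate_size` allele numbers.
#'
#' @param sim A `mos_simulation` from [simulate_insertions()].
#' @param dataset The `mos_dataset` the simulation was drawn on.
#' @param sc The same [sim_config()] (carries the artifact parameters).
#' @return The `mos_simulation` with `alleles`/`truth` updated and an
#'   `$artifacts` element recording injected ground truth:
#'   `resident_strains` (character) and `contamination` (tibble with
#'   `source_name`, `recipient_name`, `chrom`, `position`, `realized`).
#' @export
inject_artifacts <- function(sim, dataset, sc) {
  stopifnot(inherits(sim, "mos_simulation"), inherits(sc, "sim_config"))
  set.seed(derive_seed(sc$seed, "artifacts"))
  alleles <- sim$alleles
  truth <- sim$truth
  strains <- sim$strains
  artifacts <- list(resident_strains = character(0),
                    contamination = tibble::tibble(
                      source_name = character(), recipient_name = character(),
                      chrom = character(), position = integer(),
                      realized = logical()))

  record_for <- function(alleles, serial, chrom, position, source_precise = TRUE) {
    i <- match(serial, alleles$allele_number)
    row <- tibble::tibble(
      allele_name = sprintf("ttTi%d", serial), allele_number = serial,
      chrom = chrom, position = as.integer(position), precise = source_precise,
      strain_id = strains$strain_id[match(serial, strains$serial)],
      plate_id = strains$plate_id[match(serial, strains$serial)]
    )
    if (is.na(i)) {
      dplyr::arrange(dplyr::bind_rows(alleles, row), .data$allele_number)
    } else {
      alleles[i, ] <- row
      alleles
    }
  }

  if (!is.null(sc$resident_site) && sc$resident_fraction > 0) {
    rchrom <- sc$resident_site$chrom
    rpos <- as.integer(sc$resident_site$position)
    if (!rpos %in% (dataset$ta_index[[rchrom]] %||% integer(0))) {
      stop("resident_site must be a TA dinucleotide", call. = FALSE)
    }
    carrier <- strains$serial[stats::runif(nrow(strains)) < sc$resident_fraction]
    for (s in carrier) {
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        strain_id = strains$strain_id[s], plate_id = strains$plate_id[s],
        well = strains$well[s], serial = s,
        chrom = rchrom, position = rpos, source = "resident"
      ))
      alleles <- record_for(alleles, s, rchrom, rpos)
    }
    artifacts$resident_strains <- strains$strain_id[carrier]
  }

  if (sc$contamination_rate > 0 && nrow(alleles) > 0) {
    snapshot <- alleles
    events <- list()
    for (i in seq_len(nrow(snapshot))) {
      if (stats::runif(1) >= sc$contamination_rate) next
      src_serial <- snapshot$allele_number[i]
      mates <- strains$serial[strains$plate_id == snapshot$plate_id[i] &
                                strains$serial != src_serial]
      if (length(mates) == 0) next
      rec <- if (length(mates) == 1) mates else sample(mates, 1)
      events[[length(events) + 1]] <- tibble::tibble(
        source_name = snapshot$allele_name[i],
        recipient_serial = rec,
        recipient_name = sprintf("ttTi%d", rec),
        chrom = snapshot$chrom[i],
        position = snapshot$position[i]
      )
    }
    if (length(events) > 0) {
      ev <- dplyr::bind_rows(events)
      for (j in seq_len(nrow(ev))) {
        alleles <- record_for(alleles, ev$recipient_serial[j],
                              ev$chrom[j], ev$position[j])
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          strain_id = strains$strain_id[ev$recipient_serial[j]],
          plate_id = strains$plate_id[ev$recipient_serial[j]],
          well = strains$well[ev$recipient_serial[j]],
          serial = ev$recipient_serial[j],
          chrom = ev$chrom[j], position = ev$position[j],
          source = "contamination"
        ))
      }
      # an event is realized if both endpoints still carry the contaminant
      # coordinate in the final table (later events in a chain can overwrite
      # either record)
      final_rec <- alleles[match(ev$recipient_name, alleles$allele_name), ]
      final_src <- alleles[match(ev$source_name, alleles$allele_name), ]
      ev$realized <- final_rec$chrom == ev$chrom &
        final_rec$position == ev$position &
        final_src$chrom == ev$chrom &
        final_src$position == ev$position
      artifacts$contamination <- ev[, c("source_name", "recipient_name",
                                        "chrom", "position", "realized")]
    }
  }

  sim$alleles <- alleles
  sim$truth <- truth
  sim$artifacts <- artifacts
  sim
}

#' @export
print.mos_simulation <- function(x, ...) {
  cat("<mos_simulation>\n")
  cat("  strains:", nrow(x$strains),
      " true insertions:", nrow(x$truth), "\n")
  cat("  recorded alleles:", nrow(x$alleles), "\n")
  if (!is.null(x$artifacts)) {
    cat("  artifacts: resident carriers", length(x$artifacts$resident_strains),
        "; contamination events", nrow(x$artifacts$contamination), "\n")
  }
  invisible(x)
}
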