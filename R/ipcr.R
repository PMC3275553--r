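#' Restriction enzymes of the inverse-PCR protocol
#'
#' The protocol digests genomic DNA with one of two 4-cutters, self-ligates
#' the fragments and amplifies outward across the transposon-genome
#' junction with nested primers. Only bands whose size exceeds an
#' enzyme-specific threshold (270 bp for MboI, 325 bp for HaeIII) are
#' purified and sequenced; smaller products cannot contain informative
#' flanking DNA. `primer_offset` is the constant amplicon contribution of
#' transposon-internal sequence and is set equal to the size threshold, so
#' that the size filter passes exactly the amplicons with at least one
#' informative flanking base.
#'
#' @param name `"MboI"` or `"HaeIII"` (case-insensitive).
#' @param config A [mos_config()] supplying the size thresholds.
#' @return A list of class `mos_enzyme` with `name`, `recognition`,
#'   `size_threshold`, `primer_offset`.
#' @examples
#' mos_enzyme("MboI")
#' @export
mos_enzyme <- function(name, config = mos_config()) {
  key <- tolower(name)
  if (!key %in% c("mboi", "haeiii")) {
    stop("unknown enzyme `", name, "`; supported: MboI, HaeIII", call. = FALSE)
  }
  thr <- if (key == "mboi") config$size_threshold_mboi else config$size_threshold_haeiii
  structure(list(
    name = if (key == "mboi") "MboI" else "HaeIII",
    recognition = if (key == "mboi") "GATC" else "GGCC",
    size_threshold = as.integer(thr),
    primer_offset = as.integer(thr)
  ), class = "mos_enzyme")
}

# Sorted start positions of an enzyme's recognition site per chromosome.
recognition_index <- function(dataset, enzyme) {
  lapply(stats::setNames(seq_along(dataset$seqs), names(dataset$seqs)),
         function(i) {
           BiocGenerics::start(
             Biostrings::matchPattern(enzyme$recognition, dataset$seqs[[i]]))
         })
}

#' Predict inverse-PCR amplicons for a set of insertions
#'
#' For each insertion, the genomic flank runs 3' of the TA junction on the
#' plus strand, from `position + 2` through the end of the nearest
#' downstream recognition site:
#' `flank_len = site_start - (position + 2) + 4`. The amplicon adds the
#' transposon-internal primer offset, and a band passes the size filter iff
#' `amplicon_len > size_threshold` (strict). Insertions with no downstream
#' recognition site on their chromosome yield no amplicon.
#'
#' @param dataset A `mos_dataset` with sequences.
#' @param insertions Tibble with columns `strain_id`, `chrom`, `position`
#'   (e.g. the `truth` table of a [simulate_insertions()] result).
#' @param enzyme A [mos_enzyme()] or enzyme name.
#' @param config A [mos_config()].
#' @return Tibble with one row per insertion that has a downstream site:
#'   `strain_id`, `chrom`, `position`, `enzyme`, `site_start`, `flank_len`,
#'   `amplicon_len`, `passes`, `flank_seq`.
#' @export
predict_amplicons <- function(dataset, insertions, enzyme,
                              config = mos_config()) {
  if (!inherits(enzyme, "mos_enzyme")) enzyme <- mos_enzyme(enzyme, config)
  if (is.null(dataset$seqs)) {
    stop("amplicon prediction requires chromosome sequences", call. = FALSE)
  }
  if (nrow(insertions) == 0) {
    return(tibble::tibble(
      strain_id = character(), chrom = character(), position = integer(),
      enzyme = character(), site_start = integer(), flank_len = integer(),
      amplicon_len = integer(), passes = logical(), flank_seq = character()
    ))
  }
  sites <- recognition_index(dataset, enzyme)
  enzyme_name <- enzyme$name
  primer_offset <- enzyme$primer_offset
  size_threshold <- enzyme$size_threshold
  res <- insertions |>
    dplyr::mutate(
      site_start = purrr::map2_int(.data$chrom, .data$position, function(ch, p) {
        s <- sites[[ch]]
        i <- findInterval(p + 1L, s) + 1L  # first site start >= p + 2
        if (i > length(s)) NA_integer_ else s[i]
      })
    ) |>
    dplyr::filter(!is.na(.data$site_start)) |>
    dplyr::mutate(
      enzyme = enzyme_name,
      flank_len = .data$site_start - (.data$position + 2L) + 4L,
      amplicon_len = primer_offset + .data$flank_len,
      passes = .data$amplicon_len > size_threshold
    )
  res$flank_seq <- extract_genomic(dataset, res$chrom,
                                   res$position + 2L, res$flank_len)
  dplyr::select(res, dplyr::any_of(c(
    "strain_id", "chrom", "position", "enzyme", "site_start",
    "flank_len", "amplicon_len", "passes", "flank_seq")))
}

extract_genomic <- function(dataset, chrom, start, len) {
  if (length(chrom) == 0) return(character(0))
  vapply(seq_along(chrom), function(i) {
    L <- dataset$chroms$length[match(chrom[i], dataset$chroms$chrom)]
    s <- max(1L, start[i])
    e <- min(L, start[i] + len[i] - 1L)
    if (e < s) return("")
    as.character(Biostrings::subseq(dataset$seqs[[chrom[i]]], s, e))
  }, character(1))
}

#' Select the band purified for sequencing
#'
#' When a strain's inverse PCR yields multiple bands, the strongest one is
#' purified; shorter templates amplify more efficiently, so the shortest
#' amplicon passing the size filter is taken as the strongest-band proxy
#' (ties broken by lower chromosome, then position). Strains with no
#' passing band yield no row.
#'
#' @param amplicons Output of [predict_amplicons()] (may pool enzymes; band
#'   selection is per `strain_id` within `enzyme`).
#' @return Tibble with at most one row per (`strain_id`, `enzyme`).
#' @export
select_band <- function(amplicons) {
  amplicons |>
    dplyr::filter(.data$passes) |>
    dplyr::group_by(.data$strain_id, .data$enzyme) |>
    dplyr::arrange(.data$amplicon_len, .data$chrom, .data$position,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Sequence the selected bands into flank reads
#'
#' Models the two failure modes seen at the sequencing step: with
#' probability `q_fail` a read is unusable, and with probability `q_jitter`
#' the reported transposon-genome junction is shifted by a uniform integer
#' offset in `[-jitter_radius, +jitter_radius]` (poor quality around the
#' junction), in which case the recovered allele is at best precise to
#' within that radius. With both probabilities zero the read equals the
#' genomic flank exactly.
#'
#' @param bands Output of [select_band()].
#' @param dataset The `mos_dataset`.
#' @param q_jitter,q_fail Per-read probabilities (defaults 0).
#' @param jitter_radius Maximum junction offset in bp (default 10).
#' @param seed Integer seed for the noise draws.
#' @return Tibble of reads: `strain_id`, `enzyme`, `sequence` (`NA` when
#'   failed), `reported_junction_offset`, `failed`, plus the simulated
#'   truth columns `true_chrom`, `true_position` for downstream checks.
#' @export
extract_flanks <- function(bands, dataset, q_jitter = 0, q_fail = 0,
                           jitter_radius = 10L, seed = 1L) {
  set.seed(derive_seed(seed, "sequencing"))
  n <- nrow(bands)
  failed <- stats::runif(n) < q_fail
  jittered <- stats::runif(n) < q_jitter
  offset <- ifelse(jittered,
                   sample(seq(-jitter_radius, jitter_radius), n, replace = TRUE),
                   0L)
  seqs <- extract_genomic(dataset, bands$chrom,
                          bands$position + 2L + offset, bands$flank_len)
  tibble::tibble(
    strain_id = bands$strain_id,
    enzyme = bands$enzyme,
    sequence = ifelse(failed, NA_character_, seqs),
    reported_junction_offset = as.integer(offset),
    failed = failed,
    true_chrom = bands$chrom,
    true_position = bands$position
  )
}
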