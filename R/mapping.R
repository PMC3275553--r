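#' Map flank reads back to the genome
#'
#' Replaces the BLASTN step of the original pipeline with exact substring
#' search over both strands of every chromosome (simulated reads are
#' error-free substrings, so alignment heuristics add nothing). The
#' published filter semantics are preserved: reads matching two or more
#' genomic loci are ambiguous and discarded; reads shorter than
#' `min_flank_map_len` are not attempted. A uniquely matching read defines
#' a junction immediately 5' of the match on the insertion strand, which is
#' snapped to the nearest TA-site coordinate within `snap_radius` bp.
#' Reverse-strand hits are reported at plus-strand TA coordinates (TA is
#' its own reverse complement).
#'
#' @param reads Tibble of flank reads as from [extract_flanks()]; rows with
#'   `failed = TRUE` or `NA` sequence are reported with status `failed`.
#' @param dataset A `mos_dataset` with sequences and TA index.
#' @param config A [mos_config()].
#' @return Tibble with one row per read: `strain_id`, `enzyme`, `status`
#'   (`mapped`, `ambiguous`, `unmapped`, `too_short`, `failed`), `chrom`,
#'   `position`, `precise`. `position` is set only for `status == "mapped"`
#'   and is `precise` when the junction was snapped to a TA and the read
#'   reported no junction offset.
#' @export
map_flanks <- function(reads, dataset, config = mos_config()) {
  if (is.null(dataset$seqs)) {
    stop("mapping requires chromosome sequences", call. = FALSE)
  }
  if (is.null(dataset$ta_index)) dataset <- build_ta_index(dataset)
  if (nrow(reads) == 0) {
    return(tibble::tibble(
      strain_id = character(), enzyme = character(), status = character(),
      chrom = character(), position = integer(), precise = logical()
    ))
  }
  purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    base <- tibble::tibble(
      strain_id = reads$strain_id[i],
      enzyme = if ("enzyme" %in% names(reads)) reads$enzyme[i] else NA_character_,
      status = NA_character_, chrom = NA_character_,
      position = NA_integer_, precise = NA
    )
    seq <- reads$sequence[i]
    if ((!is.null(reads$failed) && isTRUE(reads$failed[i])) || is.na(seq)) {
      base$status <- "failed"
      return(base)
    }
    if (nchar(seq) < config$min_flank_map_len) {
      base$status <- "too_short"
      return(base)
    }
    offset <- if ("reported_junction_offset" %in% names(reads)) {
      reads$reported_junction_offset[i]
    } else {
      0L
    }
    hits <- genome_hits(seq, dataset)
    if (nrow(hits) == 0) {
      base$status <- "unmapped"
      return(base)
    }
    if (nrow(hits) > 1) {
      base$status <- "ambiguous"
      return(base)
    }
    junction <- hits$junction[1]
    chrom <- hits$chrom[1]
    ta <- dataset$ta_index[[chrom]]
    near <- ta[abs(ta - junction) <= config$snap_radius]
    if (length(near) > 0) {
      snapped <- near[which.min(abs(near - junction))]
      base$status <- "mapped"
      base$chrom <- chrom
      base$position <- as.integer(snapped)
      base$precise <- offset == 0L
    } else {
      L <- dataset$chroms$length[match(chrom, dataset$chroms$chrom)]
      if (junction < 1L || junction > L - 1L) {
        base$status <- "unmapped"
      } else {
        base$status <- "mapped"
        base$chrom <- chrom
        base$position <- as.integer(junction)
        base$precise <- FALSE
      }
    }
    base
  })
}

# All exact occurrences of `seq` over both strands, as plus-strand inferred
# junction coordinates (first base of the putative TA).
genome_hits <- function(seq, dataset) {
  pat <- Biostrings::DNAString(seq)
  rc <- Biostrings::reverseComplement(pat)
  palindromic <- as.character(pat) == as.character(rc)
  out <- purrr::imap_dfr(
    stats::setNames(seq_along(dataset$seqs), names(dataset$seqs)),
    function(i, chrom) {
      subject <- dataset$seqs[[i]]
      fwd <- BiocGenerics::start(Biostrings::matchPattern(pat, subject))
      rows <- tibble::tibble(chrom = chrom, start = as.integer(fwd),
                             strand = "+",
                             junction = as.integer(fwd) - 2L)
      if (!palindromic) {
        rev_m <- Biostrings::matchPattern(rc, subject)
        rs <- BiocGenerics::start(rev_m)
        re <- BiocGenerics::end(rev_m)
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          chrom = chrom, start = as.integer(rs), strand = "-",
          junction = as.integer(re) + 1L
        ))
      }
      rows
    })
  out
}

#' Build an allele table from mapping results
#'
#' Keeps reads with status `mapped` and names each allele `ttTi<serial>`
#' after its strain's production serial, matching the naming convention in
#' which allele numbers record isolation history.
#'
#' @param mapped Output of [map_flanks()].
#' @param strains Strain tibble with `strain_id`, `serial`, `plate_id`
#'   (as in a `mos_simulation`).
#' @return An allele tibble (same columns as [read_allele_table()]).
#' @export
alleles_from_mapping <- function(mapped, strains) {
  mapped |>
    dplyr::filter(.data$status == "mapped") |>
    dplyr::left_join(strains[, c("strain_id", "serial", "plate_id")],
                     by = "strain_id") |>
    dplyr::arrange(.data$serial) |>
    dplyr::transmute(
      allele_name = sprintf("ttTi%d", .data$serial),
      allele_number = .data$serial,
      chrom = .data$chrom, position = .data$position,
      precise = .data$precise,
      strain_id = .data$strain_id, plate_id = .data$plate_id
    )
}

#' Summarize mapping outcomes
#'
#' @param mapped Output of [map_flanks()].
#' @return Tibble of counts by `status`.
#' @export
mapping_summary <- function(mapped) {
  dplyr::count(mapped, .data$status, name = "n")
}
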