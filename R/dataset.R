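#' Assemble a genome dataset from in-memory components
#'
#' The central container used by every analysis step: chromosome sequences
#' (optional), gene models, a named-allele table, and derived indexes (TA
#' dinucleotide positions, merged CDS union). All coordinates are 1-based,
#' closed intervals; an insertion occupies the 2-bp TA span
#' `[position, position + 1]`. Strand is not tracked for alleles: TA is its
#' own reverse complement and insertion sites are reported strand-free.
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences, or `NULL` for coordinate-only mode (then
#'   `chrom_lengths` is required).
#' @param genes Tibble of gene spans with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `biotype`.
#' @param transcripts Tibble mapping `transcript_id` to `gene_id`.
#' @param exons,cds Tibbles of per-transcript intervals with columns
#'   `gene_id`, `transcript_id`, `chrom`, `start`, `end`.
#' @param alleles Allele tibble (see [read_allele_table()] for columns).
#' @param chrom_lengths Named integer vector of chromosome lengths; derived
#'   from `seqs` when sequences are given.
#' @param config A [mos_config()].
#'
#' @return An object of class `mos_dataset`: a list with elements `seqs`,
#'   `chroms`, `genes`, `transcripts`, `exons`, `cds`, `alleles`,
#'   `ta_index`, `config`.
#' @seealso [load_dataset()] to build one from FASTA/GFF/TSV files.
#' @export
mos_dataset <- function(seqs = NULL,
                        genes = NULL, transcripts = NULL,
                        exons = NULL, cds = NULL,
                        alleles = NULL,
                        chrom_lengths = NULL,
                        config = mos_config()) {
  if (!is.null(seqs)) {
    if (is.character(seqs)) {
      if (is.null(names(seqs))) stop("`seqs` must be named", call. = FALSE)
      seqs <- Biostrings::DNAStringSet(toupper(seqs))
    } else {
      seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    }
    chrom_lengths <- stats::setNames(Biostrings::width(seqs), names(seqs))
  }
  if (is.null(chrom_lengths)) {
    stop("either `seqs` or `chrom_lengths` must be supplied", call. = FALSE)
  }
  if (anyDuplicated(names(chrom_lengths))) {
    stop("chromosome names must be unique", call. = FALSE)
  }
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be >= 1", call. = FALSE)

  empty_iv <- tibble::tibble(
    gene_id = character(), transcript_id = character(),
    chrom = character(), start = integer(), end = integer()
  )
  ds <- structure(list(
    seqs = seqs,
    chroms = tibble::tibble(
      chrom = names(chrom_lengths),
      length = as.integer(chrom_lengths)
    ),
    genes = genes %||% tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      start = integer(), end = integer(), biotype = character()
    ),
    transcripts = transcripts %||%
      tibble::tibble(transcript_id = character(), gene_id = character()),
    exons = exons %||% empty_iv,
    cds = cds %||% empty_iv,
    alleles = alleles %||% empty_allele_table(),
    ta_index = NULL,
    config = config
  ), class = "mos_dataset")

  validate_dataset(ds)
  if (!is.null(ds$seqs)) ds <- build_ta_index(ds)
  ds
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_allele_table <- function() {
  tibble::tibble(
    allele_name = character(), allele_number = integer(),
    chrom = character(), position = integer(), precise = logical(),
    strain_id = character(), plate_id = character()
  )
}

validate_dataset <- function(ds) {
  chroms <- ds$chroms$chrom
  g <- ds$genes
  if (nrow(g) > 0) {
    missing <- setdiff(unique(g$chrom), chroms)
    if (length(missing) > 0) {
      bad <- g$gene_id[g$chrom %in% missing][1]
      stop("gene `", bad, "` refers to unknown chromosome `",
           g$chrom[g$gene_id == bad][1], "`", call. = FALSE)
    }
    if (any(g$start > g$end)) {
      stop("gene spans must satisfy start <= end", call. = FALSE)
    }
  }
  for (part in c("exons", "cds")) {
    iv <- ds[[part]]
    if (nrow(iv) == 0) next
    sp <- dplyr::left_join(iv, g[, c("gene_id", "start", "end")],
                           by = "gene_id", suffix = c("", ".gene"))
    out <- which(sp$start < sp$start.gene | sp$end > sp$end.gene)
    if (length(out) > 0) {
      stop(part, " interval of gene `", sp$gene_id[out[1]],
           "` lies outside the gene span", call. = FALSE)
    }
  }
  validate_alleles(ds$alleles, ds$chroms)
  invisible(ds)
}

validate_alleles <- function(alleles, chroms) {
  if (nrow(alleles) == 0) return(invisible(alleles))
  if (anyDuplicated(alleles$allele_name)) {
    dup <- alleles$allele_name[duplicated(alleles$allele_name)][1]
    stop("duplicate allele name `", dup, "`", call. = FALSE)
  }
  missing <- setdiff(unique(alleles$chrom), chroms$chrom)
  if (length(missing) > 0) {
    bad <- alleles$allele_name[alleles$chrom %in% missing][1]
    stop("allele `", bad, "` refers to unknown chromosome `",
         alleles$chrom[alleles$allele_name == bad][1], "`", call. = FALSE)
  }
  len <- stats::setNames(chroms$length, chroms$chrom)
  out <- which(alleles$position < 1 |
                 alleles$position > len[alleles$chrom] - 1L)
  if (length(out) > 0) {
    stop("allele `", alleles$allele_name[out[1]],
         "` position out of chromosome bounds (a TA span needs position <= length - 1)",
         call. = FALSE)
  }
  invisible(alleles)
}

#' Load a genome dataset from FASTA, GFF and allele-table files
#'
#' @param genome_path Multi-record FASTA (wrapped or unwrapped).
#' @param annotation_path GFF3 (or GFF2) file with gene/mRNA/exon/CDS
#'   features; `NULL` for no annotation.
#' @param allele_table_path Optional allele TSV (see [read_allele_table()]).
#' @param gene_key,transcript_key GFF attribute keys holding the gene
#'   sequence name and the transcript name (defaults `ID`).
#' @param config A [mos_config()].
#'
#' @return A `mos_dataset` with TA index built.
#' @examples
#' sc <- sim_config(chrom_lengths = c(chrI = 20000), n_genes = 5, seed = 1)
#' paths <- withr::local_tempdir()
#' ds0 <- simulate_genome(sc)
#' write_dataset(ds0, file.path(paths, "g.fa"), file.path(paths, "g.gff3"))
#' ds <- load_dataset(file.path(paths, "g.fa"), file.path(paths, "g.gff3"))
#' ds
#' @export
load_dataset <- function(genome_path, annotation_path = NULL,
                         allele_table_path = NULL,
                         gene_key = "ID", transcript_key = "ID",
                         config = mos_config()) {
  seqs <- Biostrings::readDNAStringSet(genome_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- if (!is.null(annotation_path)) {
    read_gff_genes(annotation_path, gene_key = gene_key,
                   transcript_key = transcript_key)
  } else {
    NULL
  }
  ds <- mos_dataset(
    seqs = seqs,
    genes = ann$genes, transcripts = ann$transcripts,
    exons = ann$exons, cds = ann$cds,
    config = config
  )
  if (!is.null(allele_table_path)) {
    ds$alleles <- read_allele_table(allele_table_path)
    validate_alleles(ds$alleles, ds$chroms)
  }
  ds
}

# Parse gene/mRNA/exon/CDS features out of a GFF file via rtracklayer.
read_gff_genes <- function(path, gene_key = "ID", transcript_key = "ID") {
  empty <- list(
    genes = NULL, transcripts = NULL, exons = NULL, cds = NULL
  )
  if (file.size(path) == 0) return(empty)
  gr <- rtracklayer::import(path)
  if (length(gr) == 0) return(empty)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  attr_chr <- function(rows, key) {
    if (!key %in% names(mc)) return(rep(NA_character_, sum(rows)))
    v <- mc[[key]][rows]
    if (methods::is(v, "List")) {
      vapply(v, function(x) if (length(x) == 0) NA_character_ else x[1],
             character(1))
    } else {
      as.character(v)
    }
  }

  is_gene <- type == "gene"
  biotype <- attr_chr(is_gene, "biotype")
  if (all(is.na(biotype))) biotype <- attr_chr(is_gene, "gene_biotype")
  genes <- tibble::tibble(
    gene_id = attr_chr(is_gene, gene_key),
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    biotype = dplyr::coalesce(biotype, "protein_coding")
  )

  is_tx <- type %in% c("mRNA", "transcript")
  transcripts <- tibble::tibble(
    transcript_id = attr_chr(is_tx, transcript_key),
    gene_id = attr_chr(is_tx, "Parent")
  )

  part_tbl <- function(ftype) {
    rows <- type == ftype
    parent <- attr_chr(rows, "Parent")
    tx2gene <- stats::setNames(transcripts$gene_id, transcripts$transcript_id)
    gene_id <- ifelse(parent %in% names(tx2gene), tx2gene[parent], parent)
    tibble::tibble(
      gene_id = unname(gene_id),
      transcript_id = ifelse(parent %in% names(tx2gene), parent,
                             NA_character_),
      chrom = as.character(GenomicRanges::seqnames(gr))[rows],
      start = GenomicRanges::start(gr)[rows],
      end = GenomicRanges::end(gr)[rows]
    )
  }
  list(
    genes = genes,
    transcripts = transcripts,
    exons = part_tbl("exon"),
    cds = part_tbl("CDS")
  )
}

#' Read or write an allele table
#'
#' Tab-separated with a header row and columns `allele_name`, `chrom`,
#' `position`, `precise` (0/1), `strain_id`, `plate_id`; extra columns are
#' ignored, `strain_id`/`plate_id` may be absent. Allele numbers are parsed
#' from the integer suffix of the name (`ttTi1234` -> 1234).
#'
#' @param path File path.
#' @return A tibble with one row per allele.
#' @export
read_allele_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop("malformed allele table row at line ", prob$row[1] + 1L, " of ",
         path, call. = FALSE)
  }
  required <- c("allele_name", "chrom", "position", "precise")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    stop("allele table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pos <- suppressWarnings(as.integer(tbl$position))
  if (anyNA(pos)) {
    stop("malformed allele table row at line ", which(is.na(pos))[1] + 1L,
         ": non-integer position", call. = FALSE)
  }
  prec <- suppressWarnings(as.integer(tbl$precise))
  if (anyNA(prec) || any(!prec %in% 0:1)) {
    stop("malformed allele table row at line ",
         which(is.na(prec) | !prec %in% 0:1)[1] + 1L,
         ": precise must be 0 or 1", call. = FALSE)
  }
  tibble::tibble(
    allele_name = tbl$allele_name,
    allele_number = parse_allele_numbers(tbl$allele_name),
    chrom = tbl$chrom,
    position = pos,
    precise = prec == 1L,
    strain_id = if ("strain_id" %in% names(tbl)) tbl$strain_id else NA_character_,
    plate_id = if ("plate_id" %in% names(tbl)) tbl$plate_id else NA_character_
  )
}

#' @rdname read_allele_table
#' @param alleles Allele tibble to write.
#' @export
write_allele_table <- function(alleles, path) {
  out <- alleles[, c("allele_name", "chrom", "position", "precise",
                     "strain_id", "plate_id")]
  out$precise <- as.integer(out$precise)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a dataset back to FASTA / GFF3 / allele TSV
#'
#' @param dataset A `mos_dataset` with sequences.
#' @param fasta_path,gff_path,allele_path Output paths (any may be `NULL`
#'   to skip that component).
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, fasta_path = NULL, gff_path = NULL,
                          allele_path = NULL) {
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(dataset$seqs, fasta_path, width = 70L)
  }
  if (!is.null(gff_path)) {
    write_gff3(dataset, gff_path)
  }
  if (!is.null(allele_path)) {
    write_allele_table(dataset$alleles, allele_path)
  }
  invisible(dataset)
}

write_gff3 <- function(dataset, path) {
  g <- dataset$genes
  tx <- dataset$transcripts
  rows <- list()
  if (nrow(g) > 0) {
    rows$gene <- GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
      type = "gene", ID = g$gene_id, Parent = NA_character_,
      biotype = g$biotype, phase = NA_integer_
    )
    txg <- dplyr::left_join(tx, g, by = "gene_id")
    rows$tx <- GenomicRanges::GRanges(
      txg$chrom, IRanges::IRanges(txg$start, txg$end), strand = txg$strand,
      type = "mRNA", ID = txg$transcript_id, Parent = txg$gene_id,
      biotype = NA_character_, phase = NA_integer_
    )
    for (part in c("exons", "cds")) {
      iv <- dataset[[part]]
      if (nrow(iv) == 0) next
      st <- stats::setNames(g$strand, g$gene_id)
      rows[[part]] <- GenomicRanges::GRanges(
        iv$chrom, IRanges::IRanges(iv$start, iv$end),
        strand = st[iv$gene_id],
        type = if (part == "exons") "exon" else "CDS",
        ID = NA_character_,
        Parent = dplyr::coalesce(iv$transcript_id, iv$gene_id),
        biotype = NA_character_,
        phase = if (part == "cds") 0L else NA_integer_
      )
    }
  }
  if (length(rows) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- sort(do.call(c, unname(rows)), ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Rebuild the per-chromosome TA dinucleotide index
#'
#' Records every position `p` with `sequence[p..p + 1] == "TA"`
#' (case-insensitive; overlapping occurrences all reported). Mos1 inserts
#' exclusively at TA dinucleotides, so this index is the target-site space
#' for simulation and the snap grid for mapping.
#'
#' @param dataset A `mos_dataset` with sequences present.
#' @return The dataset with `$ta_index` set (a named list of sorted integer
#'   vectors).
#' @export
build_ta_index <- function(dataset) {
  if (is.null(dataset$seqs)) {
    stop("TA indexing requires chromosome sequences; ",
         "coordinate-only datasets cannot be indexed", call. = FALSE)
  }
  dataset$ta_index <- lapply(
    stats::setNames(seq_along(dataset$seqs), names(dataset$seqs)),
    function(i) {
      BiocGenerics::start(Biostrings::matchPattern("TA", dataset$seqs[[i]]))
    }
  )
  dataset
}

#' TA sites as a tibble
#'
#' @param dataset A `mos_dataset` with the TA index built.
#' @return Tibble with columns `chrom`, `position` (first base of each TA).
#' @export
ta_sites <- function(dataset) {
  if (is.null(dataset$ta_index)) dataset <- build_ta_index(dataset)
  purrr::imap_dfr(dataset$ta_index, function(pos, chrom) {
    tibble::tibble(chrom = chrom, position = as.integer(pos))
  })
}

#' Merged union of coding-sequence intervals
#'
#' Union over the coding exons of all transcripts, both strands, merged to
#' disjoint sorted intervals per chromosome. The genome CDS fraction is the
#' baseline against which in-CDS insertion fractions are compared.
#'
#' @param dataset A `mos_dataset`.
#' @return Tibble with columns `chrom`, `start`, `end`; attribute
#'   `genome_cds_fraction` holds union length / genome length (0..1),
#'   also available via [cds_fraction()].
#' @examples
#' ds <- mos_dataset(chrom_lengths = c(I = 100),
#'   genes = tibble::tibble(gene_id = "g1", chrom = "I", strand = "+",
#'                          start = 10L, end = 30L, biotype = "protein_coding"),
#'   cds = tibble::tibble(gene_id = c("g1", "g1"), transcript_id = "g1.1",
#'                        chrom = "I", start = c(10L, 15L), end = c(20L, 30L)))
#' cds_union(ds)  # one merged interval [10, 30]
#' cds_fraction(ds)  # 21 / 100
#' @export
cds_union <- function(dataset) {
  gr <- GenomicRanges::reduce(intervals_to_granges(dataset$cds))
  out <- granges_to_tibble(gr)
  out <- dplyr::arrange(out, match(.data$chrom, dataset$chroms$chrom), .data$start)
  frac <- if (nrow(out) == 0) 0 else {
    sum(out$end - out$start + 1) / sum(dataset$chroms$length)
  }
  attr(out, "genome_cds_fraction") <- frac
  out
}

#' @rdname cds_union
#' @export
cds_fraction <- function(dataset) {
  attr(cds_union(dataset), "genome_cds_fraction")
}

#' @export
print.mos_dataset <- function(x, ...) {
  cat("<mos_dataset>\n")
  cat("  chromosomes:", nrow(x$chroms),
      sprintf("(%.2f Mb total)", sum(x$chroms$length) / 1e6),
      if (is.null(x$seqs)) "[coordinate-only]" else "", "\n")
  cat("  genes:", nrow(x$genes),
      " transcripts:", nrow(x$transcripts), "\n")
  cat("  alleles:", nrow(x$alleles), "\n")
  if (!is.null(x$ta_index)) {
    cat("  TA sites:", sum(lengths(x$ta_index)), "\n")
  }
  invisible(x)
}
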