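# Internal helpers shared across modules.

# Derive a reproducible, stage-specific seed below 2^31 from a master seed,
# so pipeline stages draw from independent but reproducible streams.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer(((abs(seed) %% 94906265) * 22695477 + h * 65537) %% 2147483629)
}

# Parse an allele number from its name: integer suffix after an alphabetic
# prefix (ttTi / cxTi in the published collection). Unknown prefixes are
# accepted with a warning, per-table.
parse_allele_numbers <- function(names) {
  m <- stringr::str_match(names, "^([A-Za-z]+)(\\d+)$")
  if (anyNA(m[, 1])) {
    bad <- names[is.na(m[, 1])]
    stop("allele names must be an alphabetic prefix followed by digits; offending: ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(m[, 2]), c("ttTi", "cxTi"))
  if (length(unknown) > 0) {
    warning("unrecognized allele-name prefix(es): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  as.integer(m[, 3])
}

# Convert a per-chromosome interval tibble (chrom/start/end) to a GRanges.
intervals_to_granges <- function(tbl) {
  if (nrow(tbl) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start, end = tbl$end)
  )
}

# 2-bp allele spans [position, position + 1] as GRanges.
alleles_to_granges <- function(alleles) {
  if (nrow(alleles) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    seqnames = alleles$chrom,
    ranges = IRanges::IRanges(start = alleles$position, width = 2L)
  )
}

granges_to_tibble <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
}
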