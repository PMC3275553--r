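# Shared fixture builders: everything is generated in code at test time.

# A dataset from literal sequences (named character vector).
toy_dataset <- function(seqs, genes = NULL, transcripts = NULL,
                        exons = NULL, cds = NULL, alleles = NULL) {
  mos_dataset(seqs = seqs, genes = genes, transcripts = transcripts,
              exons = exons, cds = cds, alleles = alleles)
}

# Allele table from positions (single chromosome unless given).
toy_alleles <- function(positions, numbers = seq_along(positions),
                        chrom = "I", plate_id = NA_character_,
                        prefix = "ttTi") {
  tibble::tibble(
    allele_name = paste0(prefix, numbers),
    allele_number = as.integer(numbers),
    chrom = chrom,
    position = as.integer(positions),
    precise = TRUE,
    strain_id = NA_character_,
    plate_id = plate_id
  )
}

# Random DNA of length n (seeded by the caller).
random_dna <- function(n, gc = 0.4) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# Independent oracle for TA-site enumeration: regex lookahead on the string.
ta_positions_oracle <- function(seq, motif = "TA") {
  m <- gregexpr(paste0("(?=", motif, ")"), toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# Per-base bitmap oracle for window merging and gene coverage on small
# genomes: marks every covered base, reads contigs off the run-length
# encoding, and counts genes with any covered base.
bitmap_coverage_oracle <- function(alleles, chrom_lengths, genes, flank) {
  contigs <- list()
  covered <- lapply(chrom_lengths, function(L) logical(L))
  for (i in seq_len(nrow(alleles))) {
    ch <- alleles$chrom[i]
    s <- max(1L, alleles$position[i] - flank)
    e <- min(chrom_lengths[[ch]], alleles$position[i] + 1L + flank)
    covered[[ch]][s:e] <- TRUE
  }
  for (ch in names(chrom_lengths)) {
    r <- rle(covered[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      contigs[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep],
                                      end = ends[keep])
    }
  }
  n_within <- 0L
  if (!is.null(genes) && nrow(genes) > 0) {
    pc <- genes[genes$biotype == "protein_coding", ]
    n_within <- sum(vapply(seq_len(nrow(pc)), function(i) {
      any(covered[[pc$chrom[i]]][pc$start[i]:pc$end[i]])
    }, logical(1)))
  }
  list(contigs = dplyr::bind_rows(contigs), n_genes_within = n_within)
}

# Brute-force two-sided exact binomial p-value, written independently of
# the package (explicit binomial coefficients, plain <= comparison).
binom_p_bruteforce <- function(k, n, p0) {
  pmf <- vapply(0:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
                numeric(1))
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Small simulation used by several mapping/pipeline tests.
small_sim_config <- function(seed = 11, ...) {
  sim_config(chrom_lengths = c(chrI = 1e5, chrII = 5e4),
             n_genes = 30, n_strains = 48, seed = seed, ...)
}
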