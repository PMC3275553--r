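test_that("TA index reports all occurrences, case-insensitively", {
  ds <- toy_dataset(c(I = "ATTATA"))
  expect_equal(ds$ta_index$I, c(3L, 5L))
  expect_equal(toy_dataset(c(I = "GGCC"))$ta_index$I, integer(0))
  expect_equal(toy_dataset(c(I = "tata"))$ta_index$I, c(1L, 3L))
})

test_that("TA index matches a regex oracle on random sequences", {
  set.seed(401)
  for (rep in 1:20) {
    seq <- random_dna(500, gc = runif(1, 0.2, 0.7))
    ds <- toy_dataset(c(X = seq))
    expect_equal(ds$ta_index$X, ta_positions_oracle(seq))
    # direct substring check at every reported position
    for (p in ds$ta_index$X) {
      expect_equal(toupper(substr(seq, p, p + 1)), "TA")
    }
  }
})

test_that("coordinate-only datasets refuse TA indexing", {
  ds <- mos_dataset(chrom_lengths = c(I = 1000))
  expect_error(build_ta_index(ds), "coordinate-only")
})

test_that("CDS union merges overlapping intervals and reports the genome fraction", {
  ds <- mos_dataset(
    chrom_lengths = c(I = 100),
    genes = tibble::tibble(gene_id = "g1", chrom = "I", strand = "+",
                           start = 5L, end = 40L, biotype = "protein_coding"),
    cds = tibble::tibble(gene_id = "g1", transcript_id = "g1.1", chrom = "I",
                         start = c(10L, 15L), end = c(20L, 30L))
  )
  cu <- cds_union(ds)
  expect_equal(cu$start, 10L)
  expect_equal(cu$end, 30L)
  expect_equal(sum(cu$end - cu$start + 1), 21L)
  expect_equal(cds_fraction(ds), 0.21)

  # idempotence: the union of the union is itself
  ds2 <- ds
  ds2$cds <- dplyr::mutate(cu, gene_id = "g1", transcript_id = "g1.1")
  expect_equal(cds_union(ds2)[, c("chrom", "start", "end")],
               cu[, c("chrom", "start", "end")])

  # disjoint and sorted on a busier case
  set.seed(77)
  ivs <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.1", chrom = "I",
    start = as.integer(sample(1:80, 20, replace = TRUE))
  )
  ivs$end <- pmin(100L, ivs$start + sample(1:15, 20, replace = TRUE))
  ds$genes$start <- 1L; ds$genes$end <- 100L
  ds$cds <- ivs
  cu2 <- cds_union(ds)
  expect_true(all(diff(cu2$start) > 0))
  expect_true(all(cu2$start[-1] > cu2$end[-nrow(cu2)] + 1L))
})

test_that("empty annotation yields an empty union with fraction zero", {
  ds <- mos_dataset(chrom_lengths = c(I = 100))
  expect_equal(nrow(cds_union(ds)), 0)
  expect_equal(cds_fraction(ds), 0)
})

test_that("load_dataset round-trips FASTA, GFF and allele tables exactly", {
  sc <- sim_config(chrom_lengths = c(chrI = 20000, chrII = 15000),
                   n_genes = 8, n_strains = 24, seed = 5)
  ds <- simulate_genome(sc)
  sim <- simulate_insertions(ds, sc)
  ds$alleles <- sim$alleles

  dir <- withr::local_tempdir()
  fa <- file.path(dir, "g.fa"); gff <- file.path(dir, "g.gff3")
  tsv <- file.path(dir, "a.tsv")
  write_dataset(ds, fa, gff, tsv)
  ds2 <- load_dataset(fa, gff, tsv)

  expect_equal(ds2$chroms, ds$chroms)
  expect_equal(as.character(ds2$seqs), as.character(ds$seqs))
  expect_equal(
    dplyr::arrange(ds2$genes, gene_id),
    dplyr::arrange(ds$genes, gene_id)
  )
  ord <- function(x) dplyr::arrange(x[, c("gene_id", "chrom", "start", "end")],
                                    gene_id, start)
  expect_equal(ord(ds2$exons), ord(ds$exons))
  expect_equal(ord(ds2$cds), ord(ds$cds))
  expect_equal(ds2$alleles, ds$alleles)
  expect_equal(ds2$ta_index, ds$ta_index)
})

test_that("loading a toy FASTA and GFF gives the hand-counted dimensions", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "toy.fa")
  writeLines(c(">A", strrep("ACGT", 25), ">B", strrep("TTAA", 50)), fa)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "A\ttoy\tgene\t10\t60\t.\t+\t.\tID=geneX;biotype=protein_coding",
    "A\ttoy\tmRNA\t10\t60\t.\t+\t.\tID=geneX.1;Parent=geneX",
    "A\ttoy\texon\t10\t30\t.\t+\t.\tParent=geneX.1",
    "A\ttoy\tCDS\t10\t30\t.\t+\t.\tParent=geneX.1"
  ), gff)
  ds <- load_dataset(fa, gff)
  expect_equal(ds$chroms$length, c(100L, 200L))
  expect_equal(nrow(ds$genes), 1)
  expect_equal(ds$genes$gene_id, "geneX")
  expect_equal(ds$cds$start, 10L)

  # empty annotation file: no genes, no error
  empty <- file.path(dir, "empty.gff3")
  writeLines("##gff-version 3", empty)
  ds0 <- load_dataset(fa, empty)
  expect_equal(nrow(ds0$genes), 0)

  # omitted allele table: zero alleles
  expect_equal(nrow(ds$alleles), 0)
})

test_that("allele tables are validated with named records and line numbers", {
  dir <- withr::local_tempdir()
  ds <- toy_dataset(c(I = strrep("ACTA", 250)))

  good <- file.path(dir, "good.tsv")
  writeLines(c("allele_name\tchrom\tposition\tprecise\textra",
               "ttTi1\tI\t100\t1\tx",
               "ttTi2\tI\t200\t0\ty"), good)
  al <- read_allele_table(good)
  expect_equal(al$allele_number, c(1L, 2L))
  expect_equal(al$precise, c(TRUE, FALSE))

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("allele_name\tchrom\tposition\tprecise",
               "ttTi1\tI\tnot_a_number\t1"), bad)
  expect_error(read_allele_table(bad), "line 2")

  # unknown chromosome names the offending allele
  al2 <- al; al2$chrom <- c("I", "nope")
  expect_error(mos_dataset(seqs = c(I = strrep("ACTA", 250)), alleles = al2),
               "ttTi2")

  # out-of-bounds position (TA span must fit)
  al3 <- al; al3$position <- c(100L, 1000L)
  expect_error(mos_dataset(seqs = c(I = strrep("ACTA", 250)), alleles = al3),
               "bounds")

  # unknown prefix warns but parses
  unk <- file.path(dir, "unk.tsv")
  writeLines(c("allele_name\tchrom\tposition\tprecise",
               "zzTi15\tI\t100\t1"), unk)
  expect_warning(parsed <- read_allele_table(unk), "prefix")
  expect_equal(parsed$allele_number, 15L)
})

test_that("allele tables survive a write/read round trip", {
  al <- toy_alleles(c(100, 250, 900), numbers = c(7, 2, 31),
                    plate_id = "P0001")
  al$strain_id <- c("S1", "S2", "S3")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "al.tsv")
  write_allele_table(al, p)
  expect_equal(read_allele_table(p), al)
})
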