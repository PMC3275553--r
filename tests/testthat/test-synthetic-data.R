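test_that("genome generation is byte-deterministic under a fixed seed", {
  sc <- sim_config(chrom_lengths = c(chrI = 20000), n_genes = 4, seed = 99)
  dir <- withr::local_tempdir()
  for (tag in c("a", "b")) {
    ds <- simulate_genome(sc)
    write_dataset(ds, file.path(dir, paste0(tag, ".fa")),
                  file.path(dir, paste0(tag, ".gff3")))
  }
  expect_identical(readLines(file.path(dir, "a.fa")),
                   readLines(file.path(dir, "b.fa")))
  expect_identical(readLines(file.path(dir, "a.gff3")),
                   readLines(file.path(dir, "b.gff3")))
})

test_that("gene models honour the configured structure and do not overlap", {
  sc <- sim_config(chrom_lengths = c(chrI = 50000, chrII = 30000),
                   n_genes = 25, seed = 12)
  ds <- simulate_genome(sc)
  expect_equal(nrow(ds$genes), 25)
  # non-overlap within each chromosome
  by_chrom <- split(ds$genes, ds$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # exons inside their gene span; coding genes have CDS equal to exons
  sp <- dplyr::left_join(ds$exons, ds$genes, by = "gene_id",
                         suffix = c("", ".g"))
  expect_true(all(sp$start >= sp$start.g & sp$end <= sp$end.g))
  pc <- ds$genes$gene_id[ds$genes$biotype == "protein_coding"]
  expect_setequal(unique(ds$cds$gene_id), pc)

  # zero genes is allowed
  ds0 <- simulate_genome(sim_config(chrom_lengths = c(chrI = 2000),
                                    n_genes = 0, seed = 1))
  expect_equal(nrow(ds0$genes), 0)

  # over-dense requests fail with advice
  expect_error(
    simulate_genome(sim_config(chrom_lengths = c(chrI = 1000),
                               n_genes = 40, seed = 1)),
    "density")
})

test_that("insertion counts are Poisson with the configured mean", {
  sc <- sim_config(chrom_lengths = c(chrI = 2e5), n_genes = 0,
                   n_strains = 1000, mean_insertions_per_strain = 2.0,
                   seed = 21)
  ds <- simulate_genome(sc)
  sim <- simulate_insertions(ds, sc)
  # 3 SE band for a Poisson(2) mean over 1000 strains
  expect_lt(abs(mean(sim$strains$n_insertions) - 2.0), 3 * sqrt(2 / 1000))
})

test_that("every simulated insertion is at a TA site and tables are reproducible", {
  sc <- small_sim_config(seed = 31)
  ds <- simulate_genome(sc)
  sim <- simulate_insertions(ds, sc)
  ok <- vapply(seq_len(nrow(sim$truth)), function(i) {
    sim$truth$position[i] %in% ds$ta_index[[sim$truth$chrom[i]]]
  }, logical(1))
  expect_true(all(ok))
  sim2 <- simulate_insertions(ds, sc)
  expect_identical(sim$alleles, sim2$alleles)
  expect_identical(sim$truth, sim2$truth)
})

test_that("strain serials encode plate locality and allele names follow serials", {
  sc <- small_sim_config(seed = 32)
  ds <- simulate_genome(sc)
  sim <- simulate_insertions(ds, sc)
  expect_true(all(sim$strains$well >= 1 & sim$strains$well <= sc$plate_size))
  spread <- tapply(sim$strains$serial, sim$strains$plate_id,
                   function(x) diff(range(x)))
  expect_true(all(spread < sc$plate_size))
  expect_identical(sim$alleles$allele_name,
                   sprintf("ttTi%d", sim$alleles$allele_number))
})

test_that("a heavily weighted hotspot becomes the modal insertion site", {
  sc <- sim_config(chrom_lengths = c(chrI = 5e4), n_genes = 0,
                   n_strains = 400, seed = 41)
  ds <- simulate_genome(sc)
  hot <- ds$ta_index$chrI[10]
  sc$hotspot_sites <- tibble::tibble(chrom = "chrI", position = hot,
                                     weight = 100)
  sim <- simulate_insertions(ds, sc)
  modal <- names(sort(table(sim$truth$position), decreasing = TRUE))[1]
  expect_equal(as.integer(modal), hot)
})

test_that("a genome without TA sites cannot host insertions", {
  ds <- toy_dataset(c(I = strrep("GGCC", 500)))
  sc <- sim_config(chrom_lengths = c(I = 2000), n_strains = 10, seed = 1)
  expect_error(simulate_insertions(ds, sc), "no TA sites")
})

test_that("artifact injection with zero rates leaves the table unchanged", {
  sc <- small_sim_config(seed = 51, resident_fraction = 0,
                         contamination_rate = 0)
  ds <- simulate_genome(sc)
  sim <- simulate_insertions(ds, sc)
  sim2 <- inject_artifacts(sim, ds, sc)
  expect_identical(sim2$alleles, sim$alleles)
  expect_identical(sim2$truth, sim$truth)
})

test_that("resident-insertion carriers appear at the expected binomial rate", {
  sc <- sim_config(chrom_lengths = c(chrI = 2e5), n_genes = 0,
                   n_strains = 1000, seed = 61,
                   resident_fraction = 0.1, contamination_rate = 0)
  ds <- simulate_genome(sc)
  sc$resident_site <- list(chrom = "chrI", position = ds$ta_index$chrI[500])
  sim <- inject_artifacts(simulate_insertions(ds, sc), ds, sc)
  n_res <- sum(sim$alleles$chrom == "chrI" &
                 sim$alleles$position == sc$resident_site$position)
  # 100 +/- 3 * sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(n_res - 100), 28.5)
  # a non-TA resident site is rejected
  sc$resident_site$position <- sc$resident_site$position + 1L
  expect_error(inject_artifacts(simulate_insertions(ds, sc), ds, sc),
               "TA dinucleotide")
})

test_that("contamination duplicates stay within their plate and 25 allele numbers", {
  sc <- sim_config(chrom_lengths = c(chrI = 2e5), n_genes = 0,
                   n_strains = 480, seed = 71,
                   contamination_rate = 0.2)
  ds <- simulate_genome(sc)
  sim <- inject_artifacts(simulate_insertions(ds, sc), ds, sc)
  ev <- sim$artifacts$contamination
  expect_gt(nrow(ev), 10)
  al <- sim$alleles
  src <- al[match(ev$source_name, al$allele_name), ]
  rec <- al[match(ev$recipient_name, al$allele_name), ]
  expect_true(all(src$plate_id == rec$plate_id))
  expect_true(all(abs(src$allele_number - rec$allele_number) < 25))
  # realized events leave the contaminant coordinate in the recipient record
  r <- ev[ev$realized, ]
  rec_r <- al[match(r$recipient_name, al$allele_name), ]
  expect_equal(rec_r$position, r$position)
})

test_that("uniform simulation spreads insertions in proportion to TA counts", {
  sc <- sim_config(chrom_lengths = c(chrI = 1e5, chrII = 6e4, chrIII = 4e4),
                   n_genes = 0, n_strains = 300, seed = 81)
  ds <- simulate_genome(sc)
  sim <- simulate_insertions(ds, sc)
  obs <- table(factor(sim$truth$chrom, levels = names(ds$ta_index)))
  p <- lengths(ds$ta_index) / sum(lengths(ds$ta_index))
  expect_gt(suppressWarnings(stats::chisq.test(obs, p = p)$p.value), 0.001)
})
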