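test_that("enzymes carry the published recognition sites and size thresholds", {
  mboi <- mos_enzyme("MboI")
  hae <- mos_enzyme("haeiii")
  expect_equal(mboi$recognition, "GATC")
  expect_equal(mboi$size_threshold, 270L)
  expect_equal(hae$recognition, "GGCC")
  expect_equal(hae$size_threshold, 325L)
  expect_error(mos_enzyme("EcoRI"), "unknown enzyme")
})

test_that("flank and amplicon lengths follow the junction-to-site formula", {
  # TA at 5, GATC starting exactly at position + 2 = 7
  ds1 <- toy_dataset(c(I = paste0("AAAATAGATC", strrep("A", 20))))
  ins <- tibble::tibble(strain_id = "S1", chrom = "I", position = 5L)
  amp <- predict_amplicons(ds1, ins, "MboI")
  expect_equal(amp$flank_len, 4L)
  expect_equal(amp$amplicon_len, 274L)
  expect_true(amp$passes)  # 274 > 270
  expect_equal(amp$flank_seq, "GATC")

  # GATC site starting 146 bp after the junction -> flank 150, amplicon 420
  ds2 <- toy_dataset(c(I = paste0("AAA", "TA", strrep("C", 146), "GATC",
                                  strrep("A", 30))))
  amp2 <- predict_amplicons(ds2,
                            tibble::tibble(strain_id = "S1", chrom = "I",
                                           position = 4L), "MboI")
  expect_equal(amp2$flank_len, 150L)
  expect_equal(amp2$amplicon_len, 420L)
  expect_true(amp2$passes)
  expect_equal(nchar(amp2$flank_seq), 150L)

  # no recognition site downstream -> no amplicon
  ds3 <- toy_dataset(c(I = paste0("AAATA", strrep("C", 100))))
  amp3 <- predict_amplicons(ds3,
                            tibble::tibble(strain_id = "S1", chrom = "I",
                                           position = 4L), "MboI")
  expect_equal(nrow(amp3), 0)

  # two insertions with downstream sites -> two amplicons (multiple bands)
  ds4 <- toy_dataset(c(I = paste0("AATA", strrep("C", 50), "GATC",
                                  strrep("A", 5), "TA", strrep("C", 20),
                                  "GATC", strrep("A", 10))))
  ins4 <- tibble::tibble(strain_id = "S1", chrom = "I",
                         position = c(3L, 63L))
  expect_equal(nrow(predict_amplicons(ds4, ins4, "MboI")), 2)
})

test_that("the passes flag is strictly amplicon_len > threshold", {
  set.seed(202)
  ds <- toy_dataset(c(I = random_dna(20000)))
  ins <- tibble::tibble(strain_id = sprintf("S%d", seq_along(ds$ta_index$I)),
                        chrom = "I", position = ds$ta_index$I)
  for (enz in list(mos_enzyme("MboI"), mos_enzyme("HaeIII"))) {
    amp <- predict_amplicons(ds, ins, enz)
    expect_equal(amp$passes, amp$amplicon_len > enz$size_threshold)
    expect_true(all(amp$flank_len >= 4))
    expect_equal(amp$amplicon_len, amp$flank_len + enz$primer_offset)
  }
})

test_that("band selection keeps the shortest passing amplicon per strain", {
  amp <- tibble::tibble(
    strain_id = c("S1", "S1", "S2", "S3"),
    chrom = "I", position = c(10L, 500L, 20L, 30L),
    enzyme = "MboI", site_start = 0L,
    flank_len = c(130L, 330L, 40L, 10L),
    amplicon_len = c(400L, 600L, 310L, 280L),
    passes = c(TRUE, TRUE, TRUE, TRUE),
    flank_seq = "N"
  )
  sel <- select_band(amp)
  expect_equal(sel$amplicon_len[sel$strain_id == "S1"], 400L)
  expect_equal(nrow(sel), 3)

  # sub-threshold bands are never selected: with a shorter transposon-side
  # contribution, a 250-bp amplicon fails the 270-bp MboI limit
  short_enz <- structure(list(name = "MboI", recognition = "GATC",
                              size_threshold = 270L, primer_offset = 100L),
                         class = "mos_enzyme")
  ds <- toy_dataset(c(I = paste0("AAAATAGATC", strrep("A", 300))))
  ins <- tibble::tibble(strain_id = "S1", chrom = "I", position = 5L)
  amp2 <- predict_amplicons(ds, ins, short_enz)
  expect_false(amp2$passes)  # 100 + 4 = 104 <= 270
  expect_equal(nrow(select_band(amp2)), 0)

  # ties broken by lower (chrom, position)
  tie <- amp[c(1, 1), ]
  tie$position <- c(50L, 10L)
  expect_equal(select_band(tie)$position, 10L)
})

test_that("noiseless flank reads equal the genomic substring exactly", {
  set.seed(203)
  seq <- random_dna(30000)
  ds <- toy_dataset(c(I = seq))
  ins <- tibble::tibble(strain_id = sprintf("S%d", 1:20), chrom = "I",
                        position = sample(ds$ta_index$I, 20))
  bands <- select_band(predict_amplicons(ds, ins, "MboI"))
  reads <- extract_flanks(bands, ds, q_jitter = 0, q_fail = 0, seed = 9)
  expect_false(any(reads$failed))
  expect_equal(reads$reported_junction_offset, rep(0L, nrow(reads)))
  manual <- substr(rep(seq, nrow(bands)), bands$position + 2,
                   bands$position + 1 + bands$flank_len)
  expect_equal(reads$sequence, manual)
})

test_that("junction jitter is bounded by the jitter radius", {
  set.seed(204)
  ds <- toy_dataset(c(I = random_dna(30000)))
  ins <- tibble::tibble(strain_id = sprintf("S%d", 1:30), chrom = "I",
                        position = sample(ds$ta_index$I[ds$ta_index$I > 50], 30))
  bands <- select_band(predict_amplicons(ds, ins, "MboI"))
  reads <- extract_flanks(bands, ds, q_jitter = 1, q_fail = 0, seed = 10)
  expect_true(all(abs(reads$reported_junction_offset) <= 10))
  # the read really is the shifted substring
  seq <- as.character(ds$seqs[[1]])
  shifted <- substr(rep(seq, nrow(bands)),
                    bands$position + 2 + reads$reported_junction_offset,
                    bands$position + 1 + reads$reported_junction_offset +
                      bands$flank_len)
  expect_equal(reads$sequence, shifted)

  # q_fail = 1 marks every read unusable
  fails <- extract_flanks(bands, ds, q_fail = 1, seed = 11)
  expect_true(all(fails$failed))
  expect_true(all(is.na(fails$sequence)))
})

test_that("denser recognition sites never lengthen the mean flank", {
  set.seed(205)
  base <- random_dna(20000, gc = 0.45)
  # spike GATC every 150 bp
  spiked <- base
  for (s in seq(100, 19900, by = 150)) {
    substr(spiked, s, s + 3) <- "GATC"
  }
  ds_base <- toy_dataset(c(I = base))
  ds_spiked <- toy_dataset(c(I = spiked))
  common <- intersect(ds_base$ta_index$I, ds_spiked$ta_index$I)
  ins <- tibble::tibble(strain_id = sprintf("S%d", seq_along(common)),
                        chrom = "I", position = common)
  m1 <- mean(predict_amplicons(ds_base, ins, "MboI")$flank_len)
  m2 <- mean(predict_amplicons(ds_spiked, ins, "MboI")$flank_len)
  expect_lte(m2, m1)
})
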