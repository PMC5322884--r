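small_config <- function(seed = 1, ...) {
  generator_config(seed = seed, n_full_gpcr = 6, n_partial_gpcr = 6,
                   n_membrane_decoy = 6, n_soluble_decoy = 6, ...)
}

test_that("generated proteins carry the requested architecture", {
  set.seed(71)
  cfg <- generator_config()
  full <- generate_protein("FULL_GPCR", cfg)
  expect_equal(nrow(full$helix_segments), 7)
  seg <- full$helix_segments
  lens <- seg$end - seg$start
  expect_true(all(lens >= 19 & lens <= 25))
  expect_true(all(seg$start[-1] > seg$end[-7]))
  # helix blocks are drawn from the hydrophobic alphabet
  res <- strsplit(full$aa_seq, "")[[1]]
  for (i in 1:7) {
    block <- res[(seg$start[i] + 1):seg$end[i]]
    expect_true(all(block %in% c("L", "I", "V", "F", "M", "A", "W")))
  }

  memb <- generate_protein("MEMBRANE_DECOY", cfg)
  expect_true(nrow(memb$helix_segments) %in% c(1:5, 9:11))

  sol <- generate_protein("SOLUBLE_DECOY", cfg)
  expect_equal(nrow(sol$helix_segments), 0)
  expect_equal(predict_tm_hydropathy(sol$aa_seq)$n_helices, 0L)
})

test_that("same seed gives identical proteins and datasets", {
  set.seed(5); p1 <- generate_protein("FULL_GPCR", generator_config())
  set.seed(5); p2 <- generate_protein("FULL_GPCR", generator_config())
  expect_identical(p1, p2)

  d1 <- generate_dataset(small_config(seed = 42))
  d2 <- generate_dataset(small_config(seed = 42))
  expect_identical(d1$unigenes, d2$unigenes)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(small_config(seed = 43))
  expect_false(identical(d1$unigenes, d3$unigenes))
})

test_that("reverse_translate is an exact right inverse of translation", {
  set.seed(72)
  expect_equal(reverse_translate("M"), "ATG")
  expect_error(reverse_translate("MXK"), "non-standard")
  for (rep in 1:10) {
    prot <- paste(sample(aa_alphabet(), 80, replace = TRUE), collapse = "")
    cds <- reverse_translate(prot)
    expect_equal(nchar(cds), 240)
    expect_equal(oracle_translate(cds), prot)
    expect_false(grepl("\\*", oracle_translate(cds)))
  }
})

test_that("synonymous codon choice is close to uniform", {
  set.seed(73)
  # leucine has six codons; draw many and compare to the uniform expectation
  draws <- table(vapply(1:6000, function(i) {
    substr(reverse_translate("L"), 1, 3)
  }, ""))
  expect_equal(length(draws), 6)
  p <- stats::chisq.test(draws)$p.value
  expect_gt(p, 0.001)
})

test_that("built unigenes satisfy the planted stop-codon contract", {
  set.seed(74)
  cfg <- generator_config()
  for (rep in 1:10) {
    prot <- generate_protein("FULL_GPCR", cfg)
    built <- build_unigene(reverse_translate(prot$aa_seq), "FULL_GPCR", cfg,
                           unigene_id = "u", helix_segments =
                             prot$helix_segments)
    tr <- built$truth
    orfs <- find_orfs(built$seq, "u")
    hit <- orfs[orfs$nt_start == tr$cds_start & orfs$nt_end == tr$cds_end, ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$strand, tr$strand)
    expect_equal(hit$frame, tr$frame)
    expect_equal(hit$length_aa, tr$length_aa)
    expect_equal(hit$aa_seq, prot$aa_seq)
    expect_gte(hit$upstream_stops, 2)
    expect_gte(hit$downstream_stops, 2)
  }
})

test_that("partial variants lose the stops on exactly one flank", {
  set.seed(75)
  cfg <- generator_config()
  for (rep in 1:10) {
    prot <- generate_protein("PARTIAL_GPCR", cfg)
    built <- build_unigene(reverse_translate(prot$aa_seq), "PARTIAL_GPCR",
                           cfg, unigene_id = "u",
                           helix_segments = prot$helix_segments)
    tr <- built$truth
    expect_false(tr$flanking_stops_ok)
    orfs <- find_orfs(built$seq, "u")
    hit <- orfs[orfs$nt_start == tr$cds_start & orfs$nt_end == tr$cds_end, ]
    expect_equal(nrow(hit), 1)
    one_side_zero <- xor(hit$upstream_stops == 0, hit$downstream_stops == 0)
    expect_true(one_side_zero)
    expect_lt(tr$length_aa, nchar(prot$aa_seq))
  }
})

test_that("truth rows always locate an ORF that find_orfs emits", {
  ds <- generate_dataset(small_config(seed = 77))
  expect_equal(nrow(ds$truth), 24)
  expect_equal(as.vector(table(ds$truth$label)[c("FULL_GPCR", "PARTIAL_GPCR",
                                                 "MEMBRANE_DECOY",
                                                 "SOLUBLE_DECOY")]),
               rep(6L, 4))
  orfs <- find_orfs_set(ds$unigenes)
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    if (tr$length_aa < 50) next  # below the reporting threshold
    hit <- orfs[orfs$unigene_id == tr$unigene_id &
                  orfs$nt_start == tr$cds_start &
                  orfs$nt_end == tr$cds_end &
                  orfs$strand == tr$strand, ]
    expect_equal(nrow(hit), 1, info = tr$unigene_id)
  }
  # both strands occur
  expect_true(all(c(1L, -1L) %in% ds$truth$strand))
})

test_that("antisense placement is recovered with strand -1", {
  set.seed(78)
  cfg <- generator_config(antisense_fraction = 1)
  prot <- generate_protein("FULL_GPCR", cfg)
  built <- build_unigene(reverse_translate(prot$aa_seq), "FULL_GPCR", cfg,
                         unigene_id = "anti",
                         helix_segments = prot$helix_segments)
  expect_equal(built$truth$strand, -1L)
  orfs <- find_orfs(built$seq, "anti")
  hit <- orfs[orfs$strand == -1 & orfs$aa_seq == prot$aa_seq, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length_aa, nchar(prot$aa_seq))
})

test_that("dataset writing is byte-identical across runs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  out1 <- generate_dataset(small_config(seed = 9), out_dir = d1)
  out2 <- generate_dataset(small_config(seed = 9), out_dir = d2)
  for (f in c("unigenes.fasta", "truth.tsv", "tmhmm_emulated.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_error(generate_dataset(generator_config(n_full_gpcr = 0,
                                                 n_partial_gpcr = 0,
                                                 n_membrane_decoy = 0,
                                                 n_soluble_decoy = 0)),
               "zero total count")
})

test_that("emulated topology reflects planted helix counts", {
  ds <- generate_dataset(small_config(seed = 13))
  orfs <- find_orfs_set(ds$unigenes)
  recs <- emulate_tmhmm_records(orfs, ds$truth)
  expect_setequal(names(recs), orfs$orf_id)
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    if (tr$label != "FULL_GPCR") next
    hit <- orfs[orfs$unigene_id == tr$unigene_id &
                  orfs$nt_start == tr$cds_start &
                  orfs$nt_end == tr$cds_end, ]
    expect_equal(recs[[hit$orf_id]]$predicted_helices, tr$true_n_helices)
  }
})

test_that("hydropathy caller sees the planted architecture", {
  # with loops wide enough for the window to resolve (>= 10 aa), the caller
  # recovers exactly seven helices in nearly every draw
  set.seed(79)
  cfg_wide <- generator_config(loop_len_range = c(10L, 30L))
  hits <- vapply(1:100, function(i) {
    predict_tm_hydropathy(generate_protein("FULL_GPCR",
                                           cfg_wide)$aa_seq)$n_helices
  }, 1L)
  expect_gte(sum(hits == 7), 90)

  # under the default 5-30 aa loops, loops shorter than about half a window
  # fuse adjacent helices, so counts land in 5-7 (the long-candidate band
  # still captures single fusions)
  set.seed(80)
  cfg <- generator_config()
  hits_def <- vapply(1:100, function(i) {
    predict_tm_hydropathy(generate_protein("FULL_GPCR", cfg)$aa_seq)$n_helices
  }, 1L)
  expect_gte(sum(hits_def >= 5 & hits_def <= 7), 90)

  set.seed(81)
  sol <- vapply(1:100, function(i) {
    predict_tm_hydropathy(generate_protein("SOLUBLE_DECOY",
                                           cfg)$aa_seq)$n_helices
  }, 1L)
  expect_gte(sum(sol == 0), 95)
})
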