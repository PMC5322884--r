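test_that("read_fasta uppercases, splits headers and validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">u1 some description", "acgt", ">u2", "NNAC", "GT"), f)
  x <- read_fasta(f)
  expect_equal(names(x), c("u1", "u2"))
  expect_equal(as.character(x), c(u1 = "ACGT", u2 = "NNACGT"))
  expect_equal(S4Vectors::mcols(x)$description, c("some description", ""))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "no FASTA records")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(read_fasta(dup), "duplicate id.*a")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACXGT"), bad)
  expect_error(read_fasta(bad), "non-IUPAC character 'X' at position 3")
})

test_that("write_fasta then read_fasta round-trips sequences", {
  set.seed(11)
  seqs <- setNames(vapply(1:5, function(i) random_dna(sample(50:200, 1)),
                          ""), paste0("s", 1:5))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(as.character(back), seqs)
})

test_that("parse_tmhmm reads long format and validates tiling", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "# p1 Length: 60",
    "# p1 Number of predicted TMHs:  1",
    "p1\tTMHMM2.0\toutside\t1\t10",
    "p1\tTMHMM2.0\tTMhelix\t11\t33",
    "p1\tTMHMM2.0\tinside\t34\t60"
  ), f)
  rec <- parse_tmhmm(f)
  expect_equal(rec$p1$predicted_helices, 1L)
  expect_equal(rec$p1$length, 60L)
  expect_equal(rec$p1$segments$kind, c("outside", "TMhelix", "inside"))
  # tiling: segment lengths sum to protein length
  expect_equal(sum(rec$p1$segments$end - rec$p1$segments$start + 1), 60)

  # seven helices
  f7 <- withr::local_tempfile(fileext = ".txt")
  seg <- character(0)
  pos <- 1
  for (h in 1:7) {
    seg <- c(seg, sprintf("q\tTMHMM2.0\toutside\t%d\t%d", pos, pos + 9),
             sprintf("q\tTMHMM2.0\tTMhelix\t%d\t%d", pos + 10, pos + 30))
    pos <- pos + 31
  }
  seg <- c(seg, sprintf("q\tTMHMM2.0\tinside\t%d\t%d", pos, pos + 4))
  writeLines(seg, f7)
  expect_equal(parse_tmhmm(f7)$q$predicted_helices, 7L)

  # gap detection and count mismatch
  fg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("p\tTMHMM2.0\toutside\t1\t10", "p\tTMHMM2.0\tinside\t12\t20"),
             fg)
  expect_error(parse_tmhmm(fg), "gap/overlap")
  fm <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# p Number of predicted TMHs: 2",
               "p\tTMHMM2.0\toutside\t1\t10",
               "p\tTMHMM2.0\tTMhelix\t11\t30",
               "p\tTMHMM2.0\tinside\t31\t40"), fm)
  expect_error(parse_tmhmm(fm), "declared TMH count")
})

test_that("synthetic TMHMM writer round-trips through the parser", {
  set.seed(5)
  cfg <- generator_config(seed = 5, n_full_gpcr = 3, n_partial_gpcr = 2,
                          n_membrane_decoy = 2, n_soluble_decoy = 2)
  ds <- generate_dataset(cfg)
  orfs <- find_orfs_set(ds$unigenes)
  recs <- emulate_tmhmm_records(orfs, ds$truth)
  f <- withr::local_tempfile(fileext = ".txt")
  write_tmhmm(recs, f)
  back <- parse_tmhmm(f)
  expect_equal(length(back), length(recs))
  for (id in names(recs)) {
    expect_equal(back[[id]]$predicted_helices, recs[[id]]$predicted_helices)
    expect_equal(back[[id]]$segments$start, recs[[id]]$segments$start)
    expect_equal(back[[id]]$segments$end, recs[[id]]$segments$end)
    expect_equal(back[[id]]$segments$kind, recs[[id]]$segments$kind)
  }
})

test_that("parse_hits_table filters strictly below the cutoff", {
  mk_line <- function(q, s, ev, bs, desc = NULL) {
    base <- paste(c(q, s, "90.0", "100", "10", "0", "1", "100", "1", "100",
                    format(ev), format(bs)), collapse = "\t")
    if (!is.null(desc)) base <- paste(base, desc, sep = "\t") else base
  }
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(mk_line("q1", "s1", 1e-07, 200, "a receptor"),
               mk_line("q2", "s2", 1e-06, 180),
               mk_line("q3", "s3", 0.5, 40)), f)
  hits <- parse_hits_table(f, 1e-06)
  expect_equal(hits$query_id, "q1")           # 1e-06 itself is dropped
  expect_equal(hits$description, "a receptor")

  # cutoff = Inf returns every row
  expect_equal(nrow(parse_hits_table(f, Inf)), 3)

  # random table equals a brute-force filter, order preserved
  set.seed(21)
  ev <- 10^stats::runif(100, -12, 1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(vapply(seq_along(ev), function(i)
    mk_line(paste0("q", i), "s", ev[i], 50), ""), f2)
  got <- parse_hits_table(f2, 1e-06)
  expect_equal(got$query_id, paste0("q", which(ev < 1e-06)))

  fbad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(mk_line("q1", "s1", 1e-07, 200),
               gsub("1e-07", "oops", mk_line("q2", "s2", 1e-07, 10))), fbad)
  expect_error(parse_hits_table(fbad), "line 2")
})

test_that("read_model_chain parses coordinates and HELIX records", {
  ch <- build_helix_chain(26, helix_annotations = data.frame(start = 5L,
                                                             end = 25L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model_chain(ch, f)
  back <- read_model_chain(f)
  expect_equal(nrow(back$residues), 26)
  expect_equal(back$helix_annotations, data.frame(start = 5L, end = 25L))
  # CA-CA distances of an ideal alpha helix are ~3.8 A
  ca <- as.matrix(back$residues[, c("ca_x", "ca_y", "ca_z")])
  d <- sqrt(rowSums((ca[-1, ] - ca[-nrow(ca), ])^2))
  expect_true(all(abs(d - 3.8) < 0.05))

  fe <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  N   ALA A   1      bad coords here", "END"), fe)
  expect_error(read_model_chain(fe), "malformed ATOM line 1")
})
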