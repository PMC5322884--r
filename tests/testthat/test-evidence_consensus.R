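make_records <- function(...) do.call(rbind, list(...))

test_that("aggregate_evidence builds codes in fixed T,A,G,P order", {
  rec <- make_records(
    evidence_record("orf1", "TMHMM", TRUE),
    evidence_record("orf1", "GPCRPRED", TRUE, "A", "Peptide"),
    evidence_record("orf1", "PCAGPCR", TRUE, "A", "Peptide"),
    evidence_record("orf2", "PCAGPCR", TRUE, "A", "Amine"),
    evidence_record("orf2", "ALIGNMENT", TRUE),
    evidence_record("orf3", "TMHMM", FALSE)
  )
  cons <- aggregate_evidence(rec)
  expect_equal(cons$pred_by_code[cons$orf_id == "orf1"], "TGP")
  expect_equal(cons$n_sources[cons$orf_id == "orf1"], 3)
  expect_equal(cons$pred_by_code[cons$orf_id == "orf2"], "AP")
  expect_true(cons$subfamily_consistent[cons$orf_id == "orf1"])
  # no positive record: n_sources 0, excluded from candidate sets
  expect_equal(cons$n_sources[cons$orf_id == "orf3"], 0)
  expect_equal(nrow(basic_set(cons, 1)), 2)

  all4 <- aggregate_evidence(make_records(
    evidence_record("x", "TMHMM", TRUE), evidence_record("x", "ALIGNMENT", TRUE),
    evidence_record("x", "GPCRPRED", TRUE), evidence_record("x", "PCAGPCR", TRUE)))
  expect_equal(all4$pred_by_code, "TAGP")

  bad <- evidence_record("y", "TMHMM", TRUE)
  bad$source <- "WRONG"
  expect_error(aggregate_evidence(bad), "unknown source")
})

test_that("any positive record makes an approach positive", {
  rec <- make_records(
    evidence_record("o", "ALIGNMENT", FALSE, detail = "hit1"),
    evidence_record("o", "ALIGNMENT", TRUE, detail = "hit2"),
    evidence_record("o", "ALIGNMENT", FALSE, detail = "hit3")
  )
  cons <- aggregate_evidence(rec)
  expect_equal(cons$pred_by_code, "A")
})

test_that("basic_set is anti-monotone in its threshold", {
  set.seed(51)
  recs <- list()
  for (i in 1:60) {
    srcs <- sample(names(consensus_approaches()), sample(0:4, 1))
    for (s in srcs) {
      recs[[length(recs) + 1]] <- evidence_record(sprintf("o%02d", i), s, TRUE)
    }
  }
  cons <- aggregate_evidence(do.call(rbind, recs))
  for (k in 1:3) {
    hi <- basic_set(cons, k + 1)$orf_id
    lo <- basic_set(cons, k)$orf_id
    expect_true(all(hi %in% lo))
  }
  # code is a function of sources: recomputing from n_sources letters agrees
  expect_true(all(nchar(cons$pred_by_code) == cons$n_sources))
})

test_that("venn partition is a partition matching a brute-force tally", {
  set.seed(52)
  recs <- list()
  truth <- character(0)
  for (i in 1:500) {
    srcs <- sample(names(consensus_approaches()), sample(0:4, 1))
    id <- sprintf("v%03d", i)
    code <- paste(consensus_approaches()[
      names(consensus_approaches()) %in% srcs], collapse = "")
    if (length(srcs) > 0) truth[id] <- code
    for (s in srcs) recs[[length(recs) + 1]] <- evidence_record(id, s, TRUE)
    if (length(srcs) == 0) {
      recs[[length(recs) + 1]] <- evidence_record(id, "TMHMM", FALSE)
    }
  }
  cons <- aggregate_evidence(do.call(rbind, recs))
  venn <- venn_partition(cons)
  expect_equal(length(venn), 15)
  expect_equal(sum(venn), sum(cons$n_sources >= 1))
  brute <- table(truth)
  for (region in names(venn)) {
    expect_equal(unname(venn[region]),
                 if (region %in% names(brute)) unname(as.integer(brute[region]))
                 else 0L, info = region)
  }
  # single positive approach
  single <- aggregate_evidence(evidence_record("z", "TMHMM", TRUE))
  v1 <- venn_partition(single)
  expect_equal(unname(v1["T"]), 1L)
  expect_equal(sum(v1), 1L)
})

test_that("subfamily normalization and consistency follow the stated rules", {
  expect_true(is_consistent("(Rhod)opsin", "Rhodopsin"))
  expect_false(is_consistent("GABAB", "-"))
  expect_false(is_consistent("Peptide", "Nucleotide-like"))
  expect_false(is_consistent(NA, "Peptide"))
  expect_equal(normalize_subfamily(c("(Rhod)opsin", "NA", "-", "Peptide")),
               c("rhodopsin", NA, NA, "peptide"))
})

test_that("the bundled consensus table reproduces the published counts", {
  ev <- read_consensus_fixture(fixture_path("tick_foreleg_consensus.tsv"))
  cons <- aggregate_evidence(ev)
  expect_equal(nrow(cons), 46)
  b3 <- basic_set(cons, 3)
  expect_equal(nrow(b3), 46)
  expect_equal(basic_set(cons, 4)$orf_id,
               "athaller1175_662(length)_1(strand)_1(frame)")
  rep_t <- consistency_report(b3)
  expect_equal(rep_t$count, 17)
  expect_equal(rep_t$breakdown[c("peptide", "rhodopsin", "olfactory")],
               c(peptide = 10L, rhodopsin = 5L, olfactory = 2L))
  rep_all <- consistency_report(b3, require_tmhmm = FALSE)
  expect_equal(rep_all$count, 18)
  # the extra row is the peptide/peptide candidate without topology support
  expect_equal(setdiff(rep_all$orf_ids, rep_t$orf_ids),
               "athaller1224_421(length)_1(strand)_0(frame)")
})

test_that("keyword screening matches terms case-insensitively", {
  ann <- data.frame(
    id = c("a1", "a2", "a3"),
    description = c("G protein coupled receptor activity",
                    "Adenylate cyclase terminal differentiation specific",
                    "ribosomal protein L7"),
    stringsAsFactors = FALSE
  )
  syn <- keyword_screen(ann, load_gpcr_synonym_terms())
  expect_true("a1" %in% syn$id)
  expect_false("a3" %in% syn$id)
  rel <- keyword_screen(ann, load_gpcr_related_terms())
  expect_true("a2" %in% rel$id)
  expect_equal(rel$protein_type[rel$id == "a2"], "Adenylate Cyclase")
  expect_false("a3" %in% rel$id)
  expect_error(keyword_screen(ann, character(0)), "empty term list")
  # receptor prefilter drops non-receptor descriptions before matching
  pre <- keyword_screen(ann, load_gpcr_synonym_terms(),
                        prefilter_receptor = TRUE)
  expect_equal(unique(pre$id), "a1")
})
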