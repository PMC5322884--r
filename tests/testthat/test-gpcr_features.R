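test_that("amino-acid composition matches brute-force counting", {
  x <- aa_composition("AAA")
  expect_equal(unname(x["A"]), 1)
  expect_equal(sum(x), 1)
  y <- aa_composition("ACDEFGHIKLMNPQRSTVWY")
  expect_equal(unname(y), rep(0.05, 20))
  expect_error(aa_composition("XXXB"), "no standard residues")

  set.seed(31)
  seq <- paste(sample(c(aa_alphabet(), "X"), 500, replace = TRUE),
               collapse = "")
  got <- aa_composition(seq)
  res <- strsplit(seq, "")[[1]]
  res <- res[res != "X"]
  for (a in aa_alphabet()) {
    expect_equal(unname(got[a]), sum(res == a) / length(res))
  }
})

test_that("dipeptide composition matches brute-force counting", {
  x <- dipeptide_composition("AAA")
  expect_equal(unname(x["AA"]), 1)
  y <- dipeptide_composition("ACA")
  expect_equal(unname(y[c("AC", "CA")]), c(0.5, 0.5))
  expect_equal(sum(y), 1)
  expect_error(dipeptide_composition("A"), "length >= 2")

  set.seed(32)
  seq <- paste(sample(aa_alphabet(), 300, replace = TRUE), collapse = "")
  got <- dipeptide_composition(seq)
  res <- strsplit(seq, "")[[1]]
  pairs <- paste0(res[-300], res[-1])
  expect_equal(sum(got), 1)
  for (p in sample(names(got), 40)) {
    expect_equal(unname(got[p]), sum(pairs == p) / length(pairs))
  }
})

test_that("PseAAC collapses to AAC at lambda 0 and matches a straight-line
          reimplementation", {
  seq <- "MKTLIVFAGLLGSVWAQSDE"
  expect_equal(pseudo_aa_composition(seq, lambda = 0), aa_composition(seq))
  expect_error(pseudo_aa_composition("ACDEF", lambda = 10), "exceed lambda")

  # independent straight-line implementation of the type-1 formula
  set.seed(33)
  seq <- paste(sample(aa_alphabet(), 50, replace = TRUE), collapse = "")
  lambda <- 3; w <- 0.05
  norm <- function(v) {
    v <- v[aa_alphabet()]
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / 20)
  }
  h1 <- norm(aa_property_table("kd"))
  h2 <- norm(aa_property_table("hydrophilicity"))
  h3 <- norm(aa_property_table("mass"))
  res <- strsplit(seq, "")[[1]]
  theta <- numeric(lambda)
  for (k in 1:lambda) {
    s <- 0
    for (i in 1:(50 - k)) {
      a <- res[i]; b <- res[i + k]
      s <- s + ((h1[b] - h1[a])^2 + (h2[b] - h2[a])^2 + (h3[b] - h3[a])^2) / 3
    }
    theta[k] <- s / (50 - k)
  }
  f <- as.numeric(table(factor(res, levels = aa_alphabet()))) / 50
  want <- c(f, w * theta) / (1 + w * sum(theta))
  got <- pseudo_aa_composition(seq, lambda = lambda, w = w)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-9)
})

test_that("autocorrelation and CTD match brute-force references", {
  set.seed(34)
  seq <- paste(sample(aa_alphabet(), 200, replace = TRUE), collapse = "")
  got <- autocorrelation(seq, max_lag = 10)
  kd <- aa_property_table("kd")
  p <- (kd - mean(kd)) / sd(kd)
  x <- p[strsplit(seq, "")[[1]]]
  for (d in 1:10) {
    expect_equal(unname(got[d]),
                 sum(x[1:(200 - d)] * x[(1 + d):200]) / (200 - d))
  }
  expect_error(autocorrelation("ACDEF", max_lag = 30), "exceed max_lag")

  # homopolymer: every transition descriptor is zero
  ctd_h <- ctd_descriptors(strrep("A", 50))
  expect_true(all(ctd_h[grepl("trans", names(ctd_h))] == 0))
  # composition blocks each sum to 1
  ctd <- ctd_descriptors(seq)
  expect_equal(length(ctd), 147)
  for (prop in c("hydrophobicity", "charge", "polarity")) {
    block <- ctd[grepl(paste0("^", prop, "\\.comp"), names(ctd))]
    expect_equal(sum(block), 1)
  }
  # brute-force check of one transition entry
  groups <- list(polar = c("R", "K", "E", "D", "Q", "N"),
                 neutral = c("G", "A", "S", "T", "P", "H", "Y"),
                 hydrophobic = c("C", "L", "V", "I", "M", "F", "W"))
  res <- strsplit(seq, "")[[1]]
  cls <- ifelse(res %in% groups$polar, 1,
                ifelse(res %in% groups$neutral, 2, 3))
  t12 <- sum((cls[-200] == 1 & cls[-1] == 2) |
               (cls[-200] == 2 & cls[-1] == 1)) / 199
  expect_equal(unname(ctd["hydrophobicity.trans.12"]), t12)
})

test_that("quasi-sequence-order matches a brute-force reference", {
  set.seed(35)
  seq <- paste(sample(aa_alphabet(), 120, replace = TRUE), collapse = "")
  got <- quasi_sequence_order(seq, max_lag = 5, w = 0.1)
  expect_equal(length(got), 25)
  dm <- default_residue_distance()
  res <- strsplit(seq, "")[[1]]
  tau <- numeric(5)
  for (d in 1:5) {
    s <- 0
    for (i in 1:(120 - d)) s <- s + dm[res[i], res[i + d]]^2
    tau[d] <- s
  }
  f <- as.numeric(table(factor(res, levels = aa_alphabet()))) / 120
  want <- c(f, 0.1 * tau) / (1 + 0.1 * sum(tau))
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("descriptors depend only on sequence content, with fixed dims", {
  set.seed(36)
  seqs <- setNames(vapply(1:4, function(i)
    paste(sample(aa_alphabet(), sample(60:120, 1), replace = TRUE),
          collapse = ""), ""), paste0("s", 1:4))
  fm <- feature_matrix(seqs, blocks = c("aac", "dpc", "pseaac"))
  expect_equal(dim(fm), c(4, 20 + 400 + 30))
  expect_false(anyNA(fm))
  # same sequence, different id: identical row
  fm2 <- feature_matrix(setNames(seqs[1], "other"), blocks = c("aac", "dpc",
                                                               "pseaac"))
  expect_equal(unname(fm2[1, ]), unname(fm[1, ]))
})

test_that("the stand-in classifier is deterministic and separates centroids", {
  set.seed(37)
  x <- rbind(matrix(rnorm(40 * 5, 0), 40), matrix(rnorm(40 * 5, 4), 40))
  colnames(x) <- paste0("f", 1:5)
  labels <- rep(c("A", "none"), each = 40)
  model <- train_standin_classifier(x, labels, seed = 1)
  pred <- predict(model, x)
  expect_equal(mean(pred$label == labels), 1)  # separable by construction
  expect_true(all(pred$confidence >= 0 & pred$confidence <= 1))
  expect_true(all(is.na(pred$gpcr_class[!pred$is_gpcr])))

  # permuting training rows leaves predictions unchanged
  perm <- sample(80)
  model2 <- train_standin_classifier(x[perm, ], labels[perm], seed = 99)
  pred2 <- predict(model2, x)
  expect_equal(pred2$label, pred$label)
  expect_equal(pred2$confidence, pred$confidence)

  expect_error(train_standin_classifier(x, rep("A", 80)), "2 classes")
})

test_that("classifier JSON save/load round-trips predictions", {
  set.seed(38)
  x <- rbind(matrix(rnorm(20 * 3, 0), 20), matrix(rnorm(20 * 3, 3), 20))
  colnames(x) <- c("u", "v", "w")
  model <- train_standin_classifier(x, rep(c("A", "none"), each = 20))
  f <- withr::local_tempfile(fileext = ".json")
  save_classifier(model, f)
  back <- load_classifier(f)
  expect_equal(predict(back, x), predict(model, x), tolerance = 1e-12)
})
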