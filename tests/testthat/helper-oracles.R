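# Independent brute-force oracles and small generators used across tests.
# These deliberately avoid the package's own code paths: plain loops, their
# own reverse-complement, and their own run-scanning.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# plain codon-by-codon translation (standard code via Biostrings table, but
# looked up one codon at a time in a loop)
oracle_translate <- function(seq) {
  code <- Biostrings::getGeneticCode("1")
  n <- nchar(seq) %/% 3
  out <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(seq, 3 * i - 2, 3 * i)
    aa <- code[codon]
    out[i] <- if (is.na(aa)) "X" else aa
  }
  paste(out, collapse = "")
}

# exhaustive six-frame scan for maximal stop-free runs >= min_aa, with
# flanking stop counts and forward-strand coordinates
oracle_orfs <- function(seq, min_aa = 50) {
  L <- nchar(seq)
  rows <- list()
  for (strand in c(1L, -1L)) {
    oriented <- if (strand == 1L) seq else oracle_revcomp(seq)
    for (frame in 0:2) {
      prot <- oracle_translate(substr(oriented, frame + 1, L))
      aa <- strsplit(prot, "", fixed = TRUE)[[1]]
      i <- 1
      while (i <= length(aa)) {
        if (aa[i] != "*") {
          j <- i
          while (j < length(aa) && aa[j + 1] != "*") j <- j + 1
          if (j - i + 1 >= min_aa) {
            start_o <- frame + 3 * (i - 1)
            end_o <- frame + 3 * j
            before <- aa[seq_len(i - 1)]
            after <- if (j < length(aa)) aa[(j + 1):length(aa)] else character(0)
            rows[[length(rows) + 1]] <- data.frame(
              strand = strand, frame = frame,
              nt_start = if (strand == 1L) start_o else L - end_o,
              nt_end = if (strand == 1L) end_o else L - start_o,
              aa_seq = paste(aa[i:j], collapse = ""),
              upstream_stops = sum(before == "*"),
              downstream_stops = sum(after == "*"),
              stringsAsFactors = FALSE)
          }
          i <- j + 1
        } else {
          i <- i + 1
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(strand = integer(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      aa_seq = character(), upstream_stops = integer(),
                      downstream_stops = integer()))
  }
  out <- do.call(rbind, rows)
  out[order(-out$strand, out$frame, out$nt_start), ]
}

# independent rendering of the topology decision tree as a flat truth table
oracle_tm_class <- function(len, h, up, down) {
  long <- len >= 235
  stops <- (up >= 2) && (down >= 2)
  if (long && h >= 6 && h <= 8 && stops) return("FULL_LENGTH")
  if (long && h >= 6 && h <= 8) return("POSSIBLE_FULL_LENGTH")
  if (!long && h >= 3 && h <= 6 && !stops) return("PARTIAL")
  "DISCARDED"
}

# a random tree with strictly positive branch lengths, as an additive-metric
# generator for NJ tests
random_additive_tree <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.6)
  tr
}

sort_matrix <- function(m) m[sort(rownames(m)), sort(colnames(m))]

fixture_path <- function(name) {
  system.file("extdata", name, package = "sevenTMscreen", mustWork = TRUE)
}
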