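# Synthetic transcriptome with ground truth. Unigenes carry planted coding
# regions -- intact 7TM receptors, truncated partial receptors, non-7TM
# membrane proteins and soluble decoys -- embedded in random UTRs, on either
# strand, with in-frame stop codons planted so that flanking-stop counts are
# controlled. The generator also emulates topology-predictor output from the
# planted helix geometry so the TMHMM-ingestion path of the pipeline can be
# exercised end to end.

.SYNTH_LABELS <- c("FULL_GPCR", "PARTIAL_GPCR", "MEMBRANE_DECOY",
                   "SOLUBLE_DECOY")

# helix residues: strongly hydrophobic, weights declared here once
.HELIX_WEIGHTS <- c(L = 0.30, I = 0.20, V = 0.20, F = 0.12,
                    M = 0.08, A = 0.08, W = 0.02)
# loop/soluble residues: all 20 with a mild hydrophilic bias
.LOOP_WEIGHTS <- local({
  polar <- c("R", "N", "D", "Q", "E", "G", "H", "K", "P", "S", "T")
  w <- stats::setNames(rep(1, 20), c("A", "C", "D", "E", "F", "G", "H", "I",
                                     "K", "L", "M", "N", "P", "Q", "R", "S",
                                     "T", "V", "W", "Y"))
  w[polar] <- 2
  w / sum(w)
})

#' Synthetic-dataset generator configuration
#'
#' Defaults describe the study conditions the generator emulates: 7TM
#' receptors with 19-25 aa hydrophobic helices separated by 5-30 aa mixed
#' loops, flanked by 30-300 nt UTRs with planted in-frame stops, on either
#' strand with equal probability; partial transcripts lose 20-60% of the
#' coding region from one end; membrane decoys carry 1-5 or 9-11 helices;
#' soluble decoys have no hydrophobic block.
#'
#' @param seed Integer RNG seed.
#' @param n_full_gpcr,n_partial_gpcr,n_membrane_decoy,n_soluble_decoy Counts
#'   per class (defaults 40 each).
#' @param helix_len_range,loop_len_range,utr_len_range,tail_len_range
#'   Inclusive integer ranges (aa, aa, nt, aa).
#' @param n_helices_full Helix count of an intact receptor (default 7).
#' @param antisense_fraction Probability a unigene is reverse-complemented.
#' @param truncation_fraction_range Fraction of the coding region removed
#'   from a partial transcript.
#' @param soluble_len_range Length range (aa) of soluble decoy proteins.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             n_full_gpcr = 40L, n_partial_gpcr = 40L,
                             n_membrane_decoy = 40L, n_soluble_decoy = 40L,
                             helix_len_range = c(19L, 25L),
                             loop_len_range = c(5L, 30L),
                             n_helices_full = 7L,
                             utr_len_range = c(30L, 300L),
                             antisense_fraction = 0.5,
                             truncation_fraction_range = c(0.2, 0.6),
                             tail_len_range = c(15L, 40L),
                             soluble_len_range = c(150L, 400L)) {
  stopifnot(antisense_fraction >= 0, antisense_fraction <= 1,
            helix_len_range[1] <= helix_len_range[2],
            loop_len_range[1] <= loop_len_range[2],
            utr_len_range[1] >= 9,
            truncation_fraction_range[1] >= 0,
            truncation_fraction_range[2] <= 1)
  structure(as.list(environment()), class = "generator_config")
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else
    sample(range[1]:range[2], n, replace = TRUE)
}

.sample_res <- function(n, weights) {
  if (n == 0) return(character(0))
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a synthetic protein with known helix geometry
#'
#' `FULL_GPCR` / `PARTIAL_GPCR`: `n_helices_full` hydrophobic helix blocks
#' separated by mixed loops, with hydrophilic tails. `MEMBRANE_DECOY`: the
#' same architecture with a helix count drawn from {1..5, 9..11}.
#' `SOLUBLE_DECOY`: loop-composition sequence rejected (and redrawn) until
#' the hydropathy caller finds no helix, so the absence of a transmembrane
#' block holds by construction.
#'
#' @param kind One of the four truth labels.
#' @param config A [generator_config()]. Uses the session RNG stream.
#' @return List with `aa_seq` and `helix_segments` (data.frame `start`,
#'   `end`; 0-based half-open protein coordinates).
#' @export
generate_protein <- function(kind, config = generator_config()) {
  kind <- match.arg(kind, .SYNTH_LABELS)
  if (kind == "SOLUBLE_DECOY") {
    for (attempt in 1:50) {
      n <- .runif_int(1, config$soluble_len_range)
      seq <- paste(.sample_res(n, .LOOP_WEIGHTS), collapse = "")
      if (predict_tm_hydropathy(seq)$n_helices == 0) {
        return(list(aa_seq = seq,
                    helix_segments = data.frame(start = integer(),
                                                end = integer())))
      }
    }
    stop("generate_protein: could not draw a helix-free soluble decoy")
  }
  n_helices <- switch(kind,
    FULL_GPCR = config$n_helices_full,
    PARTIAL_GPCR = config$n_helices_full,
    MEMBRANE_DECOY = sample(c(1:5, 9:11), 1)
  )
  helix_lens <- .runif_int(n_helices, config$helix_len_range)
  loop_lens <- if (n_helices > 1) {
    .runif_int(n_helices - 1, config$loop_len_range)
  } else integer(0)
  tail_lens <- .runif_int(2, config$tail_len_range)
  parts <- character(0)
  starts <- integer(n_helices)
  ends <- integer(n_helices)
  pos <- tail_lens[1]
  parts <- c(parts, paste(.sample_res(tail_lens[1], .LOOP_WEIGHTS),
                          collapse = ""))
  for (h in seq_len(n_helices)) {
    starts[h] <- pos
    parts <- c(parts, paste(.sample_res(helix_lens[h], .HELIX_WEIGHTS),
                            collapse = ""))
    pos <- pos + helix_lens[h]
    ends[h] <- pos
    if (h < n_helices) {
      parts <- c(parts, paste(.sample_res(loop_lens[h], .LOOP_WEIGHTS),
                              collapse = ""))
      pos <- pos + loop_lens[h]
    }
  }
  parts <- c(parts, paste(.sample_res(tail_lens[2], .LOOP_WEIGHTS),
                          collapse = ""))
  list(aa_seq = paste(parts, collapse = ""),
       helix_segments = data.frame(start = starts, end = ends))
}

#' Reverse-translate a protein to a coding DNA sequence
#'
#' Uniform choice among synonymous codons of the standard code; the result
#' contains no in-frame stop codon and translates back to the input exactly.
#'
#' @param protein Protein sequence over the 20 standard residues.
#' @param genetic_code NCBI translation table id (default 1).
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, genetic_code = 1L) {
  res <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  bad <- setdiff(res, aa_alphabet())
  if (length(bad) > 0) {
    stop("reverse_translate: non-standard residue(s): ",
         paste(unique(bad), collapse = ", "))
  }
  code <- .codon_table(genetic_code)
  by_aa <- split(names(code), unname(code))
  codons <- vapply(res, function(a) {
    opts <- by_aa[[a]]
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(codons, collapse = "")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_dna <- function(n) {
  if (n == 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random UTR of length >= 9 carrying at least one planted stop codon in the
# reading frame anchored at its inner edge (the edge facing the CDS):
# anchor = "end" for a 5' UTR, "start" for a 3' UTR.
.utr_with_stop <- function(len, anchor = c("end", "start")) {
  anchor <- match.arg(anchor)
  len <- max(len, 9L)
  utr <- .random_dna(len)
  n_codons <- len %/% 3
  k <- if (n_codons >= 2) sample(2:n_codons, 1) else 1
  pos <- if (anchor == "end") len - 3 * k + 1 else 3 * (k - 1) + 1
  stopcdn <- sample(.STOP_CODONS, 1)
  paste0(substr(utr, 1, pos - 1), stopcdn, substr(utr, pos + 3, len))
}

#' Assemble a unigene around a coding sequence
#'
#' Adds a bounding stop codon at each end of the CDS, UTRs carrying at least
#' one additional planted in-frame stop each (so the flanking-stop
#' requirement is met by construction), optional reverse-complement
#' placement, and -- for `PARTIAL_GPCR` -- truncation removing one flank and
#' part of the coding region.
#'
#' @param cds Coding DNA (no internal stops), from [reverse_translate()].
#' @param kind Truth label.
#' @param config A [generator_config()].
#' @param unigene_id Id for the truth record.
#' @param helix_segments Planted helix geometry (protein coordinates).
#' @return List with `seq` (DNA string) and `truth` (one-row data.frame).
#' @export
build_unigene <- function(cds, kind, config = generator_config(),
                          unigene_id = "synth1",
                          helix_segments = data.frame(start = integer(),
                                                      end = integer())) {
  kind <- match.arg(kind, .SYNTH_LABELS)
  utr5 <- .utr_with_stop(.runif_int(1, config$utr_len_range), "end")
  utr3 <- .utr_with_stop(.runif_int(1, config$utr_len_range), "start")
  # the 5' UTR's planted stop is anchored at its inner (3') edge, so pad the
  # UTR to a codon multiple to keep that stop in the CDS frame
  pad5 <- nchar(utr5) %% 3
  if (pad5 > 0) utr5 <- paste0(.random_dna(3 - pad5), utr5)
  seq <- paste0(utr5, sample(.STOP_CODONS, 1), cds,
                sample(.STOP_CODONS, 1), utr3)
  cds_start <- nchar(utr5) + 3L
  cds_end <- cds_start + nchar(cds)
  flanking_ok <- TRUE
  aa_len <- nchar(cds) %/% 3
  if (kind == "PARTIAL_GPCR") {
    f <- stats::runif(1, config$truncation_fraction_range[1],
                      config$truncation_fraction_range[2])
    cut_aa <- max(1L, as.integer(floor(f * aa_len)))
    from_5prime <- stats::runif(1) < 0.5
    if (from_5prime) {
      # drop the 5' UTR, bounding stop and the first cut_aa codons
      drop <- cds_start + 3L * cut_aa
      seq <- substr(seq, drop + 1, nchar(seq))
      cds_start <- 0L
      cds_end <- cds_end - drop
      helix_segments <- .shift_clip_segments(helix_segments, cut_aa,
                                             aa_len - cut_aa)
    } else {
      drop <- cds_end - 3L * cut_aa
      seq <- substr(seq, 1, drop)
      cds_end <- drop
      helix_segments <- .shift_clip_segments(helix_segments, 0L,
                                             aa_len - cut_aa)
    }
    aa_len <- aa_len - cut_aa
    flanking_ok <- FALSE
  }
  strand <- 1L
  if (stats::runif(1) < config$antisense_fraction) {
    L <- nchar(seq)
    seq <- .revcomp(seq)
    new_start <- L - cds_end
    cds_end <- L - cds_start
    cds_start <- new_start
    strand <- -1L
  }
  frame <- if (strand == 1L) cds_start %% 3L else
    (nchar(seq) - cds_end) %% 3L
  truth <- data.frame(
    unigene_id = unigene_id, label = kind,
    cds_start = cds_start, cds_end = cds_end,
    strand = strand, frame = frame, length_aa = aa_len,
    true_n_helices = nrow(helix_segments),
    flanking_stops_ok = flanking_ok,
    helix_segments = .serialize_segments(helix_segments),
    stringsAsFactors = FALSE
  )
  list(seq = seq, truth = truth)
}

.shift_clip_segments <- function(seg, offset, new_len) {
  if (nrow(seg) == 0) return(seg)
  start <- pmax(seg$start - offset, 0L)
  end <- pmin(seg$end - offset, new_len)
  keep <- (end - start) >= 10L  # a clipped fragment under 10 aa is unseen
  data.frame(start = as.integer(start[keep]), end = as.integer(end[keep]))
}

.serialize_segments <- function(seg) {
  if (nrow(seg) == 0) return("")
  paste(sprintf("%d-%d", seg$start, seg$end), collapse = ";")
}

.deserialize_segments <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(start = integer(), end = integer()))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[[`, "", 1)),
             end = as.integer(vapply(parts, `[[`, "", 2)))
}

#' Generate a synthetic unigene dataset with ground truth
#'
#' Reproducible from `config$seed`. Optionally writes the unigene FASTA, the
#' truth table (TSV), an emulated topology-prediction file for every ORF the
#' ORF finder reports (planted helices for true coding ORFs, no helices for
#' bystander ORFs) and the generator configuration.
#'
#' @param config A [generator_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `unigenes` (named character vector), `truth`
#'   (data.frame), and -- when `out_dir` is given -- the written `paths`.
#' @export
generate_dataset <- function(config = generator_config(), out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  counts <- c(FULL_GPCR = config$n_full_gpcr,
              PARTIAL_GPCR = config$n_partial_gpcr,
              MEMBRANE_DECOY = config$n_membrane_decoy,
              SOLUBLE_DECOY = config$n_soluble_decoy)
  if (sum(counts) == 0) stop("generate_dataset: zero total count")
  set.seed(config$seed)
  seqs <- character(0)
  truth <- list()
  k <- 0L
  for (label in names(counts)) {
    for (i in seq_len(counts[[label]])) {
      k <- k + 1L
      id <- sprintf("synth%04d", k)
      prot <- generate_protein(label, config)
      cds <- reverse_translate(prot$aa_seq)
      built <- build_unigene(cds, label, config, unigene_id = id,
                             helix_segments = prot$helix_segments)
      seqs[[id]] <- built$seq
      truth[[k]] <- built$truth
    }
  }
  truth <- do.call(rbind, truth)
  out <- list(unigenes = seqs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "unigenes.fasta"),
      truth = file.path(out_dir, "truth.tsv"),
      tmhmm = file.path(out_dir, "tmhmm_emulated.txt"),
      config = file.path(out_dir, "generator_config.json")
    )
    write_fasta(Biostrings::DNAStringSet(seqs), paths$fasta)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    orfs <- find_orfs_set(seqs)
    write_tmhmm(emulate_tmhmm_records(orfs, truth), paths$tmhmm)
    jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                         digits = NA)
    out$paths <- paths
  }
  out
}

#' Emulate topology-predictor records from planted truth
#'
#' For every ORF reported by the ORF finder, builds a TMHMM-style record:
#' ORFs that lie on a planted coding region (same unigene, strand and frame,
#' overlapping the CDS) receive the planted helix segments mapped into ORF
#' protein coordinates (clipped fragments under 10 aa are dropped, as a
#' topology predictor would miss them); every other ORF gets zero helices.
#' This is an idealized emulation of predictor output, not a predictor.
#'
#' @param orfs ORF data.frame from [find_orfs_set()].
#' @param truth Truth table from [generate_dataset()].
#' @return Named list of records suitable for [write_tmhmm()] /
#'   [tmhmm_to_topology()].
#' @export
emulate_tmhmm_records <- function(orfs, truth) {
  recs <- vector("list", nrow(orfs))
  for (i in seq_len(nrow(orfs))) {
    orf <- orfs[i, ]
    len <- orf$length_aa
    seg_prot <- data.frame(start = integer(), end = integer())
    tr <- truth[truth$unigene_id == orf$unigene_id, , drop = FALSE]
    if (nrow(tr) == 1 && tr$strand == orf$strand &&
        tr$frame == orf$frame &&
        orf$nt_start < tr$cds_end && orf$nt_end > tr$cds_start) {
      # offset of the ORF within the planted protein, in residues
      offset <- if (orf$strand == 1L) {
        (orf$nt_start - tr$cds_start) / 3
      } else {
        (tr$cds_end - orf$nt_end) / 3
      }
      planted <- .deserialize_segments(tr$helix_segments)
      if (offset == round(offset)) {
        seg_prot <- .shift_clip_segments(planted, as.integer(offset), len)
      }
    }
    recs[[i]] <- .topology_segments_to_record(orf$orf_id, len, seg_prot)
  }
  stats::setNames(recs, orfs$orf_id)
}

# Build a tiling inside/TMhelix/outside record from 0-based half-open helix
# segments on a protein of length len.
.topology_segments_to_record <- function(id, len, seg) {
  seg <- seg[order(seg$start), , drop = FALSE]
  rows <- list()
  cursor <- 0L
  side <- "outside"
  for (j in seq_len(nrow(seg))) {
    if (seg$start[j] > cursor) {
      rows[[length(rows) + 1]] <- data.frame(
        kind = side, start = cursor + 1L, end = seg$start[j])
      side <- if (side == "outside") "inside" else "outside"
    }
    rows[[length(rows) + 1]] <- data.frame(
      kind = "TMhelix", start = seg$start[j] + 1L, end = seg$end[j])
    cursor <- seg$end[j]
  }
  if (cursor < len) {
    rows[[length(rows) + 1]] <- data.frame(
      kind = side, start = cursor + 1L, end = len)
  }
  segments <- do.call(rbind, rows)
  list(protein_id = id, length = len,
       predicted_helices = sum(segments$kind == "TMhelix"),
       segments = segments)
}
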