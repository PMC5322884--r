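# Six-frame ORF extraction. ORFs are maximal stop-free runs between stop
# codons (or sequence ends) in each of the six reading frames -- no start
# codon is required, since fragmented transcriptome unigenes carry no
# guarantee of a complete 5' end. Flanking in-frame stop-codon counts are
# kept because they separate full-length from truncated coding regions
# downstream.

#' ORF-finder configuration
#'
#' @param min_length_aa Minimum ORF length in amino acids (default 50;
#'   shorter frame products are discarded).
#' @param genetic_code NCBI translation table id (default 1, the standard
#'   code).
#' @return List of class `orf_config`.
#' @export
orf_config <- function(min_length_aa = 50L, genetic_code = 1L) {
  stopifnot(min_length_aa >= 1)
  structure(list(min_length_aa = as.integer(min_length_aa),
                 genetic_code = genetic_code),
            class = "orf_config")
}

.codon_table <- function(genetic_code = 1L) {
  Biostrings::getGeneticCode(as.character(genetic_code))
}

# Translate an oriented DNA string codon by codon. Trailing partial codons
# are dropped; any codon not in the code table (e.g. containing N) becomes X.
.translate_dna <- function(seq, code) {
  n <- nchar(seq) %/% 3
  if (n == 0) return("")
  starts <- seq(1, by = 3, length.out = n)
  codons <- substring(seq, starts, starts + 2)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Six-frame translation
#'
#' Translates a unigene in all six reading frames. Reverse-strand frames are
#' defined on the reverse complement; stops are rendered `*`, codons
#' containing ambiguity codes become `X`, and trailing partial codons are
#' dropped.
#'
#' @param seq DNA sequence (single string, case-insensitive).
#' @param genetic_code NCBI translation table id (default 1).
#' @return data.frame with columns `strand` (+1/-1), `frame` (0..2) and
#'   `protein`.
#' @export
six_frame_translate <- function(seq, genetic_code = 1L) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  if (nchar(seq) < 3) {
    stop("six_frame_translate: sequence shorter than one codon")
  }
  code <- .codon_table(genetic_code)
  rc <- .revcomp(seq)
  grid <- expand.grid(frame = 0:2, strand = c(1L, -1L))[, c("strand", "frame")]
  grid <- grid[order(-grid$strand, grid$frame), ]
  grid$protein <- vapply(seq_len(nrow(grid)), function(i) {
    s <- if (grid$strand[i] == 1L) seq else rc
    .translate_dna(substr(s, grid$frame[i] + 1, nchar(s)), code)
  }, character(1))
  rownames(grid) <- NULL
  grid
}

#' Format an ORF identifier
#'
#' Builds the id scheme
#' `"<unigene_id>_<length>(length)_<strand>(strand)_<frame>(frame)"`, e.g.
#' `"athaller1175_662(length)_1(strand)_1(frame)"`.
#'
#' @param unigene_id Unigene id.
#' @param length_aa ORF length in amino acids.
#' @param strand `+1` or `-1`.
#' @param frame `0`, `1` or `2`.
#' @return Character vector of ids.
#' @export
format_orf_id <- function(unigene_id, length_aa, strand, frame) {
  stopifnot(all(strand %in% c(1L, -1L)), all(frame %in% 0:2))
  sprintf("%s_%d(length)_%d(strand)_%d(frame)",
          unigene_id, as.integer(length_aa), as.integer(strand),
          as.integer(frame))
}

#' Parse an ORF identifier
#'
#' Inverse of [format_orf_id()]. Any disambiguating `#k` suffix added for
#' colliding ids is stripped before parsing.
#'
#' @param orf_id Character vector of ORF ids.
#' @return data.frame with columns `unigene_id`, `length_aa`, `strand`,
#'   `frame`.
#' @export
parse_orf_id <- function(orf_id) {
  core <- sub("#\\d+$", "", orf_id)
  m <- regmatches(core, regexec(
    "^(.*)_(\\d+)\\(length\\)_(-?1)\\(strand\\)_([0-2])\\(frame\\)$", core))
  bad <- vapply(m, length, 1L) != 5
  if (any(bad)) {
    stop("parse_orf_id: not a valid ORF id: ", orf_id[which(bad)[1]])
  }
  data.frame(
    unigene_id = vapply(m, `[[`, "", 2),
    length_aa = as.integer(vapply(m, `[[`, "", 3)),
    strand = as.integer(vapply(m, `[[`, "", 4)),
    frame = as.integer(vapply(m, `[[`, "", 5)),
    stringsAsFactors = FALSE
  )
}

#' Find ORFs in a unigene
#'
#' Scans all six reading frames for maximal stop-free runs (delimited by stop
#' codons or the sequence ends), keeps those of at least
#' `config$min_length_aa` residues, and reports each with its translation,
#' forward-strand nucleotide coordinates (0-based half-open) and the counts
#' of in-frame stop codons upstream and downstream of the run (bounding
#' stops included). `X` from ambiguity codes never breaks a run.
#'
#' Output is sorted by (strand, frame, nt_start), forward strand first. When
#' two ORFs of one unigene share the same (length, strand, frame) the id
#' scheme collides; later duplicates get a positional `#k` suffix.
#'
#' @param seq DNA sequence (single string).
#' @param unigene_id Id used to build ORF ids.
#' @param config An [orf_config()].
#' @return data.frame with columns `orf_id`, `unigene_id`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `length_aa`, `aa_seq`, `upstream_stops`,
#'   `downstream_stops`.
#' @export
find_orfs <- function(seq, unigene_id, config = orf_config()) {
  stopifnot(inherits(config, "orf_config"))
  seq <- toupper(seq)
  L <- nchar(seq)
  frames <- if (L >= 3) six_frame_translate(seq, config$genetic_code) else
    data.frame(strand = integer(), frame = integer(), protein = character())
  rows <- list()
  for (i in seq_len(nrow(frames))) {
    prot <- frames$protein[i]
    if (!nzchar(prot)) next
    aa <- strsplit(prot, "", fixed = TRUE)[[1]]
    is_stop <- aa == "*"
    r <- rle(is_stop)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    stops_before <- cumsum(c(0, r$values * r$lengths))[-(length(r$values) + 1)]
    total_stops <- sum(is_stop)
    for (j in which(!r$values & r$lengths >= config$min_length_aa)) {
      p0 <- starts[j]; p1 <- ends[j]
      strand <- frames$strand[i]; frame <- frames$frame[i]
      start_o <- frame + 3 * (p0 - 1)
      end_o <- frame + 3 * p1
      rows[[length(rows) + 1]] <- data.frame(
        unigene_id = unigene_id,
        strand = strand,
        frame = frame,
        nt_start = if (strand == 1L) start_o else L - end_o,
        nt_end = if (strand == 1L) end_o else L - start_o,
        length_aa = p1 - p0 + 1,
        aa_seq = substr(prot, p0, p1),
        upstream_stops = stops_before[j],
        downstream_stops = total_stops - stops_before[j],
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(orf_id = character(), unigene_id = character(),
                      strand = integer(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      length_aa = integer(), aa_seq = character(),
                      upstream_stops = integer(), downstream_stops = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$strand, out$frame, out$nt_start), ]
  out$orf_id <- format_orf_id(out$unigene_id, out$length_aa,
                              out$strand, out$frame)
  dup <- stats::ave(seq_len(nrow(out)), out$orf_id, FUN = seq_along)
  out$orf_id[dup > 1] <- paste0(out$orf_id[dup > 1], "#", dup[dup > 1])
  rownames(out) <- NULL
  out[, c("orf_id", "unigene_id", "strand", "frame", "nt_start", "nt_end",
          "length_aa", "aa_seq", "upstream_stops", "downstream_stops")]
}

#' Find ORFs across a unigene collection
#'
#' @param unigenes Named character vector or [Biostrings::DNAStringSet].
#' @param config An [orf_config()].
#' @return Combined data.frame as from [find_orfs()].
#' @export
find_orfs_set <- function(unigenes, config = orf_config()) {
  seqs <- stats::setNames(as.character(unigenes), names(unigenes))
  stopifnot(!is.null(names(seqs)))
  parts <- lapply(names(seqs), function(id) find_orfs(seqs[[id]], id, config))
  do.call(rbind, parts)
}

#' Count in-frame stop codons flanking an ORF
#'
#' Re-derives, for an ORF row produced by [find_orfs()], the number of stop
#' codons in the ORF's own frame and strand strictly before its start and
#' strictly after its end (in translation direction). The ORF's bounding
#' stops are included in the counts. Errors if the coordinates do not
#' reproduce the stored translation.
#'
#' @param seq The unigene DNA sequence.
#' @param orf A single-row data.frame (or list) with `strand`, `frame`,
#'   `nt_start`, `nt_end`, `aa_seq`.
#' @param genetic_code NCBI translation table id.
#' @return Integer vector `c(upstream_stops, downstream_stops)`.
#' @export
count_flanking_stops <- function(seq, orf, genetic_code = 1L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  code <- .codon_table(genetic_code)
  if (orf$nt_start < 0 || orf$nt_end > L || orf$nt_start >= orf$nt_end ||
      (orf$nt_end - orf$nt_start) %% 3 != 0) {
    stop("count_flanking_stops: coordinates do not fit the unigene")
  }
  oriented <- if (orf$strand == 1L) seq else .revcomp(seq)
  start_o <- if (orf$strand == 1L) orf$nt_start else L - orf$nt_end
  end_o <- if (orf$strand == 1L) orf$nt_end else L - orf$nt_start
  if (start_o %% 3 != orf$frame %% 3) {
    stop("count_flanking_stops: frame does not match coordinates")
  }
  own <- .translate_dna(substr(oriented, start_o + 1, end_o), code)
  if (!identical(own, orf$aa_seq)) {
    stop("count_flanking_stops: coordinates do not reproduce aa_seq for ",
         orf$orf_id %||% "<orf>")
  }
  prot <- .translate_dna(substr(oriented, orf$frame + 1, nchar(oriented)), code)
  aa <- strsplit(prot, "", fixed = TRUE)[[1]]
  p0 <- (start_o - orf$frame) / 3  # residues before the ORF
  nres <- (end_o - start_o) / 3
  up <- sum(aa[seq_len(p0)] == "*")
  down <- sum(aa[-seq_len(p0 + nres)] == "*")
  c(upstream_stops = up, downstream_stops = down)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ORFs as protein FASTA / TSV
#'
#' @param orfs ORF data.frame from [find_orfs_set()].
#' @param path Output file.
#' @export
write_orf_fasta <- function(orfs, path) {
  seqs <- stats::setNames(orfs$aa_seq, orfs$orf_id)
  write_fasta(Biostrings::AAStringSet(seqs), path)
}

#' @rdname write_orf_fasta
#' @export
write_orf_tsv <- function(orfs, path) {
  utils::write.table(orfs[, c("orf_id", "unigene_id", "strand", "frame",
                              "nt_start", "nt_end", "length_aa",
                              "upstream_stops", "downstream_stops")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
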