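# Readers and writers for the external formats the screening pipeline
# touches: FASTA (DNA and protein), TMHMM long-format output, BLAST tabular
# (outfmt-6 style), Pfam per-sequence hit tables and single-chain PDB
# coordinate files. Parsed external coordinates keep their native 1-based
# inclusive convention; internal coordinates are 0-based half-open.

.IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")

#' Read unigene DNA sequences from FASTA
#'
#' One record per header. The header token before the first whitespace
#' becomes the id (the remainder is kept as a `description` metadata column);
#' sequences are uppercased and validated against the IUPAC DNA alphabet.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names and a
#'   `description` column in `mcols()`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: no such file: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop("read_fasta: no FASTA records in ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("read_fasta: empty sequence id in ", path)
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    if (length(chars) < 1) {
      stop("read_fasta: empty sequence for id ", ids[i])
    }
    bad <- which(!chars %in% .IUPAC_DNA)
    if (length(bad) > 0) {
      stop("read_fasta: non-IUPAC character '", chars[bad[1]],
           "' at position ", bad[1], " in record ", ids[i])
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA (60-column wrapping)
#'
#' @param seqs A named `XStringSet` or named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    stopifnot(!is.null(names(seqs)))
    seqs <- Biostrings::BStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Parse TMHMM long-format output
#'
#' Reads the long output format: data lines
#' `<id>\tTMHMM2.0\t<inside|TMhelix|outside>\t<start>\t<end>` plus comment
#' lines carrying `Length:` and `Number of predicted TMHs:`. Segments must
#' tile `1..length` without gaps or overlaps, and the helix count is
#' cross-checked against the comment line when present.
#'
#' @param path TMHMM output file.
#' @return Named list of records, each a list with `protein_id`, `length`,
#'   `predicted_helices` and a `segments` data.frame (`kind`, `start`, `end`;
#'   1-based inclusive).
#' @export
parse_tmhmm <- function(path) {
  if (!file.exists(path)) stop("parse_tmhmm: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  comments <- grepl("^#", lines)
  meta_len <- list()
  meta_tmh <- list()
  for (ln in lines[comments]) {
    m <- regmatches(ln, regexec("^#\\s*(\\S+)\\s+Length:\\s*(\\d+)", ln))[[1]]
    if (length(m) == 3) meta_len[[m[2]]] <- as.integer(m[3])
    m <- regmatches(ln, regexec(
      "^#\\s*(\\S+)\\s+Number of predicted TMHs:\\s*(\\d+)", ln))[[1]]
    if (length(m) == 3) meta_tmh[[m[2]]] <- as.integer(m[3])
  }
  data <- lines[!comments]
  if (length(data) == 0) stop("parse_tmhmm: no topology lines in ", path)
  fields <- strsplit(data, "\\s+")
  bad <- which(vapply(fields, length, 1L) != 5)
  if (length(bad) > 0) {
    stop("parse_tmhmm: malformed line: ", data[bad[1]])
  }
  df <- data.frame(
    protein_id = vapply(fields, `[[`, "", 1),
    kind = vapply(fields, `[[`, "", 3),
    start = as.integer(vapply(fields, `[[`, "", 4)),
    end = as.integer(vapply(fields, `[[`, "", 5)),
    stringsAsFactors = FALSE
  )
  if (!all(df$kind %in% c("inside", "TMhelix", "outside"))) {
    stop("parse_tmhmm: unknown segment kind: ",
         paste(setdiff(df$kind, c("inside", "TMhelix", "outside")),
               collapse = ", "))
  }
  out <- list()
  for (id in unique(df$protein_id)) {
    seg <- df[df$protein_id == id, c("kind", "start", "end")]
    seg <- seg[order(seg$start), , drop = FALSE]
    rownames(seg) <- NULL
    if (seg$start[1] != 1) {
      stop("parse_tmhmm: segments for ", id, " do not start at 1")
    }
    if (nrow(seg) > 1 &&
        any(seg$start[-1] != seg$end[-nrow(seg)] + 1)) {
      stop("parse_tmhmm: segment gap/overlap in ", id)
    }
    if (any(seg$end < seg$start)) {
      stop("parse_tmhmm: inverted segment in ", id)
    }
    len <- seg$end[nrow(seg)]
    if (!is.null(meta_len[[id]]) && meta_len[[id]] != len) {
      stop("parse_tmhmm: declared length ", meta_len[[id]],
           " != segment span ", len, " for ", id)
    }
    nh <- sum(seg$kind == "TMhelix")
    if (!is.null(meta_tmh[[id]]) && meta_tmh[[id]] != nh) {
      stop("parse_tmhmm: declared TMH count ", meta_tmh[[id]],
           " != observed ", nh, " for ", id)
    }
    out[[id]] <- list(protein_id = id, length = len,
                      predicted_helices = nh, segments = seg)
  }
  out
}

#' Write TMHMM long-format output
#'
#' Inverse of [parse_tmhmm()]; used by the synthetic-data module to emulate
#' topology-prediction output from planted ground truth.
#'
#' @param records Named list of records as returned by [parse_tmhmm()].
#' @param path Output file.
#' @export
write_tmhmm <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    writeLines(sprintf("# %s Length: %d", rec$protein_id, rec$length), con)
    writeLines(sprintf("# %s Number of predicted TMHs:  %d",
                       rec$protein_id, rec$predicted_helices), con)
    seg <- rec$segments
    writeLines(sprintf("%s\tTMHMM2.0\t%s\t%d\t%d",
                       rec$protein_id, seg$kind, seg$start, seg$end), con)
  }
  invisible(path)
}

#' Parse a BLAST tabular hit file and filter by E-value
#'
#' Assumes the standard 12-column outfmt-6 ordering (query, subject, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#' with an optional 13th description column. Hits are kept only when
#' `evalue < evalue_cutoff` (strict inequality); input order is preserved.
#'
#' @param path Tab-separated hit file.
#' @param evalue_cutoff Significance cutoff (default `1e-6`).
#' @return data.frame with columns `query_id`, `subject_id`, `evalue`,
#'   `bitscore`, `description`.
#' @export
parse_hits_table <- function(path, evalue_cutoff = 1e-6) {
  if (!file.exists(path)) stop("parse_hits_table: no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      description = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 12)) {
    stop("parse_hits_table: line ", which(nf < 12)[1],
         " has fewer than 12 columns")
  }
  ev <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11)))
  if (anyNA(ev)) {
    stop("parse_hits_table: unparseable e-value on line ", which(is.na(ev))[1])
  }
  if (any(ev < 0)) {
    stop("parse_hits_table: negative e-value on line ", which(ev < 0)[1])
  }
  df <- data.frame(
    query_id = vapply(fields, `[[`, "", 1),
    subject_id = vapply(fields, `[[`, "", 2),
    evalue = ev,
    bitscore = as.numeric(vapply(fields, `[[`, "", 12)),
    description = vapply(fields, function(f)
      if (length(f) >= 13) f[[13]] else NA_character_, ""),
    stringsAsFactors = FALSE
  )
  df[df$evalue < evalue_cutoff, , drop = FALSE]
}

#' Parse a Pfam per-sequence hit table
#'
#' Tab-separated columns: sequence id, family accession, family name, clan,
#' e-value, bit score.
#'
#' @param path Tab-separated file.
#' @param evalue_cutoff Keep hits with `evalue < evalue_cutoff`
#'   (default `Inf`, i.e. all rows).
#' @return data.frame with columns `seq_id`, `accession`, `family`, `clan`,
#'   `evalue`, `bitscore`.
#' @export
parse_pfam_table <- function(path, evalue_cutoff = Inf) {
  if (!file.exists(path)) stop("parse_pfam_table: no such file: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 6) stop("parse_pfam_table: expected 6 columns")
  names(df)[1:6] <- c("seq_id", "accession", "family", "clan",
                      "evalue", "bitscore")
  df$evalue <- as.numeric(df$evalue)
  if (anyNA(df$evalue)) stop("parse_pfam_table: unparseable e-value")
  df[df$evalue < evalue_cutoff, 1:6, drop = FALSE]
}

#' Read a single-chain PDB coordinate file
#'
#' Takes the first chain if several are present, extracts backbone (N, CA, C)
#' coordinates per residue, and captures HELIX records as declared helix
#' annotations. Residues missing any backbone atom are flagged incomplete.
#'
#' @param path PDB file.
#' @return Object of class `model_chain`: list with `residues` (data.frame
#'   `resno`, `n_x..c_z`, `complete`) and `helix_annotations` (data.frame
#'   `start`, `end`; 1-based inclusive residue numbers, possibly empty).
#' @export
read_model_chain <- function(path) {
  if (!file.exists(path)) stop("read_model_chain: no such file: ", path)
  lines <- readLines(path)
  atom_idx <- grep("^ATOM  ", lines)
  for (i in atom_idx) {
    ln <- lines[i]
    if (nchar(ln) < 54 ||
        is.na(suppressWarnings(as.numeric(substr(ln, 31, 38)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 39, 46)))) ||
        is.na(suppressWarnings(as.numeric(substr(ln, 47, 54))))) {
      stop("read_model_chain: malformed ATOM line ", i, " in ", path)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom
  chain <- atoms$chain[1]
  if (!is.na(chain)) atoms <- atoms[atoms$chain == chain | is.na(atoms$chain), ]
  atoms <- atoms[atoms$type == "ATOM", ]
  if (!any(atoms$elety == "CA")) {
    stop("read_model_chain: no CA atoms in ", path)
  }
  resnos <- sort(unique(atoms$resno))
  grab <- function(resno, elety) {
    row <- atoms[atoms$resno == resno & atoms$elety == elety, , drop = FALSE]
    if (nrow(row) == 0) rep(NA_real_, 3) else
      as.numeric(row[1, c("x", "y", "z")])
  }
  mat <- t(vapply(resnos, function(r) {
    c(grab(r, "N"), grab(r, "CA"), grab(r, "C"))
  }, numeric(9)))
  residues <- data.frame(resno = resnos,
                         n_x = mat[, 1], n_y = mat[, 2], n_z = mat[, 3],
                         ca_x = mat[, 4], ca_y = mat[, 5], ca_z = mat[, 6],
                         c_x = mat[, 7], c_y = mat[, 8], c_z = mat[, 9])
  residues$complete <- stats::complete.cases(mat)
  helix <- data.frame(start = integer(), end = integer())
  if (!is.null(pdb$helix) && length(pdb$helix$start) > 0) {
    helix <- data.frame(start = as.integer(pdb$helix$start),
                        end = as.integer(pdb$helix$end))
  }
  structure(list(residues = residues, helix_annotations = helix),
            class = "model_chain")
}

#' Write a model chain as a PDB coordinate file
#'
#' Emits backbone ATOM records (N, CA, C as poly-alanine) and optional HELIX
#' records; the counterpart of [read_model_chain()] for fixtures generated
#' in code.
#'
#' @param chain A `model_chain` object.
#' @param path Output file.
#' @export
write_model_chain <- function(chain, path) {
  stopifnot(inherits(chain, "model_chain"))
  con <- file(path, "w")
  on.exit(close(con))
  hx <- chain$helix_annotations
  if (!is.null(hx) && nrow(hx) > 0) {
    for (i in seq_len(nrow(hx))) {
      writeLines(sprintf(
        "HELIX  %3d %3s ALA A %4d  ALA A %4d  1%36d",
        i, sprintf("H%02d", i), hx$start[i], hx$end[i],
        hx$end[i] - hx$start[i] + 1), con)
    }
  }
  res <- chain$residues
  serial <- 1L
  for (i in seq_len(nrow(res))) {
    for (at in c("N", "CA", "C")) {
      pre <- tolower(at)
      xyz <- as.numeric(res[i, paste0(pre, c("_x", "_y", "_z"))])
      if (anyNA(xyz)) next
      writeLines(sprintf(
        "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, at, res$resno[i], xyz[1], xyz[2], xyz[3],
        substr(at, 1, 1)), con)
      serial <- serial + 1L
    }
  }
  writeLines("END", con)
  invisible(path)
}
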