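# Consensus over four prediction approaches. Per-tool verdicts (BLAST and
# Pfam collapse into a single alignment approach) are merged per ORF into a
# "Pred. by" letter code over T (topology/TMHMM), A (alignment methods),
# G (dipeptide-composition SVM approach) and P (multi-descriptor approach),
# together with subfamily-consistency flags, the Venn partition of the four
# positive sets, and annotation keyword screening.

.APPROACHES <- c(TMHMM = "T", ALIGNMENT = "A", GPCRPRED = "G", PCAGPCR = "P")

#' The four consensus approaches
#'
#' @return Named character vector mapping approach names to their code
#'   letters, in the fixed code order T, A, G, P.
#' @export
consensus_approaches <- function() .APPROACHES

#' Build one evidence record
#'
#' @param orf_id ORF id.
#' @param source One of `names(consensus_approaches())` (stand-in classifier
#'   sources `GPCRPRED_STANDIN` / `PCAGPCR_STANDIN` are accepted and mapped
#'   to their approach with the stand-in tag kept in `detail`).
#' @param is_gpcr Logical verdict.
#' @param gpcr_class,subfamily Optional class/subfamily labels.
#' @param detail Free-text detail (best hit, e-value, topology class, ...).
#' @return One-row data.frame.
#' @export
evidence_record <- function(orf_id, source, is_gpcr, gpcr_class = NA,
                            subfamily = NA, detail = NA) {
  src <- sub("_STANDIN$", "", source)
  if (!src %in% names(.APPROACHES)) {
    stop("evidence_record: unknown source: ", source)
  }
  if (grepl("_STANDIN$", source)) {
    detail <- if (is.na(detail)) "standin" else paste(detail, "standin")
  }
  data.frame(orf_id = orf_id, source = src, is_gpcr = as.logical(is_gpcr),
             gpcr_class = as.character(gpcr_class),
             subfamily = as.character(subfamily),
             detail = as.character(detail), stringsAsFactors = FALSE)
}

#' Aggregate per-approach evidence into consensus records
#'
#' One consensus record per ORF appearing in any evidence record. An
#' approach is positive for an ORF when any of its records is positive; the
#' `pred_by_code` concatenates the positive approaches' letters in the fixed
#' order T, A, G, P. Class and subfamily labels are taken from the first
#' positive record of the multi-descriptor (`PCAGPCR`) and dipeptide-SVM
#' (`GPCRPRED`) approaches; `subfamily_consistent` is their agreement under
#' [normalize_subfamily()], and `class_consistent` tracks class-level
#' agreement separately.
#'
#' @param records data.frame of evidence records ([evidence_record()] rows).
#' @return data.frame of consensus records sorted by `orf_id`.
#' @export
aggregate_evidence <- function(records) {
  stopifnot(is.data.frame(records))
  records$source <- sub("_STANDIN$", "", records$source)
  unknown <- setdiff(unique(records$source), names(.APPROACHES))
  if (length(unknown) > 0) {
    stop("aggregate_evidence: unknown source label(s): ",
         paste(unknown, collapse = ", "))
  }
  ids <- sort(unique(records$orf_id))
  rows <- lapply(ids, function(id) {
    rec <- records[records$orf_id == id, , drop = FALSE]
    pos <- vapply(names(.APPROACHES), function(s) {
      any(rec$is_gpcr[rec$source == s])
    }, logical(1))
    take <- function(src, col) {
      v <- rec[[col]][rec$source == src & rec$is_gpcr]
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_character_ else v[1]
    }
    pca_sub <- take("PCAGPCR", "subfamily")
    gpred_sub <- take("GPCRPRED", "subfamily")
    pca_cls <- take("PCAGPCR", "gpcr_class")
    gpred_cls <- take("GPCRPRED", "gpcr_class")
    sub_ok <- is_consistent(pca_sub, gpred_sub)
    data.frame(
      orf_id = id,
      pred_by_code = paste(.APPROACHES[pos], collapse = ""),
      n_sources = sum(pos),
      pca_class = pca_cls,
      pca_subfamily = pca_sub,
      gpcrpred_class = gpred_cls,
      gpcrpred_subfamily = gpred_sub,
      subfamily_consistent = sub_ok,
      class_consistent = !sub_ok && !is.na(pca_cls) && !is.na(gpred_cls) &&
        normalize_subfamily(pca_cls) == normalize_subfamily(gpred_cls),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' The basic candidate set
#'
#' Consensus records supported by at least `min_sources` approaches, in
#' stable `orf_id` order.
#'
#' @param consensus Output of [aggregate_evidence()].
#' @param min_sources Minimum number of positive approaches (default 3).
#' @return Subset data.frame.
#' @export
basic_set <- function(consensus, min_sources = 3L) {
  stopifnot(min_sources >= 0)
  out <- consensus[consensus$n_sources >= min_sources, , drop = FALSE]
  out <- out[order(out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Venn partition of the four positive sets
#'
#' Counts ORFs by the exact subset of approaches that called them positive:
#' 15 disjoint regions summing to the number of ORFs with at least one
#' positive approach.
#'
#' @param consensus Output of [aggregate_evidence()].
#' @return Named integer vector over the 15 non-empty approach subsets.
#' @export
venn_partition <- function(consensus) {
  letters4 <- unname(.APPROACHES)
  subsets <- unlist(lapply(1:4, function(k) {
    apply(utils::combn(letters4, k), 2, paste, collapse = "")
  }))
  counts <- stats::setNames(integer(length(subsets)), subsets)
  codes <- consensus$pred_by_code[consensus$n_sources >= 1]
  tab <- table(codes)
  counts[names(tab)] <- as.integer(tab)
  counts
}

#' Normalize a subfamily (or class) label
#'
#' Lowercases, strips non-alphanumerics and applies a small synonym map, so
#' that e.g. `"(Rhod)opsin"` and `"Rhodopsin"` compare equal. Missing
#' markers (`NA`, `""`, `"-"`, `"NA"`) normalize to `NA`.
#'
#' @param label Character vector of labels.
#' @return Character vector of canonical labels (or `NA`).
#' @export
normalize_subfamily <- function(label) {
  out <- vapply(as.character(label), function(x) {
    if (is.na(x)) return(NA_character_)
    x <- trimws(x)
    if (x %in% c("", "-", "NA", "na", "none")) return(NA_character_)
    x <- tolower(gsub("[^a-zA-Z0-9]", "", x))
    synonyms <- c(rhodopsin = "rhodopsin", rhodopsinlike = "rhodopsin",
                  gabab = "gabab", gababreceptor = "gabab")
    if (x %in% names(synonyms)) unname(synonyms[x]) else x
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Are two subfamily labels consistent?
#'
#' `TRUE` only when both labels are present and equal after
#' [normalize_subfamily()]; a missing label on either side is never
#' consistent.
#'
#' @param a,b Subfamily labels (vectors recycle).
#' @return Logical vector.
#' @export
is_consistent <- function(a, b) {
  na <- normalize_subfamily(a)
  nb <- normalize_subfamily(b)
  !is.na(na) & !is.na(nb) & na == nb
}

#' Subfamily-consistency report over a basic set
#'
#' Counts basic-set ORFs whose subfamilies agree between the two
#' composition-based approaches. By default an ORF must also carry topology
#' (`T`) support, mirroring the convention that consistency is only claimed
#' for topology-backed candidates; set `require_tmhmm = FALSE` to count all
#' consistent rows.
#'
#' @param basic Output of [basic_set()].
#' @param require_tmhmm Require `T` in the pred-by code (default `TRUE`).
#' @return List with `count`, `breakdown` (named counts per normalized
#'   subfamily, decreasing) and `orf_ids`.
#' @export
consistency_report <- function(basic, require_tmhmm = TRUE) {
  ok <- basic$subfamily_consistent
  if (require_tmhmm) ok <- ok & grepl("T", basic$pred_by_code, fixed = TRUE)
  hits <- basic[ok, , drop = FALSE]
  fam <- normalize_subfamily(hits$pca_subfamily)
  breakdown <- sort(table(fam), decreasing = TRUE)
  list(count = nrow(hits),
       breakdown = stats::setNames(as.integer(breakdown), names(breakdown)),
       orf_ids = hits$orf_id)
}

#' Keyword screening of annotation descriptions
#'
#' Case-insensitive substring matching of a term list against annotation
#' descriptions, as used to pull GPCR-synonym and GPCR-related-protein hits
#' out of alignment annotations. Each match reports the matching term (and
#' the term's protein type if provided).
#'
#' @param annotations data.frame with columns `id` and `description`.
#' @param term_list Character vector of terms, or data.frame with columns
#'   `term` and `protein_type`.
#' @param prefilter_receptor If `TRUE`, only descriptions containing the
#'   word "receptor" are screened.
#' @return data.frame with columns `id`, `description`, `term` (and
#'   `protein_type`), one row per (annotation, matching term).
#' @export
keyword_screen <- function(annotations, term_list,
                           prefilter_receptor = FALSE) {
  stopifnot(all(c("id", "description") %in% names(annotations)))
  if (is.data.frame(term_list)) {
    terms <- term_list$term
    types <- term_list$protein_type
  } else {
    terms <- as.character(term_list)
    types <- NULL
  }
  if (length(terms) == 0) stop("keyword_screen: empty term list")
  ann <- annotations
  if (prefilter_receptor) {
    ann <- ann[grepl("receptor", ann$description, ignore.case = TRUE), ,
               drop = FALSE]
  }
  terms_lower <- tolower(terms)
  rows <- list()
  for (i in seq_len(nrow(ann))) {
    desc_lower <- tolower(ann$description[i])
    hit <- which(vapply(terms_lower, function(tm) {
      grepl(tm, desc_lower, fixed = TRUE)
    }, logical(1)))
    for (j in hit) {
      row <- data.frame(id = ann$id[i], description = ann$description[i],
                        term = terms[j], stringsAsFactors = FALSE)
      if (!is.null(types)) row$protein_type <- types[j]
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(id = character(), description = character(),
                      term = character(), stringsAsFactors = FALSE)
    if (!is.null(types)) out$protein_type <- character()
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bundled keyword term lists
#'
#' `load_gpcr_synonym_terms()` returns the GPCR-activity synonym terms
#' (GO:0004930 and associated names); `load_gpcr_related_terms()` returns
#' the GPCR-related protein search terms with their protein types. Both are
#' shipped as plain-text package data.
#'
#' @return Character vector, or data.frame with `term` and `protein_type`.
#' @export
load_gpcr_synonym_terms <- function() {
  path <- system.file("extdata", "gpcr_synonym_terms.txt",
                      package = "sevenTMscreen", mustWork = TRUE)
  readLines(path)
}

#' @rdname load_gpcr_synonym_terms
#' @export
load_gpcr_related_terms <- function() {
  path <- system.file("extdata", "gpcr_related_terms.tsv",
                      package = "sevenTMscreen", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a consensus fixture table and expand it to evidence records
#'
#' Reads a TSV with columns `orf_id`, `pred_by`, `pca_class`,
#' `pca_subfamily`, `gpcrpred_class`, `gpcrpred_subfamily` (missing values
#' `-` or `NA`) -- the shape of a published consensus table -- and expands
#' each pred-by letter into a positive evidence record, attaching the class
#' and subfamily labels to the corresponding approach's record.
#'
#' @param path TSV file.
#' @return data.frame of evidence records.
#' @export
read_consensus_fixture <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-", ""))
  needed <- c("orf_id", "pred_by", "pca_class", "pca_subfamily",
              "gpcrpred_class", "gpcrpred_subfamily")
  stopifnot(all(needed %in% names(df)))
  letter_to_source <- stats::setNames(names(.APPROACHES), .APPROACHES)
  rows <- list()
  for (i in seq_len(nrow(df))) {
    letters <- strsplit(df$pred_by[i], "", fixed = TRUE)[[1]]
    for (l in letters) {
      src <- letter_to_source[[l]]
      if (is.null(src)) stop("read_consensus_fixture: unknown code letter ", l)
      cls <- switch(src, PCAGPCR = df$pca_class[i],
                    GPCRPRED = df$gpcrpred_class[i], NA)
      sub <- switch(src, PCAGPCR = df$pca_subfamily[i],
                    GPCRPRED = df$gpcrpred_subfamily[i], NA)
      rows[[length(rows) + 1]] <-
        evidence_record(df$orf_id[i], src, TRUE, cls, sub)
    }
  }
  do.call(rbind, rows)
}

#' Write consensus outputs
#'
#' @param consensus Output of [aggregate_evidence()].
#' @param tsv_path,venn_json_path Output files (either may be `NULL`).
#' @export
write_consensus_report <- function(consensus, tsv_path = NULL,
                                   venn_json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(consensus, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "-")
  }
  if (!is.null(venn_json_path)) {
    jsonlite::write_json(as.list(venn_partition(consensus)), venn_json_path,
                         auto_unbox = TRUE)
  }
  invisible(NULL)
}
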