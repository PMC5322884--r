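# Transmembrane topology: a windowed-hydropathy helix caller (a rough,
# built-in stand-in for an HMM topology predictor) plus the explicit
# length / helix-count / flanking-stop decision tree that sorts ORFs into
# full-length, possible full-length, partial and discarded candidates.

#' Topology classification rules
#'
#' The decision-tree thresholds: ORFs of at least `long_threshold_aa`
#' residues are "long" (enough for seven helices and six loops); long ORFs
#' are candidates when their helix count falls in `long_helix_range`, short
#' ORFs when it falls in `short_helix_range`; an ORF with at least
#' `min_flanking_stops` in-frame stops on *both* sides is treated as a
#' complete coding region.
#'
#' @param long_threshold_aa Long/short length cut in aa (default 235).
#' @param long_helix_range Inclusive helix-count interval for long
#'   candidates (default `c(6, 8)`).
#' @param short_helix_range Inclusive helix-count interval for short
#'   candidates (default `c(3, 6)`).
#' @param min_flanking_stops Stops required on each side (default 2).
#' @return List of class `topology_rules`.
#' @export
topology_rules <- function(long_threshold_aa = 235L,
                           long_helix_range = c(6L, 8L),
                           short_helix_range = c(3L, 6L),
                           min_flanking_stops = 2L) {
  stopifnot(long_threshold_aa >= 1,
            length(long_helix_range) == 2,
            length(short_helix_range) == 2,
            long_helix_range[1] <= long_helix_range[2],
            short_helix_range[1] <= short_helix_range[2],
            min_flanking_stops >= 0)
  structure(list(long_threshold_aa = as.integer(long_threshold_aa),
                 long_helix_range = as.integer(long_helix_range),
                 short_helix_range = as.integer(short_helix_range),
                 min_flanking_stops = as.integer(min_flanking_stops)),
            class = "topology_rules")
}

#' The four topology classes
#'
#' @return Character vector of the class labels in fixed order.
#' @export
tm_classes <- function() {
  c("FULL_LENGTH", "POSSIBLE_FULL_LENGTH", "PARTIAL", "DISCARDED")
}

.topology_call <- function(orf_id, segments, source, protein_length) {
  segments <- segments[order(segments$start), , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(orf_id = orf_id,
                 n_helices = nrow(segments),
                 segments = segments,
                 source = source,
                 protein_length = protein_length),
            class = "topology_call")
}

#' Predict transmembrane helices by windowed hydropathy
#'
#' Kyte-Doolittle window means are computed at every position with a full
#' window (unknown residues score 0); positions above `threshold` are merged
#' into runs, each run is widened by half a window on each side (trimmed at
#' the midpoint when two runs would overlap), and widened segments shorter
#' than `min_helix_len` are dropped. Deterministic. Sequences shorter than
#' `window` yield zero helices.
#'
#' This is a first-pass caller: loops shorter than roughly half a window
#' cannot be resolved and fuse adjacent helices (see the package vignette);
#' ingesting TMHMM output is the fidelity path.
#'
#' @param aa_seq Protein sequence (single string).
#' @param window Sliding-window width in residues (default 19).
#' @param threshold Window-mean hydropathy cutoff (default 1.6).
#' @param min_helix_len Minimum widened segment length (default 17).
#' @param orf_id Optional id stored on the call.
#' @return Object of class `topology_call` with 0-based half-open `segments`.
#' @export
predict_tm_hydropathy <- function(aa_seq, window = 19L, threshold = 1.6,
                                  min_helix_len = 17L, orf_id = NA_character_) {
  if (!nzchar(aa_seq)) stop("predict_tm_hydropathy: empty sequence")
  res <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  n <- length(res)
  kd <- aa_property_table("kd")
  x <- unname(kd[res])
  x[is.na(x)] <- 0
  empty <- data.frame(start = integer(), end = integer())
  if (n < window) {
    return(.topology_call(orf_id, empty, "hydropathy", n))
  }
  means <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 2))
  centers <- which(!is.na(means) & means > threshold)
  if (length(centers) == 0) {
    return(.topology_call(orf_id, empty, "hydropathy", n))
  }
  half <- window %/% 2
  breaks <- c(0, which(diff(centers) > 1), length(centers))
  segs <- data.frame(
    first = centers[breaks[-length(breaks)] + 1],
    last = centers[breaks[-1]]
  )
  # widen by half a window, trimming at the midpoint between adjacent runs
  lo <- pmax(segs$first - half, 1)
  hi <- pmin(segs$last + half, n)
  if (nrow(segs) > 1) {
    for (i in seq_len(nrow(segs) - 1)) {
      if (hi[i] >= lo[i + 1]) {
        mid <- (segs$last[i] + segs$first[i + 1]) %/% 2
        hi[i] <- mid
        lo[i + 1] <- mid + 1
      }
    }
  }
  keep <- (hi - lo + 1) >= min_helix_len
  seg <- data.frame(start = lo[keep] - 1L, end = hi[keep])  # 0-based half-open
  .topology_call(orf_id, seg, "hydropathy", n)
}

#' Convert parsed TMHMM records to topology calls
#'
#' @param records Output of [parse_tmhmm()].
#' @return Named list of `topology_call` objects (source `"tmhmm"`), keyed by
#'   protein id, with segments converted to 0-based half-open coordinates.
#' @export
tmhmm_to_topology <- function(records) {
  out <- lapply(records, function(rec) {
    hx <- rec$segments[rec$segments$kind == "TMhelix", , drop = FALSE]
    seg <- data.frame(start = hx$start - 1L, end = hx$end)
    .topology_call(rec$protein_id, seg, "tmhmm", rec$length)
  })
  stats::setNames(out, vapply(records, `[[`, "", "protein_id"))
}

#' Classify one ORF from length, helix count and flanking stops
#'
#' The decision tree: a long ORF (length >= threshold) with a helix count in
#' the long range is a candidate -- `FULL_LENGTH` when it has the required
#' stops on both sides, `POSSIBLE_FULL_LENGTH` otherwise; long ORFs outside
#' the range are `DISCARDED`. A short ORF with a helix count in the short
#' range is `DISCARDED` when the stop requirement is met (a likely complete
#' protein that cannot hold seven helices) and `PARTIAL` otherwise; short
#' ORFs outside the range are `DISCARDED`.
#'
#' @param length_aa ORF length in amino acids.
#' @param n_helices Predicted transmembrane helix count.
#' @param upstream_stops,downstream_stops In-frame flanking stop counts.
#' @param rules A [topology_rules()] object.
#' @return One of [tm_classes()].
#' @export
classify_tm <- function(length_aa, n_helices, upstream_stops,
                        downstream_stops, rules = topology_rules()) {
  stopifnot(inherits(rules, "topology_rules"))
  if (any(c(length_aa, n_helices, upstream_stops, downstream_stops) < 0)) {
    stop("classify_tm: negative input")
  }
  stops_ok <- upstream_stops >= rules$min_flanking_stops &&
    downstream_stops >= rules$min_flanking_stops
  if (length_aa >= rules$long_threshold_aa) {
    if (n_helices >= rules$long_helix_range[1] &&
        n_helices <= rules$long_helix_range[2]) {
      if (stops_ok) "FULL_LENGTH" else "POSSIBLE_FULL_LENGTH"
    } else {
      "DISCARDED"
    }
  } else {
    if (n_helices >= rules$short_helix_range[1] &&
        n_helices <= rules$short_helix_range[2]) {
      if (stops_ok) "DISCARDED" else "PARTIAL"
    } else {
      "DISCARDED"
    }
  }
}

#' @rdname classify_tm
#' @param orf A single-row ORF data.frame (or list) with `length_aa`,
#'   `upstream_stops`, `downstream_stops`.
#' @param topology A `topology_call` for that ORF.
#' @export
classify_orf <- function(orf, topology, rules = topology_rules()) {
  stopifnot(inherits(topology, "topology_call"))
  classify_tm(orf$length_aa, topology$n_helices,
              orf$upstream_stops, orf$downstream_stops, rules)
}

#' Classify a batch of ORFs
#'
#' Applies [classify_orf()] to every ORF, using topology calls keyed by
#' `orf_id`. Candidates are the union of the `FULL_LENGTH`,
#' `POSSIBLE_FULL_LENGTH` and `PARTIAL` classes.
#'
#' @param orfs ORF data.frame from [find_orfs_set()].
#' @param topologies Named list of `topology_call` objects covering all
#'   `orfs$orf_id`.
#' @param rules A [topology_rules()] object.
#' @return List with `calls` (data.frame: `orf_id`, `length_aa`,
#'   `n_helices`, `upstream_stops`, `downstream_stops`, `class`), `summary`
#'   (named counts per class) and `candidates` (subset of `calls`).
#' @export
classify_batch <- function(orfs, topologies, rules = topology_rules()) {
  missing <- setdiff(orfs$orf_id, names(topologies))
  if (length(missing) > 0) {
    stop("classify_batch: no topology for: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  }
  nh <- vapply(orfs$orf_id, function(id) topologies[[id]]$n_helices, 1L)
  cls <- vapply(seq_len(nrow(orfs)), function(i) {
    classify_tm(orfs$length_aa[i], nh[i],
                orfs$upstream_stops[i], orfs$downstream_stops[i], rules)
  }, character(1))
  calls <- data.frame(orf_id = orfs$orf_id,
                      length_aa = orfs$length_aa,
                      n_helices = unname(nh),
                      upstream_stops = orfs$upstream_stops,
                      downstream_stops = orfs$downstream_stops,
                      class = cls,
                      stringsAsFactors = FALSE)
  summary <- vapply(tm_classes(), function(k) sum(cls == k), 1L)
  list(calls = calls,
       summary = summary,
       candidates = calls[cls != "DISCARDED", , drop = FALSE])
}

#' Write a topology classification report
#'
#' TSV of per-ORF calls plus a JSON per-class count summary.
#'
#' @param batch Output of [classify_batch()].
#' @param tsv_path,json_path Output files (either may be `NULL`).
#' @export
write_topology_report <- function(batch, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(batch$calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as.list(batch$summary), json_path,
                         auto_unbox = TRUE)
  }
  invisible(NULL)
}
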