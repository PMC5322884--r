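# End-to-end orchestration of the screening flow: ORF extraction, topology
# classification, evidence collection, consensus, consistency reporting and
# the optional tree and structure-score stages, writing a reproducible
# report bundle. Stages are exported individually; this module wires them
# together under one configuration.

#' Pipeline configuration
#'
#' @param fasta Path to the unigene FASTA (or `NULL` when `unigenes` is
#'   supplied directly).
#' @param unigenes Optional named character vector / `DNAStringSet`
#'   overriding `fasta`.
#' @param out_dir Output directory for the report bundle.
#' @param orf An [orf_config()].
#' @param rules A [topology_rules()].
#' @param tmhmm_file Optional TMHMM output covering all ORFs; when absent
#'   the built-in hydropathy caller is used.
#' @param evidence Named list of external prediction tables (TSV with
#'   columns `orf_id`, `is_gpcr` Y/N, `class`, `subfamily`), keyed by
#'   approach name (`ALIGNMENT`, `GPCRPRED`, `PCAGPCR`).
#' @param classifier_gpcrpred,classifier_pcagpcr Optional
#'   `standin_classifier` objects (or JSON paths) supplying stand-in
#'   verdicts for the two composition approaches when no external table is
#'   given. The first is applied to every ORF, the second only to ORFs
#'   already positive elsewhere (mirroring a submission-limited service).
#' @param feature_blocks Descriptor blocks for the stand-in classifiers.
#' @param min_sources Basic-set threshold (default 3).
#' @param alignment_file Optional aligned FASTA of candidates for the tree
#'   stage.
#' @param model_dir Optional directory of `<orf_id>.pdb` model files for the
#'   structure stage.
#' @param seed Integer seed recorded in the manifest and used for any
#'   stochastic stage.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta = NULL, unigenes = NULL, out_dir,
                            orf = orf_config(), rules = topology_rules(),
                            tmhmm_file = NULL, evidence = list(),
                            classifier_gpcrpred = NULL,
                            classifier_pcagpcr = NULL,
                            feature_blocks = c("aac", "dpc"),
                            min_sources = 3L, alignment_file = NULL,
                            model_dir = NULL, seed = 1L) {
  stopifnot(min_sources >= 1, min_sources <= 4)
  if (is.null(fasta) && is.null(unigenes)) {
    stop("pipeline_config: need `fasta` or `unigenes`")
  }
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  for (p in c(fasta, tmhmm_file, alignment_file, model_dir,
              unlist(evidence))) {
    if (is.character(p) && !file.exists(p)) {
      stop("pipeline_config: no such path: ", p)
    }
  }
  cfg
}

.load_model <- function(x) {
  if (is.null(x) || inherits(x, "standin_classifier")) return(x)
  load_classifier(x)
}

#' Run the screening pipeline
#'
#' Executes every configured stage and writes the report bundle to
#' `config$out_dir`: ORF FASTA/TSV, topology TSV and per-class summary,
#' evidence TSV, consensus TSV and Venn-partition JSON, basic-set TSV and
#' FASTA, consistency-report JSON, optional Newick tree and structure-score
#' TSV, plus a run manifest (package version, configuration hash, seed and
#' per-stage record counts). Identical configuration and inputs produce an
#' identical bundle.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and file
#'   paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  path <- function(f) file.path(config$out_dir, f)
  stage <- function(name, n_in, n_out) {
    message(sprintf("[%s] in=%d out=%d", name, n_in, n_out))
  }

  unigenes <- if (!is.null(config$unigenes)) {
    stats::setNames(as.character(config$unigenes), names(config$unigenes))
  } else {
    x <- read_fasta(config$fasta)
    stats::setNames(as.character(x), names(x))
  }

  # -- ORF stage
  orfs <- find_orfs_set(unigenes, config$orf)
  if (nrow(orfs) == 0) stop("run_pipeline: ORF stage produced no ORFs")
  write_orf_fasta(orfs, path("orfs.faa"))
  write_orf_tsv(orfs, path("orfs.tsv"))
  stage("orfs", length(unigenes), nrow(orfs))

  # -- topology stage
  topologies <- if (!is.null(config$tmhmm_file)) {
    tmhmm_to_topology(parse_tmhmm(config$tmhmm_file))
  } else {
    stats::setNames(
      lapply(seq_len(nrow(orfs)), function(i) {
        predict_tm_hydropathy(orfs$aa_seq[i], orf_id = orfs$orf_id[i])
      }), orfs$orf_id)
  }
  batch <- classify_batch(orfs, topologies, config$rules)
  write_topology_report(batch, path("topology.tsv"),
                        path("class_summary.json"))
  stage("topology", nrow(orfs), nrow(batch$candidates))

  # -- evidence stage
  ev <- list()
  cls <- batch$calls
  cand <- cls$class != "DISCARDED"
  ev$tmhmm <- do.call(rbind, lapply(which(cand), function(i) {
    evidence_record(cls$orf_id[i], "TMHMM", TRUE, detail = cls$class[i])
  }))
  for (src in names(config$evidence)) {
    ev[[src]] <- parse_prediction_table(config$evidence[[src]], src)
  }
  gmod <- .load_model(config$classifier_gpcrpred)
  pmod <- .load_model(config$classifier_pcagpcr)
  if (!is.null(gmod) && is.null(config$evidence$GPCRPRED)) {
    feats <- feature_matrix(stats::setNames(orfs$aa_seq, orfs$orf_id),
                            blocks = config$feature_blocks)
    pred <- predict(gmod, feats)
    ev$gpcrpred <- do.call(rbind, lapply(seq_len(nrow(pred)), function(i) {
      evidence_record(rownames(pred)[i], "GPCRPRED_STANDIN", pred$is_gpcr[i],
                      pred$gpcr_class[i], pred$subfamily[i],
                      detail = sprintf("conf=%.3f", pred$confidence[i]))
    }))
  }
  pre <- do.call(rbind, ev)
  if (!is.null(pmod) && is.null(config$evidence$PCAGPCR)) {
    pos_ids <- unique(pre$orf_id[pre$is_gpcr])
    if (length(pos_ids) > 0) {
      sel <- orfs[orfs$orf_id %in% pos_ids, ]
      feats <- feature_matrix(stats::setNames(sel$aa_seq, sel$orf_id),
                              blocks = config$feature_blocks)
      pred <- predict(pmod, feats)
      ev$pcagpcr <- do.call(rbind, lapply(seq_len(nrow(pred)), function(i) {
        evidence_record(rownames(pred)[i], "PCAGPCR_STANDIN", pred$is_gpcr[i],
                        pred$gpcr_class[i], pred$subfamily[i],
                        detail = sprintf("conf=%.3f", pred$confidence[i]))
      }))
    }
  }
  evidence <- do.call(rbind, ev)
  rownames(evidence) <- NULL
  utils::write.table(evidence, path("evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  stage("evidence", nrow(orfs), nrow(evidence))

  # -- consensus stage
  consensus <- aggregate_evidence(evidence)
  write_consensus_report(consensus, path("consensus.tsv"), path("venn.json"))
  basic <- basic_set(consensus, config$min_sources)
  utils::write.table(basic, path("basic_set.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  basic_orfs <- orfs[orfs$orf_id %in% basic$orf_id, , drop = FALSE]
  if (nrow(basic_orfs) > 0) {
    write_orf_fasta(basic_orfs, path("basic_set.faa"))
  }
  report <- consistency_report(basic)
  jsonlite::write_json(report, path("consistency.json"), auto_unbox = TRUE)
  stage("consensus", nrow(consensus), nrow(basic))

  # -- optional tree stage
  tree <- NULL
  if (!is.null(config$alignment_file)) {
    aln <- Biostrings::readAAStringSet(config$alignment_file)
    dm <- p_distance_matrix(aln)
    tree <- neighbor_joining(dm)
    write_newick(tree, path("candidates.nwk"))
    utils::write.table(dm, path("distance_matrix.tsv"), sep = "\t",
                       quote = FALSE)
    stage("tree", length(aln), length(tree$tip.label))
  }

  # -- optional structure stage
  scores <- NULL
  if (!is.null(config$model_dir)) {
    scores <- score_model_dir(config$model_dir)
    utils::write.table(scores, path("structure_scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage("structure", nrow(scores), nrow(scores))
  }

  # -- manifest
  cfg_public <- config[c("min_sources", "seed")]
  cfg_public$orf <- unclass(config$orf)
  cfg_public$rules <- unclass(config$rules)
  cfg_json <- jsonlite::toJSON(cfg_public, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "sevenTMscreen",
    version = as.character(utils::packageVersion("sevenTMscreen")),
    seed = config$seed,
    config = cfg_public,
    config_md5 = unname(tools::md5sum(tmp)),
    counts = list(unigenes = length(unigenes), orfs = nrow(orfs),
                  candidates = nrow(batch$candidates),
                  evidence = nrow(evidence), consensus = nrow(consensus),
                  basic_set = nrow(basic),
                  consistent = report$count)
  )
  unlink(tmp)
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(orfs = orfs, batch = batch, evidence = evidence,
                 consensus = consensus, basic_set = basic,
                 consistency = report, tree = tree, structure = scores,
                 manifest = manifest, out_dir = config$out_dir))
}

#' Parse an external prediction table into evidence records
#'
#' TSV with columns `orf_id`, `is_gpcr` (`Y`/`N`), `class`, `subfamily`
#' (missing as `-` or `NA`).
#'
#' @param path TSV file.
#' @param source Approach name the verdicts belong to.
#' @return data.frame of evidence records.
#' @export
parse_prediction_table <- function(path, source) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "-", ""))
  stopifnot(all(c("orf_id", "is_gpcr") %in% names(df)))
  if (!all(df$is_gpcr %in% c("Y", "N"))) {
    stop("parse_prediction_table: is_gpcr must be Y or N")
  }
  do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    evidence_record(df$orf_id[i], source, df$is_gpcr[i] == "Y",
                    df$class[i] %||% NA, df$subfamily[i] %||% NA)
  }))
}
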