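# Alignment-free sequence descriptors. These are the feature families behind
# composition-based GPCR predictors: amino-acid and dipeptide composition,
# pseudo amino acid composition, autocorrelation, CTD and
# quasi-sequence-order, plus a deterministic stand-in classifier so the full
# screening pipeline can run without external web services.

#' Amino-acid composition
#'
#' Frequencies of the 20 standard residues, in fixed alphabetical order.
#' Non-standard residues (X, B, Z, U, ...) are excluded from both numerator
#' and denominator.
#'
#' @param aa_seq Protein sequence (single string).
#' @return Named numeric vector of length 20 summing to 1.
#' @export
aa_composition <- function(aa_seq) {
  res <- .standard_residues(aa_seq)
  if (length(res) == 0) {
    stop("aa_composition: sequence contains no standard residues")
  }
  counts <- table(factor(res, levels = aa_alphabet()))
  stats::setNames(as.numeric(counts) / length(res), aa_alphabet())
}

#' Dipeptide composition
#'
#' Frequencies of the 400 overlapping residue pairs, ordered with the first
#' residue as the major index (AA, AC, ..., AY, CA, ...). Pairs containing a
#' non-standard residue are skipped.
#'
#' @param aa_seq Protein sequence (single string).
#' @return Named numeric vector of length 400 summing to 1.
#' @export
dipeptide_composition <- function(aa_seq) {
  res <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  if (length(res) < 2) {
    stop("dipeptide_composition: sequence must have length >= 2")
  }
  aa <- aa_alphabet()
  first <- res[-length(res)]
  second <- res[-1]
  keep <- first %in% aa & second %in% aa
  if (!any(keep)) {
    stop("dipeptide_composition: no valid standard-residue dipeptides")
  }
  pairs <- paste0(first[keep], second[keep])
  lev <- as.vector(t(outer(aa, aa, paste0)))
  counts <- table(factor(pairs, levels = lev))
  stats::setNames(as.numeric(counts) / sum(counts), lev)
}

#' Pseudo amino-acid composition (type 1)
#'
#' Chou's type-1 pseudo amino acid composition: the 20 residue frequencies
#' extended with `lambda` sequence-order correlation factors computed from
#' normalized hydrophobicity, hydrophilicity and side-chain mass. With
#' `lambda = 0` the result is exactly [aa_composition()].
#'
#' @param aa_seq Protein sequence (single string).
#' @param lambda Number of correlation tiers (rank of sequence-order effect).
#' @param w Weight of the sequence-order terms (default 0.05).
#' @return Named numeric vector of length `20 + lambda` summing to 1.
#' @export
pseudo_aa_composition <- function(aa_seq, lambda = 10, w = 0.05) {
  stopifnot(lambda >= 0, w >= 0)
  res <- .standard_residues(aa_seq)
  n <- length(res)
  if (n == 0) stop("pseudo_aa_composition: no standard residues")
  if (lambda > 0 && n <= lambda) {
    stop("pseudo_aa_composition: sequence length (", n,
         ") must exceed lambda (", lambda, ")")
  }
  props <- list(
    .chou_normalize(aa_property_table("kd")),
    .chou_normalize(aa_property_table("hydrophilicity")),
    .chou_normalize(aa_property_table("mass"))
  )
  f <- as.numeric(table(factor(res, levels = aa_alphabet()))) / n
  theta <- numeric(lambda)
  if (lambda > 0) {
    pv <- vapply(props, function(p) p[res], numeric(n))
    for (k in seq_len(lambda)) {
      idx <- seq_len(n - k)
      # mean squared property difference, averaged over the three properties
      theta[k] <- mean(rowMeans((pv[idx + k, , drop = FALSE] -
                                   pv[idx, , drop = FALSE])^2))
    }
  }
  denom <- sum(f) + w * sum(theta)
  out <- c(f, w * theta) / denom
  names(out) <- c(aa_alphabet(),
                  if (lambda > 0) paste0("lambda", seq_len(lambda)))
  out
}

#' Normalized Moreau-Broto autocorrelation
#'
#' Autocorrelation of a standardized residue property along the sequence:
#' `AC(d) = sum_i P(i) P(i+d) / (n - d)` for lags `d = 1..max_lag`, where `P`
#' is the property table centered and scaled over the 20 standard residues.
#'
#' @param aa_seq Protein sequence (single string).
#' @param property_table Named numeric vector over the 20 standard residues
#'   (default: Kyte-Doolittle hydropathy).
#' @param max_lag Maximum lag (default 30); sequence must be longer than this.
#' @return Named numeric vector of length `max_lag`.
#' @export
autocorrelation <- function(aa_seq, property_table = aa_property_table("kd"),
                            max_lag = 30) {
  res <- .standard_residues(aa_seq)
  n <- length(res)
  if (n <= max_lag) {
    stop("autocorrelation: sequence length (", n,
         ") must exceed max_lag (", max_lag, ")")
  }
  p <- property_table[aa_alphabet()]
  p <- (p - mean(p)) / stats::sd(p)
  x <- p[res]
  out <- vapply(seq_len(max_lag), function(d) {
    idx <- seq_len(n - d)
    sum(x[idx] * x[idx + d]) / (n - d)
  }, numeric(1))
  stats::setNames(out, paste0("lag", seq_len(max_lag)))
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' For each of seven physicochemical properties, residues are mapped to three
#' classes and the descriptor reports: the class composition (3 values),
#' the normalized frequency of adjacent-residue class transitions (3 values),
#' and, per class, the relative sequence positions at which the first,
#' 25%, 50%, 75% and 100% of that class's residues are found (15 values).
#'
#' @param aa_seq Protein sequence (single string).
#' @return Named numeric vector of length 147 (7 properties x 21).
#' @export
ctd_descriptors <- function(aa_seq) {
  res <- .standard_residues(aa_seq)
  n <- length(res)
  if (n < 2) stop("ctd_descriptors: need at least 2 standard residues")
  out <- numeric(0)
  for (prop in names(.CTD_GROUPS)) {
    groups <- .CTD_GROUPS[[prop]]
    cls <- integer(n)
    for (g in 1:3) cls[res %in% groups[[g]]] <- g
    gnames <- names(groups)
    # composition
    comp <- vapply(1:3, function(g) sum(cls == g) / n, numeric(1))
    names(comp) <- paste(prop, "comp", gnames, sep = ".")
    # transitions between distinct classes among adjacent residues
    a <- cls[-n]; b <- cls[-1]
    npair <- n - 1
    tr <- c(
      sum((a == 1 & b == 2) | (a == 2 & b == 1)) / npair,
      sum((a == 1 & b == 3) | (a == 3 & b == 1)) / npair,
      sum((a == 2 & b == 3) | (a == 3 & b == 2)) / npair
    )
    names(tr) <- paste(prop, "trans",
                       c("12", "13", "23"), sep = ".")
    # distribution
    distr <- numeric(0)
    for (g in 1:3) {
      pos <- which(cls == g)
      qv <- if (length(pos) == 0) rep(0, 5) else {
        k <- length(pos)
        idx <- pmax(1, ceiling(k * c(0.0001, 0.25, 0.5, 0.75, 1)))
        pos[idx] / n
      }
      names(qv) <- paste(prop, "distr", gnames[g],
                         c("first", "q25", "q50", "q75", "q100"), sep = ".")
      distr <- c(distr, qv)
    }
    out <- c(out, comp, tr, distr)
  }
  out
}

#' Quasi-sequence-order descriptors
#'
#' Sequence-order coupling numbers `tau_d = sum_i dist(R_i, R_{i+d})^2` for
#' `d = 1..max_lag`, combined with the residue frequencies into the standard
#' quasi-sequence-order vector. The default residue-pair distance is the
#' Euclidean distance over the standardized (hydropathy, hydrophilicity,
#' side-chain mass) triple shipped with the package; any 20 x 20 matrix can
#' be supplied instead.
#'
#' @param aa_seq Protein sequence (single string).
#' @param max_lag Maximum coupling rank (default 30).
#' @param w Weight of the coupling terms (default 0.1).
#' @param dist_matrix Optional 20 x 20 residue distance matrix with
#'   `aa_alphabet()` dimnames.
#' @return Named numeric vector of length `20 + max_lag`.
#' @export
quasi_sequence_order <- function(aa_seq, max_lag = 30, w = 0.1,
                                 dist_matrix = NULL) {
  res <- .standard_residues(aa_seq)
  n <- length(res)
  if (n <= max_lag) {
    stop("quasi_sequence_order: sequence length (", n,
         ") must exceed max_lag (", max_lag, ")")
  }
  if (is.null(dist_matrix)) dist_matrix <- default_residue_distance()
  dm <- dist_matrix[aa_alphabet(), aa_alphabet()]
  tau <- vapply(seq_len(max_lag), function(d) {
    idx <- seq_len(n - d)
    sum(dm[cbind(res[idx], res[idx + d])]^2)
  }, numeric(1))
  f <- as.numeric(table(factor(res, levels = aa_alphabet()))) / n
  denom <- sum(f) + w * sum(tau)
  out <- c(f / denom, w * tau / denom)
  names(out) <- c(aa_alphabet(), paste0("tau", seq_len(max_lag)))
  out
}

#' Default residue-pair physicochemical distance
#'
#' Euclidean distance between residues in the standardized three-property
#' space (hydropathy, hydrophilicity, side-chain mass). Used by
#' [quasi_sequence_order()] when no matrix is supplied.
#'
#' @return 20 x 20 symmetric numeric matrix.
#' @export
default_residue_distance <- function() {
  m <- cbind(
    .chou_normalize(aa_property_table("kd")),
    .chou_normalize(aa_property_table("hydrophilicity")),
    .chou_normalize(aa_property_table("mass"))
  )
  as.matrix(stats::dist(m))
}

#' Assemble a feature matrix for a set of protein sequences
#'
#' @param seqs Named character vector of protein sequences (names become row
#'   names).
#' @param blocks Descriptor blocks to include, any of `"aac"`, `"dpc"`,
#'   `"pseaac"`, `"autocorr"`, `"ctd"`, `"qso"`.
#' @param lambda,max_lag,w Parameters passed to the respective descriptors.
#' @return Numeric matrix, one row per sequence.
#' @export
feature_matrix <- function(seqs, blocks = c("aac", "dpc"),
                           lambda = 10, max_lag = 30, w = 0.05) {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  blocks <- match.arg(blocks, c("aac", "dpc", "pseaac", "autocorr",
                                "ctd", "qso"), several.ok = TRUE)
  one <- function(s) {
    parts <- list()
    if ("aac" %in% blocks) parts$aac <- aa_composition(s)
    if ("dpc" %in% blocks) parts$dpc <- dipeptide_composition(s)
    if ("pseaac" %in% blocks) {
      parts$pseaac <- pseudo_aa_composition(s, lambda = lambda, w = w)
    }
    if ("autocorr" %in% blocks) parts$ac <- autocorrelation(s, max_lag = max_lag)
    if ("ctd" %in% blocks) parts$ctd <- ctd_descriptors(s)
    if ("qso" %in% blocks) parts$qso <- quasi_sequence_order(s, max_lag = max_lag)
    unlist(parts)
  }
  rows <- lapply(seqs, one)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(seqs)
  mat
}

#' Train the stand-in composition classifier
#'
#' A deterministic nearest-centroid classifier on (column-standardized)
#' descriptor vectors. It is an explicit surrogate for external
#' composition-based GPCR predictors: evidence produced from it is tagged as
#' a stand-in, and parsing the real tools' output tables is the fidelity
#' path. Training is order-invariant and fully determined by the data and
#' `seed` (recorded in the model metadata; the decision rule itself uses no
#' randomness).
#'
#' @param x Numeric feature matrix (rows = sequences).
#' @param labels Class label per row. Use `"none"` for non-GPCR and a GPCR
#'   class letter (`"A"`..`"F"`) otherwise.
#' @param seed Integer recorded in the model metadata.
#' @return Object of class `standin_classifier`.
#' @export
train_standin_classifier <- function(x, labels, seed = 1L) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels))
  if (length(unique(labels)) < 2) {
    stop("train_standin_classifier: need at least 2 classes in `labels`")
  }
  mu <- colMeans(x)
  sdev <- apply(x, 2, stats::sd)
  sdev[sdev == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sdev, "/")
  classes <- sort(unique(labels))
  centroids <- t(vapply(classes, function(cl) {
    colMeans(xs[labels == cl, , drop = FALSE])
  }, numeric(ncol(xs))))
  rownames(centroids) <- classes
  structure(list(
    classes = classes,
    centroids = centroids,
    center = mu,
    scale = sdev,
    features = colnames(x),
    metadata = list(type = "nearest_centroid", seed = as.integer(seed),
                    n_train = nrow(x), version = "1")
  ), class = "standin_classifier")
}

#' Predict with the stand-in classifier
#'
#' Returns one class prediction per row: the nearest centroid's label, with a
#' confidence in `[0.5, 1]` from a logistic transform of the margin between
#' the two closest centroids. `is_gpcr` is `TRUE` for any label other than
#' `"none"`, and `gpcr_class` is `NA` for non-GPCR calls.
#'
#' @param object A `standin_classifier`.
#' @param newdata Feature matrix with the training columns.
#' @param ... Unused.
#' @return data.frame with columns `label`, `is_gpcr`, `gpcr_class`,
#'   `subfamily`, `confidence`.
#' @export
predict.standin_classifier <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features)) {
    stopifnot(identical(colnames(x), object$features))
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  d <- vapply(seq_len(nrow(object$centroids)), function(k) {
    rowSums(sweep(xs, 2, object$centroids[k, ])^2)
  }, numeric(nrow(xs)))
  d <- matrix(d, nrow = nrow(xs))
  ord <- apply(d, 1, order)
  best <- ord[1, ]
  second <- ord[2, ]
  margin <- sqrt(d[cbind(seq_len(nrow(d)), second)]) -
    sqrt(d[cbind(seq_len(nrow(d)), best)])
  label <- object$classes[best]
  data.frame(
    label = label,
    is_gpcr = label != "none",
    gpcr_class = ifelse(label == "none", NA_character_, label),
    subfamily = NA_character_,
    confidence = 1 / (1 + exp(-margin)),
    row.names = rownames(x),
    stringsAsFactors = FALSE
  )
}

#' Save / load a stand-in classifier as versioned JSON
#'
#' @param model A `standin_classifier`.
#' @param path File path.
#' @return `load_classifier` returns the restored model.
#' @export
save_classifier <- function(model, path) {
  stopifnot(inherits(model, "standin_classifier"))
  obj <- unclass(model)
  obj$centroids <- list(values = as.vector(model$centroids),
                        dim = dim(model$centroids),
                        rownames = rownames(model$centroids))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cen <- matrix(obj$centroids$values, nrow = obj$centroids$dim[1])
  rownames(cen) <- obj$centroids$rownames
  colnames(cen) <- obj$features
  structure(list(
    classes = obj$classes,
    centroids = cen,
    center = stats::setNames(obj$center, obj$features),
    scale = stats::setNames(obj$scale, obj$features),
    features = obj$features,
    metadata = obj$metadata
  ), class = "standin_classifier")
}
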