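# Candidate phylogeny: p-distances from a supplied multiple alignment and a
# hand-written Saitou-Nei neighbor-joining implementation with a
# deterministic tie-break, exported as Newick. The alignment itself is
# consumed, not computed.

#' Pairwise p-distance matrix from a protein alignment
#'
#' For each pair, the fraction of mismatching columns among columns where
#' neither sequence has a gap (`-` or `.`). Errors on ragged alignments and
#' on pairs with no comparable column.
#'
#' @param alignment Named character vector of aligned sequences, or an
#'   `AAStringSet`.
#' @return Symmetric numeric matrix with zero diagonal and sequence ids as
#'   dimnames.
#' @export
p_distance_matrix <- function(alignment) {
  ids <- names(alignment)
  seqs <- toupper(as.character(alignment))
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  n <- length(seqs)
  if (n < 2) stop("p_distance_matrix: need at least 2 sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    stop("p_distance_matrix: ragged alignment (lengths ",
         paste(unique(lens), collapse = ", "), ")")
  }
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  gap <- chars == "-" | chars == "."
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop("p_distance_matrix: no comparable columns between ",
             ids[i], " and ", ids[j])
      }
      d[i, j] <- d[j, i] <- sum(chars[i, ok] != chars[j, ok]) / sum(ok)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined (ties broken by the lowest row index, then column
#' index, of the current matrix), pendant branch lengths follow the standard
#' formulas, and the final three (or two) nodes are joined into an unrooted
#' tree. Negative branch-length estimates are clamped to zero with a
#' warning. On an additive matrix the generating tree is recovered exactly.
#'
#' @param dm Symmetric distance matrix with unique dimnames (ids).
#' @return An unrooted tree of class [ape::phylo].
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("neighbor_joining: need at least 2 taxa")
  ids <- rownames(dm)
  stopifnot(!is.null(ids), !anyDuplicated(ids),
            isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)),
            all(diag(dm) == 0))
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.15g", x)
  # agglomerate over placeholder labels; real ids (which may contain Newick
  # metacharacters) are restored on the final phylo object
  labels <- paste0("t", seq_len(n))
  d <- dm
  while (nrow(d) > 3) {
    m <- nrow(d)
    rs <- rowSums(d)
    q <- (m - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    # lowest (i, j) among minima, scanning rows then columns
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    li <- bl(d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2)))
    lj <- bl(d[i, j] - (d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))))
    new_label <- sprintf("(%s:%s,%s:%s)", labels[i], fmt(li),
                         labels[j], fmt(lj))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    labels <- c(labels[keep], new_label)
    rownames(d2) <- colnames(d2) <- NULL
    d <- d2
  }
  newick <- if (nrow(d) == 2) {
    sprintf("(%s:%s,%s:%s);", labels[1], fmt(bl(d[1, 2] / 2)),
            labels[2], fmt(bl(d[1, 2] / 2)))
  } else {
    v1 <- bl((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
    v2 <- bl((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
    v3 <- bl((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    sprintf("(%s:%s,%s:%s,%s:%s);", labels[1], fmt(v1),
            labels[2], fmt(v2), labels[3], fmt(v3))
  }
  if (clamped) {
    warning("neighbor_joining: negative branch length estimate clamped to 0")
  }
  tree <- ape::read.tree(text = newick)
  tree$tip.label <- ids[as.integer(sub("^t", "", tree$tip.label))]
  tree
}

.quote_newick_label <- function(x) {
  if (grepl("[](),:;'[ \t]", x)) {
    paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
  } else {
    x
  }
}

#' Serialize a tree to Newick with fixed 6-decimal branch lengths
#'
#' Labels containing Newick metacharacters are single-quoted. Round-trips
#' through [ape::read.tree()] to an isomorphic tree with equal lengths.
#'
#' @param tree An [ape::phylo] tree.
#' @param digits Decimal places for branch lengths (default 6).
#' @return Newick string (with trailing `;`).
#' @export
to_newick <- function(tree, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- paste0("%.", digits, "f")
  rec <- function(node) {
    if (node <= n_tip) {
      .quote_newick_label(tree$tip.label[node])
    } else {
      parts <- vapply(kids[[as.character(node)]], function(e) {
        child <- tree$edge[e, 2]
        paste0(rec(child), ":", sprintf(fmt, tree$edge.length[e]))
      }, character(1))
      paste0("(", paste(parts, collapse = ","), ")")
    }
  }
  paste0(rec(root), ";")
}

#' Write a tree as a Newick file
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output file.
#' @param digits Decimal places for branch lengths.
#' @export
write_newick <- function(tree, path, digits = 6) {
  writeLines(to_newick(tree, digits), path)
  invisible(path)
}
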