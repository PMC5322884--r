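# Signed helix-integrity scoring of 3D model chains: count the helices h of
# a model, give +h when every helix is intact and -h when any is broken.
# +7 flags a strong full-length 7TM candidate; +3..+6 a partial one. Helices
# are assigned from backbone phi/psi dihedrals unless the file declares
# HELIX annotations, which take precedence.

.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' Backbone phi/psi dihedrals of a model chain
#'
#' @param chain A `model_chain` from [read_model_chain()] or
#'   [build_helix_chain()].
#' @return data.frame with `resno`, `phi`, `psi` in degrees (`NA` at chain
#'   termini or next to incomplete residues).
#' @export
backbone_dihedrals <- function(chain) {
  res <- chain$residues
  n <- nrow(res)
  get <- function(i, at) as.numeric(res[i, paste0(at, c("_x", "_y", "_z"))])
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && res$complete[i] && res$complete[i - 1]) {
      phi[i] <- .dihedral(get(i - 1, "c"), get(i, "n"), get(i, "ca"),
                          get(i, "c"))
    }
    if (i < n && res$complete[i] && res$complete[i + 1]) {
      psi[i] <- .dihedral(get(i, "n"), get(i, "ca"), get(i, "c"),
                          get(i + 1, "n"))
    }
  }
  data.frame(resno = res$resno, phi = phi, psi = psi)
}

#' Assign helices (intact or broken) to a model chain
#'
#' Declared HELIX annotations, when present, are taken verbatim as intact
#' helices. Otherwise residues whose phi/psi fall in the helical ranges are
#' grouped into maximal runs of at least `min_run` residues; two or more
#' runs separated by gaps of at most `max_break_gap` residues are paired
#' into one *broken* helix (counted once), and an isolated run is intact
#' only when it reaches `intact_min_len` residues -- shorter isolated
#' fragments are kept but flagged broken.
#'
#' @param chain A `model_chain`.
#' @param min_run Minimum helical run length (default 6).
#' @param phi_range,psi_range Inclusive helical dihedral windows in degrees
#'   (defaults `[-100, -30]` and `[-80, 0]`).
#' @param max_break_gap Maximum coil gap pairing two fragments into one
#'   broken helix (default 4).
#' @param intact_min_len Minimum length of an intact isolated helix
#'   (default 15).
#' @return Object of class `helix_assignment`: list with `segments`
#'   (data.frame `start`, `end`, `intact`, `helix` group index; residue
#'   numbers, inclusive) and `h` (number of distinct helices).
#' @export
assign_helices <- function(chain, min_run = 6L, phi_range = c(-100, -30),
                           psi_range = c(-80, 0), max_break_gap = 4L,
                           intact_min_len = 15L) {
  stopifnot(inherits(chain, "model_chain"))
  hx <- chain$helix_annotations
  if (!is.null(hx) && nrow(hx) > 0) {
    seg <- data.frame(start = hx$start, end = hx$end, intact = TRUE,
                      helix = seq_len(nrow(hx)))
    return(structure(list(segments = seg, h = nrow(hx)),
                     class = "helix_assignment"))
  }
  if (nrow(chain$residues) < 4) {
    stop("assign_helices: need >= 4 residues or declared HELIX annotations")
  }
  di <- backbone_dihedrals(chain)
  helical <- !is.na(di$phi) & !is.na(di$psi) &
    di$phi >= phi_range[1] & di$phi <= phi_range[2] &
    di$psi >= psi_range[1] & di$psi <= psi_range[2]
  # chain termini have one undefined angle; extend runs into a terminal
  # residue whose defined angle is helical
  first_ok <- is.na(di$phi[1]) && !is.na(di$psi[1]) &&
    di$psi[1] >= psi_range[1] && di$psi[1] <= psi_range[2]
  n <- length(helical)
  last_ok <- is.na(di$psi[n]) && !is.na(di$phi[n]) &&
    di$phi[n] >= phi_range[1] && di$phi[n] <= phi_range[2]
  if (first_ok) helical[1] <- TRUE
  if (last_ok) helical[n] <- TRUE
  r <- rle(helical)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_run)
  if (length(keep) == 0) {
    return(structure(list(
      segments = data.frame(start = integer(), end = integer(),
                            intact = logical(), helix = integer()),
      h = 0L), class = "helix_assignment"))
  }
  runs <- data.frame(start = di$resno[starts[keep]],
                     end = di$resno[ends[keep]])
  # group runs: a coil gap of <= max_break_gap pairs fragments into one helix
  group <- integer(nrow(runs))
  group[1] <- 1L
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - runs$end[i - 1] - 1
      group[i] <- if (gap <= max_break_gap) group[i - 1] else group[i - 1] + 1L
    }
  }
  intact <- logical(nrow(runs))
  for (g in unique(group)) {
    idx <- which(group == g)
    intact[idx] <- length(idx) == 1 &&
      (runs$end[idx] - runs$start[idx] + 1) >= intact_min_len
  }
  seg <- data.frame(start = runs$start, end = runs$end, intact = intact,
                    helix = group)
  structure(list(segments = seg, h = length(unique(group))),
            class = "helix_assignment")
}

#' Signed helix-integrity score of a model
#'
#' `score = +h` when every assigned helix is intact, `-h` when any is
#' broken, `0` when no helix was found. Categories: `+7` is
#' `STRONG_FULL_LENGTH`, `+3..+6` is `PARTIAL`, anything else `REJECTED`.
#' `needs_review` flags models with 6-8 helices for the visual-inspection
#' step that an automated score cannot replace.
#'
#' @param assignment A `helix_assignment`.
#' @param orf_id Optional id carried into the result.
#' @return One-row data.frame: `orf_id`, `h`, `intact_count`, `score`,
#'   `category`, `needs_review`.
#' @export
score_model <- function(assignment, orf_id = NA_character_) {
  stopifnot(inherits(assignment, "helix_assignment"))
  h <- assignment$h
  seg <- assignment$segments
  intact_count <- length(unique(seg$helix[seg$intact]))
  all_intact <- h > 0 && all(seg$intact)
  score <- if (h == 0) 0L else if (all_intact) h else -h
  data.frame(orf_id = orf_id, h = h, intact_count = intact_count,
             score = as.integer(score),
             category = score_category(score),
             needs_review = h >= 6 && h <= 8,
             stringsAsFactors = FALSE)
}

#' Map a signed helix score to its category
#'
#' @param score Integer signed score (vectorized).
#' @return `"STRONG_FULL_LENGTH"` for `+7`, `"PARTIAL"` for `+3..+6`,
#'   `"REJECTED"` otherwise.
#' @export
score_category <- function(score) {
  ifelse(score == 7, "STRONG_FULL_LENGTH",
         ifelse(score >= 3 & score <= 6, "PARTIAL", "REJECTED"))
}

# -- ideal-chain construction (fixtures and tests) ---------------------------

# Place atom D given A, B, C and internal coordinates: |CD| = bond,
# angle(BCD) = theta (deg), torsion(ABCD) = chi (deg). Standard NeRF step.
.place_atom <- function(a, b, c, bond, theta, chi) {
  th <- theta * pi / 180
  ch <- chi * pi / 180
  d2 <- c(bond * cos(pi - th),
          bond * cos(ch) * sin(pi - th),
          bond * sin(ch) * sin(pi - th))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  nrm <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  m <- cbind(bc, c(nrm[2] * bc[3] - nrm[3] * bc[2],
                   nrm[3] * bc[1] - nrm[1] * bc[3],
                   nrm[1] * bc[2] - nrm[2] * bc[1]), nrm)
  as.numeric(c + m %*% d2)
}

#' Build an ideal poly-alanine backbone from phi/psi angles
#'
#' Constructs N/CA/C backbone coordinates residue by residue with standard
#' bond lengths and angles (N-CA 1.458, CA-C 1.525, C-N 1.329 A; omega
#' fixed at 180 deg). `phi`/`psi` may be scalars (ideal repeat, e.g. the
#' alpha-helical -57/-47) or per-residue vectors, so kinked and broken
#' chains can be generated analytically for tests.
#'
#' @param n_res Number of residues.
#' @param phi,psi Backbone torsions in degrees (recycled to `n_res`).
#' @param helix_annotations Optional data.frame (`start`, `end`) of declared
#'   helices to attach.
#' @return A `model_chain` object.
#' @export
build_helix_chain <- function(n_res, phi = -57, psi = -47,
                              helix_annotations = NULL) {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  ang_ncac <- 111.2; ang_cacn <- 116.2; ang_cnca <- 121.7
  coords <- matrix(NA_real_, nrow = 3 * n_res, ncol = 3)
  # seed the first residue
  coords[1, ] <- c(0, 0, 0)                       # N1
  coords[2, ] <- c(b_nca, 0, 0)                   # CA1
  th <- ang_ncac * pi / 180
  coords[3, ] <- coords[2, ] + b_cac * c(cos(pi - th), sin(pi - th), 0)  # C1
  idx <- function(i, at) 3 * (i - 1) + match(at, c("N", "CA", "C"))
  for (i in 2:n_res) {
    coords[idx(i, "N"), ] <- .place_atom(
      coords[idx(i - 1, "N"), ], coords[idx(i - 1, "CA"), ],
      coords[idx(i - 1, "C"), ], b_cn, ang_cacn, psi[i - 1])
    coords[idx(i, "CA"), ] <- .place_atom(
      coords[idx(i - 1, "CA"), ], coords[idx(i - 1, "C"), ],
      coords[idx(i, "N"), ], b_nca, ang_cnca, 180)  # omega
    coords[idx(i, "C"), ] <- .place_atom(
      coords[idx(i - 1, "C"), ], coords[idx(i, "N"), ],
      coords[idx(i, "CA"), ], b_cac, ang_ncac, phi[i])
  }
  residues <- data.frame(
    resno = seq_len(n_res),
    n_x = coords[idx(seq_len(n_res), "N"), 1],
    n_y = coords[idx(seq_len(n_res), "N"), 2],
    n_z = coords[idx(seq_len(n_res), "N"), 3],
    ca_x = coords[idx(seq_len(n_res), "CA"), 1],
    ca_y = coords[idx(seq_len(n_res), "CA"), 2],
    ca_z = coords[idx(seq_len(n_res), "CA"), 3],
    c_x = coords[idx(seq_len(n_res), "C"), 1],
    c_y = coords[idx(seq_len(n_res), "C"), 2],
    c_z = coords[idx(seq_len(n_res), "C"), 3]
  )
  residues$complete <- TRUE
  hx <- if (is.null(helix_annotations)) {
    data.frame(start = integer(), end = integer())
  } else helix_annotations
  structure(list(residues = residues, helix_annotations = hx),
            class = "model_chain")
}

#' Score a directory of model chains
#'
#' Reads every `<orf_id>.pdb` under `dir`, assigns helices and scores them.
#'
#' @param dir Directory of PDB files named by ORF id.
#' @param ... Passed to [assign_helices()].
#' @return data.frame, one row per model, as from [score_model()].
#' @export
score_model_dir <- function(dir, ...) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  rows <- lapply(files, function(f) {
    chain <- read_model_chain(f)
    score_model(assign_helices(chain, ...),
                orf_id = sub("\\.pdb$", "", basename(f)))
  })
  do.call(rbind, rows)
}
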