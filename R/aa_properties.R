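# Residue-level constants used by the hydropathy caller, the composition
# descriptors and the synthetic generator. All tables are keyed by the 20
# standard one-letter codes in alphabetical order.

#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter residue codes in alphabetical order. This is the
#' fixed ordering used by every composition descriptor in the package.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Kyte-Doolittle hydropathy index
.KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3
)

# Hopp-Woods hydrophilicity
.HW_HYDROPHILICITY <- c(
  A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
  I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
  R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3
)

# Side-chain mass (Da)
.SIDE_CHAIN_MASS <- c(
  A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82,
  I = 57, K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72,
  R = 101, S = 31, T = 45, V = 43, W = 130, Y = 107
)

#' Residue property tables
#'
#' Returns one of the fixed per-residue property tables shipped with the
#' package: `"kd"` (Kyte-Doolittle hydropathy), `"hydrophilicity"`
#' (Hopp-Woods) or `"mass"` (side-chain mass in Da). These are the constants
#' behind [predict_tm_hydropathy()], [pseudo_aa_composition()],
#' [autocorrelation()] and [quasi_sequence_order()].
#'
#' @param name One of `"kd"`, `"hydrophilicity"`, `"mass"`.
#' @return Named numeric vector over the 20 standard residues.
#' @export
aa_property_table <- function(name = c("kd", "hydrophilicity", "mass")) {
  name <- match.arg(name)
  tab <- switch(name,
    kd = .KD_HYDROPATHY,
    hydrophilicity = .HW_HYDROPHILICITY,
    mass = .SIDE_CHAIN_MASS
  )
  tab[aa_alphabet()]
}

# Three-class groupings used by the CTD descriptors (composition /
# transition / distribution). Standard groupings over seven physicochemical
# properties.
.CTD_GROUPS <- list(
  hydrophobicity = list(
    polar = c("R", "K", "E", "D", "Q", "N"),
    neutral = c("G", "A", "S", "T", "P", "H", "Y"),
    hydrophobic = c("C", "L", "V", "I", "M", "F", "W")
  ),
  vdw_volume = list(
    small = c("G", "A", "S", "T", "P", "D"),
    medium = c("N", "V", "E", "Q", "I", "L"),
    large = c("M", "H", "K", "F", "R", "Y", "W")
  ),
  polarity = list(
    low = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    medium = c("P", "A", "T", "G", "S"),
    high = c("H", "Q", "R", "K", "N", "E", "D")
  ),
  polarizability = list(
    low = c("G", "A", "S", "D", "T"),
    medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    high = c("K", "M", "H", "F", "R", "Y", "W")
  ),
  charge = list(
    positive = c("K", "R"),
    neutral = c("A", "N", "C", "Q", "G", "H", "I", "L", "M", "F",
                "P", "S", "T", "W", "Y", "V"),
    negative = c("D", "E")
  ),
  secondary_structure = list(
    helix = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    strand = c("V", "I", "Y", "C", "W", "F", "T"),
    coil = c("G", "N", "P", "S", "D")
  ),
  solvent_accessibility = list(
    buried = c("A", "L", "F", "C", "G", "I", "V", "W"),
    exposed = c("R", "K", "Q", "E", "N", "D"),
    intermediate = c("M", "S", "P", "T", "H", "Y")
  )
)

# Chou-style normalization: center on the 20-residue mean and divide by the
# root mean square deviation (denominator 20).
.chou_normalize <- function(tab) {
  tab <- tab[aa_alphabet()]
  mu <- mean(tab)
  (tab - mu) / sqrt(mean((tab - mu)^2))
}

# Keep only standard residues of an uppercased sequence; used by every
# descriptor (X, B, Z, U and friends never enter a count).
.standard_residues <- function(aa_seq) {
  stopifnot(is.character(aa_seq), length(aa_seq) == 1)
  res <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  res[res %in% aa_alphabet()]
}
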