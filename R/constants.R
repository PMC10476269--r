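# Monoisotopic masses used throughout. All values in Da.

#' @keywords internal
#' @noRd
ELEMENT_MONO <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Se = 79.9165213,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  Br = 78.9183371,
  F  = 18.99840322,
  I  = 126.904473
)

# average-free monoisotopic residue masses (peptide-bond residues, not free AAs)
RESIDUE_MONO <- c(
  G = 57.02146372, A = 71.03711378, S = 87.03202840, P = 97.05276384,
  V = 99.06841390, T = 101.04767846, C = 103.00918447, L = 113.08406396,
  I = 113.08406396, N = 114.04292744, D = 115.02694302, Q = 128.05857750,
  K = 128.09496301, E = 129.04259308, M = 131.04048508, H = 137.05891186,
  F = 147.06841390, R = 156.10111102, Y = 163.06332852, W = 186.07931294,
  U = 150.95363508  # selenocysteine
)

PROTON_MASS  <- 1.007276466812
H2O_MASS     <- 18.0105646863
# average isotopic spacing used for envelope walking (C13 - C12 approximation)
NEUTRON_SPACING <- 1.00336

# carbamidomethylation of cysteine, the default fixed modification
CARBAMIDOMETHYL_DELTA <- 57.02146372

#' Monoisotopic mass of an elemental formula
#'
#' Computes the monoisotopic mass of a molecular formula such as `"C3H2O"` or
#' `"C8H12O4S2"` by summing embedded IUPAC monoisotopic atomic masses.
#' An empty formula has mass 0.
#'
#' @param formula Character scalar, element symbols each followed by an
#'   optional integer count (e.g. `"C3H2OS"`).
#' @return Monoisotopic mass in Da.
#' @examples
#' mass_from_composition("C3H2O")   # DSSO alkene (short-arm) remnant
#' mass_from_composition("C3H2OS")  # DSSO thiol (long-arm) remnant
#' @export
mass_from_composition <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- gsub("[[:space:]]", "", formula)
  if (nchar(formula) == 0L) return(0.0)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("malformed elemental formula: '", formula, "'")
  }
  total <- 0.0
  for (tok in tokens) {
    sym <- sub("[0-9]*$", "", tok)
    cnt <- sub("^[A-Za-z]+", "", tok)
    n <- if (nchar(cnt)) as.integer(cnt) else 1L
    if (!sym %in% names(ELEMENT_MONO)) {
      stop("unknown element '", sym, "' in formula '", formula, "'")
    }
    total <- total + ELEMENT_MONO[[sym]] * n
  }
  total
}

#' Monoisotopic neutral mass of a peptide
#'
#' Sum of residue masses plus one water, plus any fixed modifications.
#'
#' @param sequence Uppercase amino-acid string.
#' @param fixed_mods Named numeric vector of per-residue mass deltas, e.g.
#'   `c(C = 57.02146)` for carbamidomethylation.
#' @return Neutral monoisotopic mass in Da.
#' @export
peptide_mass <- function(sequence, fixed_mods = c(C = CARBAMIDOMETHYL_DELTA)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1]]
  unknown <- setdiff(aa, names(RESIDUE_MONO))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))
  }
  m <- sum(RESIDUE_MONO[aa]) + H2O_MASS
  if (length(fixed_mods)) {
    hit <- aa %in% names(fixed_mods)
    if (any(hit)) m <- m + sum(fixed_mods[aa[hit]])
  }
  m
}

# ppm distance helpers
ppm_tol_da <- function(mz, ppm) mz * ppm * 1e-6
within_ppm <- function(observed, expected, ppm) {
  abs(observed - expected) <= abs(expected) * ppm * 1e-6
}

mz_from_neutral <- function(neutral_mass, z) neutral_mass / z + PROTON_MASS
neutral_from_mz <- function(mz, z) z * (mz - PROTON_MASS)
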