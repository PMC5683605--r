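# Frozen monoisotopic residue mass table (Da, 5 dp) for the 20 standard
# amino acids, plus the physical constants every mass computation uses.
# These are package-versioned constants: reproducing printed theoretical
# masses requires a fixed table.
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_WATER <- 18.010565
.MASS_PROTON <- 1.00728

# Modification mass deltas (Da)
.MOD_ACETYL <- 42.01057
.MOD_OXIDATION <- 15.99491

#' Monoisotopic residue masses
#'
#' The package's frozen table of monoisotopic residue masses for the 20
#' standard amino acids (Da). All theoretical mass computations in the
#' package derive from this table plus water (18.010565 Da) and the
#' modification deltas for N-terminal acetylation (+42.01057 Da) and
#' methionine oxidation (+15.99491 Da).
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
#' @examples
#' amino_acid_masses()[["G"]]
amino_acid_masses <- function() .AA_MONO

#' Signed parts-per-million mass difference
#'
#' Relative difference between an observed and a theoretical mass,
#' \eqn{(obs - theor)/theor \times 10^6}. Identification is typically gated
#' at 50 ppm.
#'
#' @param observed Observed monoisotopic mass (Da).
#' @param theoretical Theoretical monoisotopic mass (Da); must be > 0.
#' @return Signed ppm difference (numeric, vectorized).
#' @export
#' @examples
#' ppm_difference(817.42, 817.43)
ppm_difference <- function(observed, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    stop("'theoretical' mass must be positive")
  }
  (observed - theoretical) / theoretical * 1e6
}
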