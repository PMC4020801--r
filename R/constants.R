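#' Physical constants and residue masses
#'
#' Monoisotopic masses (Da) used throughout the package. `PROTON_MASS` is the
#' mass of a proton, `ISOTOPE_SPACING` the average spacing between adjacent
#' isotopologue peaks of a peptide, and `WATER_MASS` the condensation water
#' added to the residue-mass sum of a peptide chain.
#'
#' @name constants
#' @keywords internal
NULL

PROTON_MASS <- 1.00728
ISOTOPE_SPACING <- 1.00235
WATER_MASS <- 18.01056

# Modification deltas (Da)
MOD_CARBAMIDOMETHYL <- 57.02146 # fixed, every Cys
MOD_OXIDATION <- 15.99491 # variable, Met
MOD_HYDROXYLATION <- 15.99491 # variable, Pro (collagen-type hydroxyproline)

# Monoisotopic residue masses, 20 standard amino acids
RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

# Acquisition window and sequenced-peptide mass range used as simulator bounds
MZ_RANGE <- c(350, 3000)
PEPTIDE_MASS_RANGE <- c(804, 3953)
CE_TIME_RANGE <- c(19, 50)
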