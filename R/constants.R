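#' Monoisotopic mass constants
#'
#' Monoisotopic masses (Da) used throughout the package: the 20 standard
#' amino-acid residue masses, terminal/adduct bookkeeping constants and the
#' modification deltas for phosphorylation (+HPO3) and cysteine
#' carbamidomethylation.
#'
#' @format A named list:
#' \describe{
#'   \item{residues}{named numeric vector, residue monoisotopic masses}
#'   \item{water}{H2O, 18.010565}
#'   \item{ammonia}{NH3, 17.026549}
#'   \item{h3po4}{H3PO4, 97.976896 (phospho neutral loss)}
#'   \item{phospho}{HPO3, 79.966331 (phospho-S/T mass delta)}
#'   \item{proton}{1.0072765}
#'   \item{carbamidomethyl}{CH2CONH2 on Cys, 57.021464}
#' }
#' @export
MASS <- list(
  residues = c(
    G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
    T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
    N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
    E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
    R = 156.10111, Y = 163.06333, W = 186.07931
  ),
  water = 18.010565,
  ammonia = 17.026549,
  h3po4 = 97.976896,
  phospho = 79.966331,
  proton = 1.0072765,
  carbamidomethyl = 57.021464
)

# the 20 standard one-letter codes, for validation
STANDARD_AA <- names(MASS$residues)
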