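# Unit system of the simulation core: length nm, time ns, per-molecule kinetics.
# All conversions from molar rate constants are centralized here.

AVOGADRO <- 6.02214076e23

# 1 M^-1 s^-1 expressed in nm^3 ns^-1 molecule^-1:
# 1 L = 1e24 nm^3, 1 s = 1e9 ns.
K_MOLAR_TO_NM3_NS <- 1e24 / (AVOGADRO * 1e9)

# 1 molecule per 100 eV in micromol per joule.
GVALUE_UMOL_PER_J <- 0.10364

#' Convert a bimolecular rate constant to per-molecule units
#'
#' Converts a rate constant from M^-1 s^-1 to nm^3 ns^-1 (per molecule pair),
#' the internal unit system of the IRT engine.
#'
#' @param k25 Rate constant in M^-1 s^-1.
#' @return Rate constant in nm^3/ns.
#' @examples
#' k_molar_to_engine(1.7e10)
#' @export
k_molar_to_engine <- function(k25) {
  stopifnot(is.numeric(k25))
  k25 * K_MOLAR_TO_NM3_NS
}

#' Convert radiation chemical yields to SI units
#'
#' G values in molecules per 100 eV are converted to micromoles per joule
#' (1 molecule/100 eV = 0.10364 umol/J).
#'
#' @param g Yield in molecules per 100 eV (vectorized).
#' @return Yield in umol/J.
#' @examples
#' convert_gvalue_units(15.5)
#' @export
convert_gvalue_units <- function(g) {
  stopifnot(is.numeric(g), all(is.finite(g)))
  g * GVALUE_UMOL_PER_J
}
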