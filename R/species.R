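# Species catalogue for the aerated Fricke-cystamine system at pH 0.46.
#
# Charges on the cystamine family include the two protonated amino groups
# (pKa 8.7-9, fully protonated below pH 8), so RSSR carries +2, its radical
# cation +3, the disulfide electron adduct +1, and single-arm fragments +1.
# Diffusion coefficients are 25 C literature values in 1e-9 m^2/s, which is
# numerically identical to nm^2/ns, the engine unit.
#
# Superoxide and HO2- are never instantiated: at pH 0.46 their protonations
# (pKa 4.8 and 11.6) are treated as instantaneous and products are written
# directly in the acid forms HO2* and H2O2.

#' Default species table
#'
#' Returns the species catalogue of the default reaction scheme: every trace
#' (track) species and every bulk solute, with charge, diffusion coefficient,
#' elemental composition, and default bulk concentration.
#'
#' @param cystamine_conc Cystamine (RSSR) concentration in mol/L.
#' @param fe2_conc Ferrous ion concentration in mol/L (standard Fricke: 1e-3).
#' @param o2_conc Dissolved oxygen in mol/L (air-saturated: 2.5e-4).
#' @param hplus_conc Proton background of 0.4 M H2SO4 with the first
#'   dissociation complete (0.4 M).
#' @return A tibble with one row per species: `name`, `charge`,
#'   `diffusion_coefficient` (nm^2/ns), `is_bulk`, `conc` (mol/L), and
#'   elemental composition columns `nH`, `nO`, `nS`, `nN`, `nC`, `nFe`.
#' @examples
#' default_species()
#' @export
default_species <- function(cystamine_conc = 0, fe2_conc = 1e-3,
                            o2_conc = 2.5e-4, hplus_conc = 0.4) {
  stopifnot(cystamine_conc >= 0, fe2_conc >= 0, o2_conc >= 0, hplus_conc >= 0)
  sp <- tibble::tribble(
    ~name,     ~charge, ~diffusion_coefficient, ~is_bulk, ~conc, ~nH, ~nO, ~nS, ~nN, ~nC, ~nFe,
    "e_aq",       -1L,   4.90, FALSE, 0,      0L, 0L, 0L, 0L, 0L, 0L,
    "H",           0L,   7.00, FALSE, 0,      1L, 0L, 0L, 0L, 0L, 0L,
    "OH",          0L,   2.20, FALSE, 0,      1L, 1L, 0L, 0L, 0L, 0L,
    "H2",          0L,   4.80, FALSE, 0,      2L, 0L, 0L, 0L, 0L, 0L,
    "H2O2",        0L,   2.30, FALSE, 0,      2L, 2L, 0L, 0L, 0L, 0L,
    "H3Op",        1L,   9.46, TRUE,  NA,     3L, 1L, 0L, 0L, 0L, 0L,
    "OHm",        -1L,   5.27, FALSE, 0,      1L, 1L, 0L, 0L, 0L, 0L,
    "O2",          0L,   2.40, TRUE,  NA,     0L, 2L, 0L, 0L, 0L, 0L,
    "HO2",         0L,   2.30, FALSE, 0,      1L, 2L, 0L, 0L, 0L, 0L,
    "O3P",         0L,   2.00, FALSE, 0,      0L, 1L, 0L, 0L, 0L, 0L,
    "O3",          0L,   1.75, FALSE, 0,      0L, 3L, 0L, 0L, 0L, 0L,
    "Fe2p",        2L,   0.72, TRUE,  NA,     0L, 0L, 0L, 0L, 0L, 1L,
    "Fe3p",        3L,   0.60, FALSE, 0,      0L, 0L, 0L, 0L, 0L, 1L,
    "RSSR",        2L,   0.60, TRUE,  NA,    14L, 0L, 2L, 2L, 4L, 0L,
    "RSSRm",       1L,   0.60, FALSE, 0,     14L, 0L, 2L, 2L, 4L, 0L,
    "RSSRp",       3L,   0.60, FALSE, 0,     14L, 0L, 2L, 2L, 4L, 0L,
    "RSSR2p",      4L,   0.60, FALSE, 0,     14L, 0L, 2L, 2L, 4L, 0L,
    "RS",          1L,   0.70, FALSE, 0,      7L, 0L, 1L, 1L, 2L, 0L,
    "RSm",         0L,   0.70, FALSE, 0,      7L, 0L, 1L, 1L, 2L, 0L,
    "RSH",         1L,   0.80, FALSE, 0,      8L, 0L, 1L, 1L, 2L, 0L,
    "RSOO",        1L,   0.60, FALSE, 0,      7L, 2L, 1L, 1L, 2L, 0L,
    "RSOOH",       1L,   0.60, FALSE, 0,      8L, 2L, 1L, 1L, 2L, 0L,
    "RSSSR",       2L,   0.55, FALSE, 0,     14L, 0L, 3L, 2L, 4L, 0L,
    "R",           1L,   0.70, FALSE, 0,      7L, 0L, 0L, 1L, 2L, 0L,
    "ROO",         1L,   0.60, FALSE, 0,      7L, 2L, 0L, 1L, 2L, 0L,
    "ROOH",        1L,   0.60, FALSE, 0,      8L, 2L, 0L, 1L, 2L, 0L
  )
  sp$conc[sp$name == "H3Op"] <- hplus_conc
  sp$conc[sp$name == "O2"] <- o2_conc
  sp$conc[sp$name == "Fe2p"] <- fe2_conc
  sp$conc[sp$name == "RSSR"] <- cystamine_conc
  sp
}

#' Bulk solution description for the standard Fricke-cystamine system
#'
#' Collects the background solute concentrations and computes the effective
#' ionic strength from a fixed speciation assumption: the first dissociation
#' of 0.4 M H2SO4 complete (H+ 0.4 M, HSO4- 0.4 M), FeSO4 fully dissociated
#' (Fe2+ + SO4^2-, 1 mM each), and cystamine as its dihydrochloride salt
#' (RSSR^2+ + 2 Cl-). This gives I = 0.404 + 3 [RSSR] mol/L.
#'
#' @inheritParams default_species
#' @param ionic_strength Optional override of the computed ionic strength.
#' @return A list of class `bulk_solution` with elements `concentrations`
#'   (named numeric, mol/L) and `ionic_strength` (mol/L).
#' @examples
#' bulk_solution(cystamine_conc = 1e-3)
#' @export
bulk_solution <- function(cystamine_conc = 0, fe2_conc = 1e-3,
                          o2_conc = 2.5e-4, hplus_conc = 0.4,
                          ionic_strength = NULL) {
  conc <- c(H3Op = hplus_conc, O2 = o2_conc, Fe2p = fe2_conc,
            RSSR = cystamine_conc)
  if (any(conc < 0)) stop("bulk concentrations must be >= 0")
  if (is.null(ionic_strength)) {
    # 1/2 sum c z^2 over H+, HSO4-, Fe2+, SO4^2-, RSSR^2+, 2 Cl-
    ionic_strength <- 0.5 * (hplus_conc + hplus_conc +
                               4 * fe2_conc + 4 * fe2_conc +
                               4 * cystamine_conc + 2 * cystamine_conc)
  }
  if (ionic_strength < 0) stop("ionic_strength must be >= 0")
  structure(list(concentrations = conc, ionic_strength = ionic_strength),
            class = "bulk_solution")
}
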