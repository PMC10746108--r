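# Experiment drivers: the stoichiometric calculator, kinetics runs,
# concentration x LET scans, and the paired multiple-ionization comparison.

#' Stoichiometric Fricke yield from primary (escape) yields
#'
#' G(Fe3+) = 3\[g(H) + g(HO2)\] + g(OH) + 2 g(H2O2): each H atom is converted
#' by oxygen to HO2, which oxidizes three ferrous ions in sequence (via the
#' intermediate H2O2 and the OH it releases), while an escaping OH oxidizes
#' one and an escaping H2O2 two.
#'
#' @param g_H,g_OH,g_H2O2,g_HO2 Primary yields in molecules per 100 eV.
#' @return G(Fe3+) in molecules per 100 eV.
#' @examples
#' fricke_stoichiometric_yield(3.70, 2.90, 0.80, 0.02)  # 15.66
#' @export
fricke_stoichiometric_yield <- function(g_H, g_OH, g_H2O2, g_HO2 = 0) {
  g <- c(g_H, g_OH, g_H2O2, g_HO2)
  if (any(!is.finite(g)) || any(g < 0))
    stop("primary yields must be finite and >= 0")
  3 * (g_H + g_HO2) + g_OH + 2 * g_H2O2
}

#' Kinetics experiment with replicate error bars
#'
#' Thin driver over [simulate_fricke_kinetics()] mirroring the reported
#' figure protocol: averages time-dependent G(Fe3+) and its per-reaction
#' extents over replicate track segments.
#'
#' @inheritParams simulate_fricke_kinetics
#' @return A `fricke_kinetics` object.
#' @export
run_kinetics_experiment <- function(energy_per_nucleon = NULL, let = NULL,
                                    cystamine_conc = 0, mi_probability = 0,
                                    replicates = 10, seed = 1, ...) {
  simulate_fricke_kinetics(energy_per_nucleon = energy_per_nucleon, let = let,
                           cystamine_conc = cystamine_conc,
                           mi_probability = mi_probability,
                           replicates = replicates, seed = seed, ...)
}

#' 200-s Fricke yield over a cystamine-concentration x LET grid
#'
#' @param let LET values (keV/um); alternatively `energy_per_nucleon`.
#' @param energy_per_nucleon Beam energies (MeV/u), converted via
#'   [let_for_energy()].
#' @param conc Cystamine concentrations (mol/L); may include 0.
#' @param mi_probability Double-ionization fraction (0 = off).
#' @param replicates Track segments per grid point.
#' @param seed Base seed; each grid point gets a distinct derived seed.
#' @param ... Passed to [simulate_fricke_yield()] (e.g. `segment_um`,
#'   `target_particles`).
#' @return A tibble of class `fricke_scan`: `let`, `conc`, `G200`, `se`,
#'   `n`, `seed`; metadata in `attr(, "meta")`.
#' @export
run_concentration_scan <- function(let = NULL, energy_per_nucleon = NULL,
                                   conc = 10^seq(-6, 0, by = 1),
                                   mi_probability = 0, replicates = 5,
                                   seed = 1, ...) {
  if (is.null(let)) {
    if (is.null(energy_per_nucleon)) stop("give let or energy_per_nucleon")
    let <- let_for_energy(energy_per_nucleon)
  }
  if (length(conc) == 0 || length(let) == 0) stop("empty scan grid")
  grid <- tidyr::expand_grid(let = let, conc = conc)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(k) {
    pseed <- (seed + 104729L * k) %% .Machine$integer.max
    g <- simulate_fricke_yield(let = grid$let[k], cystamine_conc = grid$conc[k],
                               mi_probability = mi_probability,
                               replicates = replicates, seed = pseed,
                               return_all = TRUE, ...)
    tibble::tibble(let = grid$let[k], conc = grid$conc[k], G200 = mean(g),
                   se = if (length(g) > 1) stats::sd(g) / sqrt(length(g)) else NA_real_,
                   n = length(g), seed = pseed)
  })
  attr(rows, "meta") <- list(mi_probability = mi_probability,
                             replicates = replicates, seed = seed)
  class(rows) <- c("fricke_scan", class(rows))
  rows
}

#' Paired comparison of the multiple-ionization channel
#'
#' Runs the concentration scan twice at the same LET with identical seeds -
#' once without and once with the double-ionization channel - and reports
#' the per-concentration relative reduction in the 200-s yield. Seed pairing
#' is exact: the MI conversion is the last random step of track generation,
#' so both arms share every preceding draw.
#'
#' @param conc Cystamine concentrations (mol/L).
#' @param let LET (keV/um); default 248 (6 MeV/u carbon ions).
#' @param mi_probability Double-ionization fraction for the MI arm (> 0).
#' @param replicates Track segments per point.
#' @param seed Base seed shared by both arms.
#' @param ... Passed to [simulate_fricke_yield()].
#' @return A tibble of class `fricke_mi`: `conc`, `G_off`, `G_on`,
#'   `se_off`, `se_on`, `rel_reduction`.
#' @export
run_mi_comparison <- function(conc = c(1e-3, 1), let = 248,
                              mi_probability = 0.25, replicates = 5,
                              seed = 1, ...) {
  if (mi_probability < 0) stop("mi_probability must be >= 0")
  rows <- purrr::map_dfr(seq_along(conc), function(k) {
    pseed <- (seed + 104729L * k) %% .Machine$integer.max
    g0 <- simulate_fricke_yield(let = let, cystamine_conc = conc[k],
                                mi_probability = 0, replicates = replicates,
                                seed = pseed, return_all = TRUE, ...)
    g1 <- simulate_fricke_yield(let = let, cystamine_conc = conc[k],
                                mi_probability = mi_probability,
                                replicates = replicates, seed = pseed,
                                return_all = TRUE, ...)
    se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    tibble::tibble(conc = conc[k], G_off = mean(g0), G_on = mean(g1),
                   se_off = se(g0), se_on = se(g1),
                   rel_reduction = (mean(g0) - mean(g1)) / mean(g0))
  })
  attr(rows, "meta") <- list(let = let, mi_probability = mi_probability,
                             replicates = replicates, seed = seed)
  class(rows) <- c("fricke_mi", class(rows))
  rows
}
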