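# Reaction scheme for aerated Fricke-cystamine solutions.
#
# The ferrous-ion oxidation set (ids 6-9) and the cystamine set (ids 10-21)
# carry the printed 25 C rate constants. The intratrack pure-water set
# (ids W1-W20) is a compiled Elliot/Buxton-style selection restricted to the
# species that matter at pH 0.46: acid-base forms are pre-resolved (superoxide
# appears only as HO2*, peroxide anion only as H2O2), and OH- is an inert
# product sink. H2O and H+ participate implicitly where a reaction's element
# or charge balance requires them; the balance checker solves for those
# implicit counts and rejects anything else.

#' Assemble a validated reaction network
#'
#' @param species Species tibble as returned by [default_species()].
#' @param reactions Reaction tibble: columns `id` (character), `reactants`
#'   (list of 1-2 species names), `products` (list of 0-4 species names),
#'   `k25` (M^-1 s^-1 for bimolecular channels), `kinetic_class`, `no_ionic`
#'   (exempt from ionic-strength correction), `bulk_stage` (participates in
#'   the homogeneous continuation), `note`.
#' @param check Validate the network (unknown species, positive rates,
#'   element/charge balance with implicit H2O/H+)?
#' @return A list of class `reaction_network` with elements `species` and
#'   `reactions`.
#' @export
reaction_network <- function(species, reactions, check = TRUE) {
  net <- structure(list(species = species, reactions = reactions),
                   class = "reaction_network")
  if (check) validate_network(net)
  net
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$reactions), " reactions among ",
      nrow(x$species), " species\n", sep = "")
  invisible(x)
}

new_reaction_row <- function(id, reactants, products, k25,
                             kinetic_class = "fully-diffusion-controlled",
                             no_ionic = FALSE, bulk_stage = TRUE, note = "") {
  tibble::tibble(id = id, reactants = list(reactants), products = list(products),
                 k25 = k25, kinetic_class = kinetic_class, no_ionic = no_ionic,
                 bulk_stage = bulk_stage, note = note)
}

#' Default reaction scheme of the Fricke-cystamine system
#'
#' Ships the printed ferrous (6-9) and cystamine (10-21) reactions with their
#' 25 C rate constants, a standard pure-water intratrack set (W1-W17), and the
#' triplet-oxygen channels (W18-W20) used when the double-ionization channel
#' of water is enabled.
#'
#' @inheritParams default_species
#' @return A `reaction_network`.
#' @examples
#' net <- default_scheme()
#' subset(net$reactions, id == "8")$k25  # 52 M^-1 s^-1
#' @export
default_scheme <- function(cystamine_conc = 0, fe2_conc = 1e-3,
                           o2_conc = 2.5e-4, hplus_conc = 0.4) {
  fdc <- "fully-diffusion-controlled"
  pdc <- "partially-diffusion-controlled"
  pfo <- "bulk-pseudo-first-order"
  rx <- dplyr::bind_rows(
    # --- ferric-ion production from water radiolysis products
    new_reaction_row("6",  c("OH", "Fe2p"),   c("Fe3p", "OHm"),         3.4e8, pfo, note = "Fe2+ oxidation by OH"),
    new_reaction_row("7",  c("HO2", "Fe2p"),  c("Fe3p", "H2O2"),        7.9e5, pfo, note = "HO2- product protonated instantly"),
    new_reaction_row("8",  c("H2O2", "Fe2p"), c("Fe3p", "OH", "OHm"),   52,    pfo, note = "Fenton step"),
    new_reaction_row("9",  c("H", "Fe2p"),    c("Fe3p", "H2"),          1.3e7, pfo, bulk_stage = FALSE,
                     note = "minor channel; intratrack stage only (+ H+ implicit)"),
    # --- cystamine chemistry
    new_reaction_row("10", c("e_aq", "RSSR"),  c("RSSRm"),              4.1e10, fdc, note = "electron adduct"),
    new_reaction_row("11", c("H", "RSSR"),     c("RS", "RSH"),          8e9,   pdc),
    new_reaction_row("12", c("OH", "RSSR"),    c("RSSRp"),              1.7e10, fdc, note = "+ H+ implicit, H2O product"),
    new_reaction_row("13", c("RSSRm", "H3Op"), c("RS", "RSH"),          4.2e9, pdc),
    new_reaction_row("14", c("RS", "O2"),      c("RSOO"),               2e9,   pfo),
    new_reaction_row("15", c("RSOO", "Fe2p"),  c("Fe3p", "RSOOH"),      1e7,   pfo, note = "+ H+ implicit"),
    new_reaction_row("16", c("RS", "Fe2p"),    c("Fe3p", "RSm"),        2.5e8, pfo),
    new_reaction_row("17", c("RS", "RSSR"),    c("RSSSR", "R"),         1e6,   pfo),
    new_reaction_row("18", c("R", "O2"),       c("ROO"),                2e9,   pfo),
    new_reaction_row("19", c("ROO", "Fe2p"),   c("Fe3p", "ROOH"),       7.9e5, pfo, note = "+ H+ implicit"),
    new_reaction_row("20", c("RSSRp", "Fe2p"), c("Fe3p", "RSSR"),       2e6,   pfo),
    new_reaction_row("21", c("RSSRp", "RSSRp"), c("RSSR2p", "RSSR"),    2.5e9, fdc, bulk_stage = FALSE,
                     note = "disproportionation; intratrack pairs only in the single-track limit"),
    new_reaction_row("22", c("RS", "RS"),       c("RSSR"),              1.5e9, pdc, bulk_stage = FALSE,
                     note = "thiyl dimerization (full cystamine scheme); governs the >0.1 M plateau"),
    # --- pure-water intratrack set
    new_reaction_row("W1",  c("e_aq", "e_aq"), c("H2", "OHm", "OHm"),   5.5e9, fdc, no_ionic = TRUE,
                     note = "exempt from ionic-strength correction"),
    new_reaction_row("W2",  c("e_aq", "H"),    c("H2", "OHm"),          2.5e10, fdc),
    new_reaction_row("W3",  c("e_aq", "OH"),   c("OHm"),                3.0e10, fdc),
    new_reaction_row("W4",  c("e_aq", "H2O2"), c("OH", "OHm"),          1.1e10, fdc),
    new_reaction_row("W5",  c("e_aq", "H3Op"), c("H"),                  2.3e10, fdc),
    new_reaction_row("W6",  c("e_aq", "O2"),   c("HO2"),                1.9e10, pfo, note = "superoxide protonated instantly"),
    new_reaction_row("W7",  c("e_aq", "HO2"),  c("H2O2"),               1.3e10, fdc),
    new_reaction_row("W8",  c("H", "H"),       c("H2"),                 7.8e9, pdc),
    new_reaction_row("W9",  c("H", "OH"),      character(0),            7.0e9, pdc, note = "water reformation"),
    new_reaction_row("W10", c("H", "H2O2"),    c("OH"),                 9.0e7, pdc),
    new_reaction_row("W11", c("H", "O2"),      c("HO2"),                2.1e10, pfo),
    new_reaction_row("W12", c("H", "HO2"),     c("H2O2"),               1.0e10, pdc),
    new_reaction_row("W13", c("OH", "OH"),     c("H2O2"),               5.5e9, pdc),
    new_reaction_row("W14", c("OH", "H2O2"),   c("HO2"),                2.7e7, pdc),
    new_reaction_row("W15", c("OH", "HO2"),    c("O2"),                 7.9e9, pdc),
    new_reaction_row("W16", c("OH", "H2"),     c("H"),                  4.2e7, pdc),
    new_reaction_row("W17", c("HO2", "HO2"),   c("H2O2", "O2"),         8.3e5, pdc),
    # --- triplet oxygen channels (double-ionization chemistry)
    new_reaction_row("W18", c("O3P", "OH"),    c("HO2"),                2.0e10, fdc),
    new_reaction_row("W19", c("O3P", "O3P"),   c("O2"),                 2.2e9, pdc),
    new_reaction_row("W20", c("O3P", "O2"),    c("O3"),                 4.0e9, pfo, note = "ozone is an inert sink here"),
    new_reaction_row("W21", c("O3P", "H"),     c("OH"),                 2.0e10, fdc),
    new_reaction_row("W22", c("O3P", "e_aq"),  c("OH", "OHm"),          2.0e10, fdc,
                     note = "via O- + water")
  )
  reaction_network(default_species(cystamine_conc, fe2_conc, o2_conc, hplus_conc), rx)
}

# ---------------------------------------------------------------------------
# validation

balance_one <- function(net, i) {
  comp_cols <- c("nH", "nO", "nS", "nN", "nC", "nFe")
  sp <- net$species
  r <- net$reactions[i, ]
  side <- function(names) {
    idx <- match(names, sp$name)
    if (anyNA(idx)) stop("reaction ", r$id, ": unknown species ",
                         paste(names[is.na(idx)], collapse = ", "), call. = FALSE)
    m <- sp[idx, comp_cols, drop = FALSE]
    c(colSums(as.matrix(m)), charge = sum(sp$charge[idx]))
  }
  d <- side(r$reactants[[1]]) - side(r$products[[1]])
  n_h2o <- d[["nO"]]                 # implicit H2O on the product side
  n_hplus <- d[["nH"]] - 2 * n_h2o   # implicit H+ on the product side
  ok <- (d[["charge"]] == n_hplus) && all(d[c("nS", "nN", "nC", "nFe")] == 0)
  list(ok = ok, n_h2o = n_h2o, n_hplus = n_hplus)
}

validate_network <- function(net) {
  sp <- net$species
  if (anyDuplicated(sp$name)) stop("duplicated species names")
  if (any(sp$diffusion_coefficient < 0)) stop("diffusion coefficients must be >= 0")
  bulk_conc <- sp$conc[sp$is_bulk]
  if (any(is.na(bulk_conc)) || any(bulk_conc < 0))
    stop("bulk species need a defined concentration >= 0")
  rx <- net$reactions
  if (anyDuplicated(rx$id)) stop("duplicated reaction ids")
  if (any(rx$k25 <= 0)) stop("k25 must be > 0 for reaction(s) ",
                             paste(rx$id[rx$k25 <= 0], collapse = ", "))
  for (i in seq_len(nrow(rx))) {
    nr <- length(rx$reactants[[i]])
    if (nr < 1 || nr > 2) stop("reaction ", rx$id[i], ": needs 1-2 reactants")
    b <- balance_one(net, i)
    if (!b$ok) stop("reaction ", rx$id[i], ": element/charge balance fails")
  }
  invisible(net)
}

# ---------------------------------------------------------------------------
# rate-constant arithmetic

#' Ionic-strength correction of a rate constant between ions
#'
#' Brønsted–Bjerrum correction at 25 C with the Davies-style
#' sqrt(I)/(1+sqrt(I)) term:
#' k(I) = k25 * 10^(1.02 zA zB sqrt(I)/(1+sqrt(I))).
#' Identity when zA*zB = 0 or I = 0. The hydrated-electron self-recombination
#' is exempt in the default scheme (its `no_ionic` flag), reflecting the lack
#' of an observed ionic-strength effect for that reaction.
#'
#' @param k25 Infinite-dilution rate constant (M^-1 s^-1).
#' @param z_a,z_b Reactant charges (elementary units).
#' @param I Ionic strength (mol/L), >= 0.
#' @return Corrected rate constant, same units as `k25`.
#' @examples
#' correct_for_ionic_strength(1e10, 1, 2, 0.1) / 1e10  # ~3.09
#' @export
correct_for_ionic_strength <- function(k25, z_a, z_b, I) {
  if (any(I < 0)) stop("ionic strength must be >= 0")
  s <- sqrt(I)
  k25 * 10^(1.02 * z_a * z_b * s / (1 + s))
}

#' Characteristic scavenging time
#'
#' The inverse of the scavenging power k\[S\]: the mean time at which a radical
#' is removed by a homogeneously distributed solute S.
#'
#' @param k Bimolecular rate constant (M^-1 s^-1), > 0.
#' @param c Scavenger concentration (mol/L), > 0.
#' @return Time in seconds.
#' @examples
#' scavenging_time(4.1e10, 1e-4)  # ~0.25 us: e_aq + cystamine
#' @export
scavenging_time <- function(k, c) {
  if (any(k <= 0) || any(c <= 0)) stop("k and c must be > 0")
  1 / (k * c)
}

#' Competition (branching) fractions among parallel pseudo-first-order channels
#'
#' @param k Rate constants of the channels (M^-1 s^-1).
#' @param c Scavenger concentrations (mol/L), same length as `k`.
#' @return Fractions k_i c_i / sum(k_j c_j); they sum to 1.
#' @examples
#' branching_fractions(c(3.4e8, 1.7e10), c(1e-3, 1e-3))  # OH: Fe2+ vs RSSR
#' @export
branching_fractions <- function(k, c) {
  stopifnot(length(k) == length(c), length(k) >= 1)
  p <- k * c
  if (any(p < 0)) stop("all k*c must be >= 0")
  tot <- sum(p)
  if (tot <= 0) stop("at least one channel must have positive rate")
  p / tot
}

#' Effective encounter radius of a diffusion-influenced reaction
#'
#' Inverts the Smoluchowski relation k = 4 pi D R: every bimolecular channel
#' (fully or partially diffusion-controlled) is mapped to the effective
#' radius that reproduces its observed 25 C rate constant
#' (Collins–Kimball effective-radius treatment).
#'
#' @param k25 Rate constant in M^-1 s^-1, > 0.
#' @param D_mutual Mutual diffusion coefficient (sum of the pair's
#'   coefficients) in nm^2/ns, > 0.
#' @return Encounter radius in nm.
#' @examples
#' diffusion_reaction_radius(1.7e10, 5)  # ~0.45 nm
#' @export
diffusion_reaction_radius <- function(k25, D_mutual) {
  if (any(k25 <= 0) || any(D_mutual <= 0)) stop("k25 and D_mutual must be > 0")
  k_molar_to_engine(k25) / (4 * pi * D_mutual)
}
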