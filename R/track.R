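# Parametric 1-ps track-segment generator.
#
# Stands in for an event-by-event physical-stage transport code: energy
# deposition events are a Poisson process along the segment axis with mean
# linear density LET / mean_energy_per_event, each event spawns dissociation
# patterns (counts Poisson on the event's energy share), and every particle
# is displaced from the event centre by an isotropic Gaussian. Electrons get
# a wider Gaussian (thermalization distance) than the heavy species. The
# segment is axially periodic: all distances downstream use the minimum
# image, so per-100-eV yields carry no end artifacts.
#
# Event patterns (charge- and element-balanced, water implicit):
#   single ionization   ->  e_aq + OH + H3O+
#   double ionization   ->  2 e_aq + 2 H3O+ + O(3P)     (MI channel)
#   radical excitation  ->  H + OH
#   molecular channel   ->  H2 + H2O2
#
# The 1-ps pattern yields are fixed, community-standard numbers; only the
# geometry (mean energy per event, Gaussian widths) is tunable and is frozen
# after a one-time calibration against the 60Co-equivalent escape yields and
# the cystamine-free LET series.

LET_ANCHORS <- tibble::tibble(
  energy = c(6, 70, 300, 500),       # MeV per nucleon
  let = c(248, 34.5, 11.7, 9.3)      # keV/um
)

#' LET of a carbon-ion beam at a given energy
#'
#' Tabulated anchors (500 -> 9.3, 300 -> 11.7, 70 -> 34.5, 6 -> 248 keV/um)
#' with log-log interpolation between them; monotone decreasing in energy.
#'
#' @param energy_per_nucleon Beam energy in MeV per nucleon, within 6-500.
#' @return LET in keV/um.
#' @examples
#' let_for_energy(c(6, 70, 300, 500))
#' @export
let_for_energy <- function(energy_per_nucleon) {
  e <- energy_per_nucleon
  if (any(e < 6 | e > 500))
    stop("energy outside the 6-500 MeV/u table; supply an explicit LET instead")
  exp(approx(log(LET_ANCHORS$energy), log(LET_ANCHORS$let), xout = log(e))$y)
}

#' Beam specification
#'
#' @param energy_per_nucleon MeV per nucleon (6-500); mutually exclusive with
#'   `let`.
#' @param let LET in keV/um, given directly.
#' @param segment_um Track-segment length in um; default chosen so the
#'   segment holds roughly `target_particles` reactive species, clamped to
#'   the 1.5-30 um protocol range (override for reduced-scale runs).
#' @param ion Ion label (metadata only).
#' @param target_particles Sizing target for the default segment length.
#' @return A list of class `beam_spec` with `ion`, `let`, `segment_um`.
#' @examples
#' beam_spec(energy_per_nucleon = 500)
#' @export
beam_spec <- function(energy_per_nucleon = NULL, let = NULL, segment_um = NULL,
                      ion = "12C6+", target_particles = 6000) {
  if (is.null(energy_per_nucleon) == is.null(let))
    stop("give exactly one of energy_per_nucleon or let")
  if (is.null(let)) let <- let_for_energy(energy_per_nucleon)
  if (let <= 0) stop("LET must be positive")
  if (is.null(segment_um))
    segment_um <- default_segment_length(let, target_particles)
  structure(list(ion = ion, energy_per_nucleon = energy_per_nucleon,
                 let = let, segment_um = segment_um),
            class = "beam_spec")
}

default_segment_length <- function(let, target_particles = 6000,
                                   params = default_track_params()) {
  y <- params$yields_1ps
  per_100ev <- 3 * y[["ion"]] + 2 * y[["exc_radical"]] + 2 * y[["exc_molecular"]]
  per_um <- per_100ev / 100 * let * 1000   # particles per um of path
  min(30, max(1.5, target_particles / per_um))
}

#' Track-model parameters
#'
#' Geometry and stoichiometry of the 1-ps cluster model. The shipped values
#' of `mean_energy_per_event` and `spur_radius_sigma` are the one-time
#' calibration result (see [calibrate_track_model()] and the methods
#' vignette); the 1-ps pattern yields are fixed.
#'
#' @param mean_energy_per_event Mean energy per deposition event, eV.
#' @param spur_radius_sigma Gaussian radial scale of heavy species around an
#'   event centre, nm.
#' @param electron_sigma_factor Multiplier on `spur_radius_sigma` for
#'   hydrated-electron thermalization displacements.
#' @param yields_1ps Named vector of 1-ps pattern yields per 100 eV:
#'   `ion` (single-ionization triplets), `exc_radical` (H + OH pairs),
#'   `exc_molecular` (H2 + H2O2 pairs).
#' @param penumbra_fraction Fraction of deposition events displaced off-axis
#'   by delta-ray transport (the track penumbra); the remainder sit on the
#'   core axis. Off-axis placement leaves isolated-spur (low-LET) chemistry
#'   unchanged but lets part of the energy escape the dense high-LET column.
#' @param penumbra_radius Gaussian radial scale (nm) of the penumbra
#'   displacement at the reference LET `penumbra_let_ref`. The effective
#'   radius scales as (penumbra_let_ref / LET)^penumbra_let_exp: delta-ray
#'   ranges grow with ion velocity, so faster (lower-LET) ions carry a wider
#'   penumbra.
#' @param penumbra_let_ref Reference LET (keV/um) at which `penumbra_radius`
#'   applies.
#' @param penumbra_let_exp Exponent of the penumbra-width vs LET law.
#' @param mi_probability Fraction of ionization events that are double
#'   ionizations; 0 disables the MI channel.
#' @return A list of class `track_params`.
#' @export
track_params <- function(mean_energy_per_event = 90,
                         spur_radius_sigma = 0.9,
                         electron_sigma_factor = 2.7,
                         yields_1ps = c(ion = 4.9, exc_radical = 0.62,
                                        exc_molecular = 0.12),
                         penumbra_fraction = 0.65,
                         penumbra_radius = 70,
                         penumbra_let_ref = 34.5,
                         penumbra_let_exp = 0.1,
                         mi_probability = 0) {
  stopifnot(mean_energy_per_event > 0, spur_radius_sigma > 0,
            electron_sigma_factor > 0, all(yields_1ps >= 0),
            penumbra_fraction >= 0, penumbra_fraction <= 1,
            penumbra_radius >= 0, penumbra_let_ref > 0,
            penumbra_let_exp >= 0,
            mi_probability >= 0, mi_probability <= 1)
  req <- c("ion", "exc_radical", "exc_molecular")
  if (!all(req %in% names(yields_1ps)))
    stop("yields_1ps needs entries: ", paste(req, collapse = ", "))
  structure(list(mean_energy_per_event = mean_energy_per_event,
                 spur_radius_sigma = spur_radius_sigma,
                 electron_sigma_factor = electron_sigma_factor,
                 yields_1ps = yields_1ps,
                 penumbra_fraction = penumbra_fraction,
                 penumbra_radius = penumbra_radius,
                 penumbra_let_ref = penumbra_let_ref,
                 penumbra_let_exp = penumbra_let_exp,
                 mi_probability = mi_probability),
            class = "track_params")
}

#' @rdname track_params
#' @export
default_track_params <- function() track_params()

#' Generate the 1-ps species inventory of a track segment
#'
#' @param beam A [beam_spec()].
#' @param params A [track_params()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   identical seeds give identical segments.
#' @return A list of class `track_segment`: `particles` (tibble with
#'   `species`, `x`, `y`, `z` in nm; birth time 1 ps), `let`, `length_nm`,
#'   `deposited_eV`, `n_events`, `beam`, `params`, `seed`.
#' @examples
#' trk <- generate_track(beam_spec(let = 9.3, segment_um = 0.5), seed = 1)
#' nrow(trk$particles)
#' @export
generate_track <- function(beam, params = default_track_params(), seed = NULL) {
  if (!inherits(beam, "beam_spec")) stop("beam must be a beam_spec")
  if (!inherits(params, "track_params")) stop("params must be track_params")
  if (beam$let <= 0) stop("zero LET")
  y <- params$yields_1ps
  if (sum(y) <= 0) stop("empty 1-ps yields")
  if (!is.null(seed)) set.seed(seed)

  let_ev_nm <- beam$let                  # keV/um == eV/nm numerically
  L <- beam$segment_um * 1000            # nm
  e_ev <- params$mean_energy_per_event
  n_events <- rpois(1, L * let_ev_nm / e_ev)
  xs <- runif(n_events) * L
  # core/penumbra split: a penumbra event centre is carried off-axis by its
  # delta ray; the event's internal spur geometry is unchanged
  pen <- runif(n_events) < params$penumbra_fraction
  pr_eff <- params$penumbra_radius *
    (params$penumbra_let_ref / beam$let)^params$penumbra_let_exp
  ys <- ifelse(pen, rnorm(n_events, 0, pr_eff), 0)
  zs <- ifelse(pen, rnorm(n_events, 0, pr_eff), 0)

  n_ion <- rpois(n_events, y[["ion"]] * e_ev / 100)
  n_exc1 <- rpois(n_events, y[["exc_radical"]] * e_ev / 100)
  n_exc2 <- rpois(n_events, y[["exc_molecular"]] * e_ev / 100)

  # no-MI inventory first; the MI conversion happens last so that paired
  # runs (same seed, MI on/off) share every preceding random draw.
  # One entry per dissociation slot, then one particle per pattern member.
  ev_ion <- rep(seq_len(n_events), n_ion)
  ev_exc1 <- rep(seq_len(n_events), n_exc1)
  ev_exc2 <- rep(seq_len(n_events), n_exc2)
  species <- c(
    rep(c("e_aq", "OH", "H3Op"), each = length(ev_ion)),
    rep(c("H", "OH"), each = length(ev_exc1)),
    rep(c("H2", "H2O2"), each = length(ev_exc2))
  )
  origin <- c(
    rep("ion", 3 * length(ev_ion)),
    rep("exc", 2 * length(ev_exc1) + 2 * length(ev_exc2))
  )
  event <- c(rep(ev_ion, 3), rep(ev_exc1, 2), rep(ev_exc2, 2))
  n <- length(species)
  esig <- params$spur_radius_sigma * params$electron_sigma_factor
  sig <- ifelse(species == "e_aq", esig, params$spur_radius_sigma)
  particles <- tibble::tibble(
    species = species,
    x = (xs[event] + rnorm(n, 0, sig)) %% L,
    y = ys[event] + rnorm(n, 0, sig),
    z = zs[event] + rnorm(n, 0, sig),
    event = event, origin = origin
  )

  if (params$mi_probability > 0) {
    # A double ionization carries the energy budget of two single
    # ionizations: the pair of slots {2 e_aq, 2 OH, 2 H3O+} becomes
    # {2 e_aq, 2 H3O+, O(3P)} - one slot's OH turns into O(3P) in place,
    # the companion slot's OH is removed (its oxygen is the one doubly
    # ionized). Electrons and hydronium are unchanged, so seed-paired
    # MI-on/off runs share every particle except the converted oxygens.
    slot_oh <- which(particles$species == "OH" & particles$origin == "ion")
    sel <- slot_oh[runif(length(slot_oh)) < params$mi_probability]
    drop <- integer(0)
    if (length(sel) > 0) {
      avail <- setdiff(slot_oh, sel)
      for (i in sel) {
        cand <- avail[particles$event[avail] == particles$event[i]]
        if (length(cand) == 0) next  # lone ionization: stays single
        particles$species[i] <- "O3P"
        particles$origin[i] <- "mi"
        # Coulomb explosion of the doubly ionized water ejects the oxygen
        # fragment from the event core: fresh displacement at twice the
        # spur scale instead of the parent OH position
        ev <- particles$event[i]
        s2 <- 2 * params$spur_radius_sigma
        particles$x[i] <- (xs[ev] + rnorm(1, 0, s2)) %% L
        particles$y[i] <- ys[ev] + rnorm(1, 0, s2)
        particles$z[i] <- zs[ev] + rnorm(1, 0, s2)
        drop <- c(drop, cand[1])
        avail <- setdiff(avail, cand[1])
      }
      if (length(drop) > 0) particles <- particles[-drop, ]
    }
  }
  structure(list(particles = particles, event_x = xs, let = beam$let,
                 length_nm = L, deposited_eV = n_events * e_ev,
                 n_events = n_events, beam = beam, params = params,
                 seed = seed),
            class = "track_segment")
}

#' @export
print.track_segment <- function(x, ...) {
  cat("<track_segment> LET ", x$let, " keV/um, ", round(x$length_nm / 1000, 2),
      " um, ", nrow(x$particles), " particles, ",
      format(x$deposited_eV, big.mark = ","), " eV deposited\n", sep = "")
  invisible(x)
}

#' One-time calibration of the track-model geometry
#'
#' Tunes the two global geometry parameters (`mean_energy_per_event`,
#' `spur_radius_sigma`) so that simulated escape yields in 0.4 M acid at low
#' LET match target 60Co-equivalent g-values, optionally together with
#' cystamine-free 200-s Fricke yields over an LET series. Parameters are
#' global (not per-LET) and are meant to be frozen after calibration; the
#' shipped [default_track_params()] are the frozen result.
#'
#' @param targets Named list: `g_values` (named vector with `H`, `OH`,
#'   `H2O2`; escape yields at the reference LET) and optionally `let_series`
#'   (data frame with columns `let`, `G200`).
#' @param base_params Starting [track_params()].
#' @param let_ref Reference low LET for the g-value targets (keV/um).
#' @param maxit Optimizer iteration budget (> 0, or an error is raised).
#' @param n_segments Replicate segments per objective evaluation.
#' @param target_particles Segment sizing used during calibration.
#' @param seed Seed for the objective's common random numbers.
#' @return A list: `params` (calibrated [track_params()]), `value` (objective
#'   at the optimum), `convergence`, `evaluations`.
#' @export
calibrate_track_model <- function(targets, base_params = default_track_params(),
                                  let_ref = 0.3, maxit = 20, n_segments = 4,
                                  target_particles = 3000, seed = 1) {
  if (maxit <= 0) stop("calibration budget must be a positive iteration count")
  if (is.null(targets$g_values))
    stop("targets$g_values with entries H, OH, H2O2 is required")
  gv <- targets$g_values
  objective <- function(theta) {
    p <- track_params(mean_energy_per_event = exp(theta[1]),
                      spur_radius_sigma = exp(theta[2]),
                      electron_sigma_factor = base_params$electron_sigma_factor,
                      yields_1ps = base_params$yields_1ps)
    esc <- escape_yields(let = let_ref, params = p, n_segments = n_segments,
                         target_particles = target_particles, seed = seed)
    err <- c((esc[["H"]] - gv[["H"]]) / gv[["H"]],
             (esc[["OH"]] - gv[["OH"]]) / gv[["OH"]],
             (esc[["H2O2"]] - gv[["H2O2"]]) / gv[["H2O2"]])
    if (!is.null(targets$let_series)) {
      ls <- targets$let_series
      for (i in seq_len(nrow(ls))) {
        sim <- simulate_fricke_yield(let = ls$let[i], params = p,
                                     replicates = n_segments,
                                     target_particles = target_particles,
                                     seed = seed + i)
        err <- c(err, (sim - ls$G200[i]) / ls$G200[i])
      }
    }
    sum(err^2)
  }
  theta0 <- log(c(base_params$mean_energy_per_event,
                  base_params$spur_radius_sigma))
  fit <- optim(theta0, objective, method = "Nelder-Mead",
               control = list(maxit = maxit))
  out <- track_params(mean_energy_per_event = exp(fit$par[1]),
                      spur_radius_sigma = exp(fit$par[2]),
                      electron_sigma_factor = base_params$electron_sigma_factor,
                      yields_1ps = base_params$yields_1ps)
  list(params = out, value = fit$value, convergence = fit$convergence,
       evaluations = fit$counts[["function"]])
}
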