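# R-side interface to the IRT engine: channel-table construction, the
# exported samplers, and yield bookkeeping from the event log.

#' Sample first-passage reaction times of an isolated Brownian pair
#'
#' Draws from W(t) = (R/r0) erfc((r0 - R)/(2 sqrt(D t))): the probability
#' that a freely diffusing pair born at separation `r0` has reacted (reached
#' contact distance `R`) by time t. With probability 1 - R/r0 the pair never
#' reacts and `Inf` is returned. At `r0 == R` the time is 0.
#'
#' @param n Number of draws.
#' @param r0 Birth separation (nm), must be >= `R`.
#' @param R Encounter radius (nm), > 0.
#' @param D_mutual Mutual diffusion coefficient (nm^2/ns), > 0.
#' @return Times in ns (`Inf` = never).
#' @examples
#' set.seed(1)
#' mean(is.finite(sample_pair_reaction_time(1e4, 2, 1, 1)))  # ~ R/r0 = 0.5
#' @export
sample_pair_reaction_time <- function(n, r0, R, D_mutual) {
  if (R <= 0 || D_mutual <= 0) stop("R and D_mutual must be > 0")
  if (r0 < R) stop("r0 < R: overlapping births are resolved by the engine, not the sampler")
  sample_pair_times_cpp(as.integer(n), r0, R, D_mutual)
}

#' Sample pseudo-first-order scavenging times
#'
#' Exponential with rate equal to the scavenging power k\[S\]; zero power
#' means the species is never scavenged (`Inf`).
#'
#' @param n Number of draws.
#' @param scavenging_power Rate k\[S\] in 1/s, >= 0.
#' @return Times in seconds.
#' @export
sample_scavenging_time <- function(n, scavenging_power) {
  if (scavenging_power < 0) stop("scavenging power must be >= 0")
  if (scavenging_power == 0) return(rep(Inf, n))
  rexp(n, rate = scavenging_power)
}

particle_capable <- function(species) !species$is_bulk | species$name == "H3Op"

corrected_k <- function(network, bulk) {
  sp <- network$species
  rx <- network$reactions
  I <- bulk$ionic_strength
  vapply(seq_len(nrow(rx)), function(i) {
    re <- rx$reactants[[i]]
    if (rx$no_ionic[i] || length(re) < 2) return(rx$k25[i])
    z <- sp$charge[match(re, sp$name)]
    correct_for_ionic_strength(rx$k25[i], z[1], z[2], I)
  }, numeric(1))
}

# Assemble the integer-coded channel tables consumed by the C++ engine.
build_engine_tables <- function(network, bulk) {
  sp <- network$species
  rx <- network$reactions
  code <- setNames(seq_len(nrow(sp)) - 1L, sp$name)
  pok <- particle_capable(sp)
  names(pok) <- sp$name
  conc <- bulk$concentrations
  kc <- corrected_k(network, bulk)

  pair <- list(a = integer(0), b = integer(0), rxn = integer(0),
               R = numeric(0), D = numeric(0))
  scav <- list(sp = integer(0), rxn = integer(0), rate = numeric(0))
  for (i in seq_len(nrow(rx))) {
    re <- rx$reactants[[i]]
    if (length(re) == 1) {  # unimolecular transform: k25 in 1/s
      scav$sp <- c(scav$sp, code[[re]])
      scav$rxn <- c(scav$rxn, i - 1L)
      scav$rate <- c(scav$rate, rx$k25[i] / 1e9)
      next
    }
    d1 <- sp$diffusion_coefficient[match(re[1], sp$name)]
    d2 <- sp$diffusion_coefficient[match(re[2], sp$name)]
    if (pok[[re[1]]] && pok[[re[2]]]) {
      dm <- d1 + d2
      pair$a <- c(pair$a, code[[re[1]]])
      pair$b <- c(pair$b, code[[re[2]]])
      pair$rxn <- c(pair$rxn, i - 1L)
      # effective encounter radius, capped at the physical contact scale:
      # ionic-strength acceleration cannot push the reaction distance beyond
      # an encounter diameter
      pair$R <- c(pair$R, min(k_molar_to_engine(kc[i]) / (4 * pi * dm), 2))
      pair$D <- c(pair$D, dm)
    }
    for (k in 1:2) {
      b <- re[k]; other <- re[3 - k]
      if (sp$is_bulk[match(b, sp$name)] && !is.na(conc[b]) && conc[b] > 0 &&
          pok[[other]]) {
        scav$sp <- c(scav$sp, code[[other]])
        scav$rxn <- c(scav$rxn, i - 1L)
        scav$rate <- c(scav$rate, kc[i] * conc[[b]] / 1e9)  # 1/ns
      }
    }
  }
  reactant_somewhere <- sp$name %in% unlist(rx$reactants)
  active <- (pok & reactant_somewhere)
  prods <- purrr::map(rx$products, ~ unname(code[.x]))
  list(code = code, pair = pair, scav = scav, products = prods,
       active = active, k_corr = kc)
}

#' Run the intratrack IRT stage
#'
#' Executes the nonhomogeneous chemical stage from 1 ps to the handoff time:
#' pairwise first-passage reactions among track species, pseudo-first-order
#' scavenging by the bulk solutes (ionic-strength-corrected rate constants
#' for ion-ion channels), products re-entering the competition as they are
#' formed.
#'
#' @param track A [generate_track()] segment.
#' @param network A [reaction_network()]; defaults to [default_scheme()] with
#'   the track's solution unspecified, so pass the network matching your
#'   solution composition.
#' @param bulk A [bulk_solution()]; derived from `network` when `NULL`.
#' @param t_handoff Handoff time in seconds (default 1e-6: track expansion is
#'   essentially complete by ~0.2 us at low LET; 1 us adds margin for
#'   high-LET columns).
#' @param cutoff_nm Pair-sampling neighbour cutoff (nm); capped at half the
#'   segment period, recorded in the result.
#' @return An object of class `event_log`: `events` (tibble `t_s`,
#'   `reaction`, `kind` "pair"/"scavenging"), `survivors` (tibble `species`,
#'   `x`, `y`, `z`, `birth_ns`), `init_counts`, `deposited_eV`,
#'   `t_handoff_s`, `meta`.
#' @export
run_track_stage <- function(track, network = default_scheme(), bulk = NULL,
                            t_handoff = 1e-6, cutoff_nm = 120) {
  if (t_handoff < 1e-12) stop("t_handoff must be >= 1 ps")
  sp <- network$species
  unknown <- setdiff(unique(track$particles$species), sp$name)
  if (length(unknown) > 0)
    stop("track species not in network: ", paste(unknown, collapse = ", "))
  if (is.null(bulk)) bulk <- bulk_from_network(network)
  tb <- build_engine_tables(network, bulk)

  p <- track$particles
  res <- run_irt_cpp(
    p_sp = unname(tb$code[p$species]), p_x = p$x, p_y = p$y, p_z = p$z,
    t_start = 1e-3, t_handoff = t_handoff * 1e9,
    L = track$length_nm, cutoff = cutoff_nm, n_species = nrow(sp),
    pc_a = tb$pair$a, pc_b = tb$pair$b, pc_rxn = tb$pair$rxn,
    pc_R = tb$pair$R, pc_D = tb$pair$D,
    sc_sp = tb$scav$sp, sc_rxn = tb$scav$rxn, sc_rate = tb$scav$rate,
    rxn_products = tb$products, active_sp = tb$active
  )
  init <- table(factor(p$species, levels = sp$name))
  events <- tibble::tibble(
    t_s = res$ev_t / 1e9,
    reaction = network$reactions$id[res$ev_rxn + 1L],
    kind = c("pair", "scavenging")[res$ev_kind + 1L]
  )
  survivors <- tibble::tibble(
    species = sp$name[res$surv_sp + 1L],
    x = res$surv_x, y = res$surv_y, z = res$surv_z,
    birth_ns = res$surv_birth
  )
  structure(list(
    events = events, survivors = survivors,
    init_counts = setNames(as.integer(init), sp$name),
    deposited_eV = track$deposited_eV, t_handoff_s = t_handoff,
    network = network, bulk = bulk,
    meta = list(cutoff_nm = res$cutoff_used, n_cells = res$n_cells,
                ionic_strength = bulk$ionic_strength,
                let = track$let, length_nm = track$length_nm,
                seed = track$seed)
  ), class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat("<event_log> ", nrow(x$events), " events to ",
      format(x$t_handoff_s), " s; ", nrow(x$survivors), " survivors of ",
      sum(x$init_counts), " initial particles\n", sep = "")
  invisible(x)
}

bulk_from_network <- function(network) {
  conc <- setNames(network$species$conc, network$species$name)
  bulk_solution(cystamine_conc = conc[["RSSR"]], fe2_conc = conc[["Fe2p"]],
                o2_conc = conc[["O2"]], hplus_conc = conc[["H3Op"]])
}

# Per-event species deltas for a reaction, by event kind. Scavenging events
# consume only the trace (non-bulk) reactant; the bulk partner comes from the
# reservoir and is not part of the trace inventory.
reaction_deltas <- function(network) {
  sp <- network$species
  rx <- network$reactions
  n <- nrow(sp)
  dpair <- matrix(0L, nrow(rx), n, dimnames = list(rx$id, sp$name))
  dscav <- dpair
  for (i in seq_len(nrow(rx))) {
    for (pr in rx$products[[i]]) {
      dpair[i, pr] <- dpair[i, pr] + 1L
      dscav[i, pr] <- dscav[i, pr] + 1L
    }
    for (re in rx$reactants[[i]]) {
      dpair[i, re] <- dpair[i, re] - 1L
      if (!sp$is_bulk[match(re, sp$name)])
        dscav[i, re] <- dscav[i, re] - 1L
    }
  }
  list(pair = dpair, scavenging = dscav)
}

#' Time-dependent yields from an event log
#'
#' G_X(t) = 100 * (net number of X present/created by t) / deposited energy
#' (eV), and per-reaction extents dG(t) from the executed-event counts. The
#' sum of the extents over ferric-producing channels equals G(Fe3+)(t)
#' exactly.
#'
#' @param log An [run_track_stage()] event log.
#' @param t_grid Times (s) at which to evaluate; must not exceed the log's
#'   handoff time.
#' @param deposited_eV Energy normalization; defaults to the log's.
#' @return A list with `yields` (tibble `t_s`, `species`, `G`) and
#'   `channels` (tibble `t_s`, `reaction`, `dG`, ferric-producing reactions
#'   only).
#' @export
time_dependent_yields <- function(log, t_grid, deposited_eV = log$deposited_eV) {
  if (any(t_grid > log$t_handoff_s * (1 + 1e-9)))
    stop("t_grid extends beyond the event log coverage (t_handoff)")
  net <- log$network
  deltas <- reaction_deltas(net)
  ev <- log$events
  n_ev <- nrow(ev)
  sp_names <- net$species$name
  # cumulative species counts at event resolution
  dmat <- matrix(0, max(n_ev, 1), length(sp_names))
  if (n_ev > 0) {
    ir <- match(ev$reaction, net$reactions$id)
    for (k in which(!net$species$is_bulk)) {
      dk <- ifelse(ev$kind == "pair", deltas$pair[cbind(ir, k)],
                   deltas$scavenging[cbind(ir, k)])
      dmat[, k] <- cumsum(dk)
    }
  }
  idx <- if (n_ev > 0) findInterval(t_grid, ev$t_s) else rep(0L, length(t_grid))
  init <- log$init_counts
  gfun <- function(k) {
    base <- init[[k]]
    cnt <- ifelse(idx == 0, base, base + dmat[pmax(idx, 1L), k])
    100 * cnt / deposited_eV
  }
  yields <- purrr::map_dfr(seq_along(sp_names), function(k) {
    tibble::tibble(t_s = t_grid, species = sp_names[k], G = gfun(k))
  })
  yields <- yields[!net$species$is_bulk[match(yields$species, sp_names)], ]

  fe_rxns <- net$reactions$id[purrr::map_lgl(net$reactions$products,
                                             ~ "Fe3p" %in% .x)]
  channels <- purrr::map_dfr(fe_rxns, function(id) {
    if (n_ev > 0) {
      cum <- cumsum(ev$reaction == id)
      cnt <- ifelse(idx == 0, 0, cum[pmax(idx, 1L)])
    } else cnt <- rep(0, length(t_grid))
    tibble::tibble(t_s = t_grid, reaction = id, dG = 100 * cnt / deposited_eV)
  })
  list(yields = yields, channels = channels)
}

# Survivor inventory of an event log as G values (molecules per 100 eV) per
# non-bulk species. The event bookkeeping (initial counts plus per-event
# deltas) equals the live-particle inventory for mobile species and
# accumulates the terminal products (Fe3+, OH-, ...) as well.
handoff_yields <- function(log) {
  yt <- time_dependent_yields(log, log$t_handoff_s)
  setNames(yt$yields$G, yt$yields$species)
}
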