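no_bulk <- function() bulk_solution(0, 0, 0, 0)

test_that("an empty track yields an empty log and no survivors", {
  trk <- toy_track(character(0), numeric(0), numeric(0), numeric(0))
  log <- run_track_stage(trk, toy_self_network(), no_bulk(), t_handoff = 1e-8)
  expect_identical(nrow(log$events), 0L)
  expect_identical(nrow(log$survivors), 0L)
})

test_that("identical seeds give identical event logs", {
  net <- default_scheme(cystamine_conc = 1e-3)
  b <- beam_spec(let = 34.5, segment_um = 0.3)
  run <- function() {
    trk <- generate_track(b, seed = 99)
    run_track_stage(trk, net)
  }
  l1 <- run(); l2 <- run()
  expect_identical(l1$events, l2$events)
  expect_identical(l1$survivors, l2$survivors)
})

test_that("unknown track species are rejected", {
  trk <- toy_track("Q", 0, 0, 0)
  expect_error(run_track_stage(trk, toy_self_network(), no_bulk()), "Q")
})

test_that("isolated-pair ultimate reaction probability equals R/r0", {
  R <- 0.8; r0 <- 1.6; D <- 1
  net <- toy_self_network(R_nm = R, D = D)
  set.seed(404)
  n <- 600
  reacted <- purrr::map_int(seq_len(n), function(i) {
    trk <- toy_track(c("A", "A"), c(500, 500 + r0), c(0, 0), c(0, 0))
    nrow(run_track_stage(trk, net, no_bulk(), t_handoff = 1e-5)$events)
  })
  p_inf <- R / r0
  # W at the horizon is ~0.996 of the ultimate probability
  expect_lt(abs(mean(reacted) - p_inf), 3 * sqrt(p_inf * (1 - p_inf) / n) + 0.01)
})

test_that("engine matches the Brownian-dynamics oracle on toy configurations", {
  R <- 0.8; D <- 1
  net <- toy_self_network(R_nm = R, D = D)
  run_irt <- function(pos, n, t_handoff) {
    purrr::map_int(seq_len(n), function(i) {
      trk <- toy_track(rep("A", nrow(pos)), 500 + pos[, 1], pos[, 2], pos[, 3])
      nrow(run_track_stage(trk, net, no_bulk(), t_handoff = t_handoff)$events)
    })
  }
  compare <- function(pos, n_irt, n_bd, t_max, seed) {
    set.seed(seed)
    irt <- run_irt(pos, n_irt, t_max * 1e-9)
    bd <- bd_multi_reaction_counts(n_bd, pos, D, R, dt = 5e-3, t_max = t_max,
                                   seed = seed + 1)
    sigma <- sqrt(stats::var(irt) / n_irt + stats::var(bd) / n_bd)
    expect_lt(abs(mean(irt) - mean(bd)), 3 * sigma + 0.03,
              label = paste(nrow(pos), "particles: IRT vs BD mean reactions"))
  }
  # three particles in a triangle
  pos3 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0))
  compare(pos3, n_irt = 800, n_bd = 500, t_max = 10, seed = 505)
  # ten particles in a spur-like Gaussian cluster
  set.seed(42)
  pos10 <- matrix(rnorm(30, 0, 1.8), ncol = 3)
  compare(pos10, n_irt = 500, n_bd = 400, t_max = 10, seed = 606)
})

test_that("the event log conserves elements and charge", {
  net <- default_scheme(cystamine_conc = 1e-3)
  trk <- generate_track(beam_spec(let = 60, segment_um = 0.25),
                        track_params(mi_probability = 0.05), seed = 21)
  log <- run_track_stage(trk, net)
  expect_gt(nrow(log$events), 100)
  sp <- net$species
  comp <- as.matrix(sp[, c("nH", "nO", "nS", "nN", "nC", "nFe")])
  rownames(comp) <- sp$name
  charge <- setNames(sp$charge, sp$name)
  deltas <- frickeirt:::reaction_deltas(net)
  ir <- match(log$events$reaction, net$reactions$id)
  # trace-side species change + bulk partners consumed by scavenging events
  d_trace <- numeric(nrow(sp)); names(d_trace) <- sp$name
  bulk_in <- numeric(nrow(sp)); names(bulk_in) <- sp$name
  for (k in seq_along(ir)) {
    dm <- if (log$events$kind[k] == "pair") deltas$pair else deltas$scavenging
    d_trace <- d_trace + dm[ir[k], ]
    if (log$events$kind[k] == "scavenging") {
      re <- net$reactions$reactants[[ir[k]]]
      bre <- re[sp$is_bulk[match(re, sp$name)]]
      if (length(bre) == 1) bulk_in[bre] <- bulk_in[bre] + 1
    }
  }
  residue <- as.numeric((d_trace - bulk_in) %*% comp)
  names(residue) <- colnames(comp)
  residue_charge <- sum((d_trace - bulk_in) * charge)
  # residues must be implicit water/protons only
  expect_identical(unname(residue[c("nS", "nN", "nC", "nFe")]), rep(0, 4))
  expect_equal(residue[["nH"]] - 2 * residue[["nO"]] - residue_charge, 0)
  # and the bookkeeping matches the survivor inventory for mobile species
  yt <- time_dependent_yields(log, log$t_handoff_s)
  g_oh <- yt$yields$G[yt$yields$species == "OH"]
  expect_equal(g_oh * log$deposited_eV / 100,
               sum(log$survivors$species == "OH"))
})

test_that("surviving H atoms convert to HO2 on the oxygen scavenging scale", {
  net <- default_scheme(cystamine_conc = 0, fe2_conc = 0, o2_conc = 2.5e-4)
  trk <- generate_track(beam_spec(let = 9.3, segment_um = 1.5), seed = 31)
  log <- run_track_stage(trk, net)
  th <- log$events$t_s[log$events$reaction == "W11"]
  expect_gt(length(th), 50)
  # truncated-exponential median at rate k[O2] = 5.25e6/s, horizon 1 us
  lam <- 2.1e10 * 2.5e-4
  med_th <- -log(1 - 0.5 * (1 - exp(-lam * 1e-6))) / lam
  expect_gt(median(th), 0.5 * med_th)
  expect_lt(median(th), 1.7 * med_th)
})

test_that("yields are consistent, monotone in Fe3+, and coverage-checked", {
  kin <- cached_kinetics("lowlet", let = 9.3, replicates = 3, seed = 2,
                         segment_um = 1)
  g <- kin$kinetics$G
  expect_true(all(diff(g) >= -1e-12))
  # channel extents sum to the total at every grid point
  sums <- dplyr::summarise(dplyr::group_by(kin$channels, .data$t_s),
                           s = sum(.data$dG))
  joined <- dplyr::inner_join(kin$kinetics, sums, by = "t_s")
  expect_equal(joined$G, joined$s, tolerance = 1e-9)
  # a single ferric-producing event in a 100 eV deposit means G = 1
  net <- default_scheme()
  fake <- structure(list(
    events = tibble::tibble(t_s = 1e-9, reaction = "6", kind = "scavenging"),
    survivors = tibble::tibble(species = character(0), x = numeric(0),
                               y = numeric(0), z = numeric(0),
                               birth_ns = numeric(0)),
    init_counts = setNames(rep(0L, nrow(net$species)), net$species$name),
    deposited_eV = 100, t_handoff_s = 1e-6, network = net,
    bulk = bulk_solution(), meta = list()), class = "event_log")
  y <- time_dependent_yields(fake, c(1e-10, 1e-6))
  gfe <- y$yields$G[y$yields$species == "Fe3p"]
  expect_equal(gfe, c(0, 1))
  expect_error(time_dependent_yields(fake, 1e-3), "coverage")
})
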