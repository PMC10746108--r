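test_that("pseudo-first-order time scales match the competition arithmetic", {
  net <- default_scheme(cystamine_conc = 1e-3)
  gen <- frickeirt:::build_bulk_generator(net, bulk_solution(1e-3))
  rate_of <- function(id) {
    ch <- purrr::keep(gen$channels, ~ net$reactions$id[.x$rxn] == id)
    sum(purrr::map_dbl(ch, "rate"))
  }
  # Fenton step at 1 mM ferrous: tau ~19 s, > 99% complete by 200 s
  expect_equal(1 / rate_of("8"), 19.2, tolerance = 0.01)
  expect_gt(1 - exp(-200 * rate_of("8")), 0.99)
  # HO2 + Fe2+: tau ~1.3 ms, completes on the ~10 ms scale
  expect_equal(1 / rate_of("7"), 1.27e-3, tolerance = 0.01)
  # thiyl + Fe2+ (uncorrected arithmetic): ~4 us
  expect_equal(scavenging_time(2.5e8, 1e-3), 4e-6, tolerance = 1e-12)
})

test_that("cystamine-free cascade reproduces the stoichiometric identity", {
  chk <- stoichiometric_consistency_check(
    c(H = 3.70, HO2 = 0.02, OH = 2.90, H2O2 = 0.80))
  expect_equal(chk$G_stoichiometric, 15.66, tolerance = 1e-12)
  expect_lt(abs(chk$relative_error), 1e-9)
  # all-zero survivors give zero; a lone H2O2 gives exactly 2
  expect_identical(stoichiometric_consistency_check(c(H2O2 = 0))$G_final, 0)
  chk2 <- stoichiometric_consistency_check(c(H2O2 = 1))
  expect_equal(chk2$G_final, 2, tolerance = 1e-12)
  # coefficient checks through the cascade: a lone H gives 3, a lone OH 1
  expect_equal(stoichiometric_consistency_check(c(H = 1))$G_final, 3,
               tolerance = 1e-12)
  expect_equal(stoichiometric_consistency_check(c(OH = 1))$G_final, 1,
               tolerance = 1e-12)
})

test_that("matrix-exponential propagation agrees with a stiff ODE solve", {
  skip_if_not_installed("deSolve")
  net <- default_scheme(cystamine_conc = 1e-3)
  bulk <- bulk_solution(1e-3)
  gen <- frickeirt:::build_bulk_generator(net, bulk)
  surv <- c(H = 1.2, OH = 0.8, H2O2 = 0.9, HO2 = 0.4, RS = 0.3, RSSRp = 0.5)
  out <- propagate_bulk_stage(surv, net, bulk,
                              t_grid = c(1e-6, 1e-3, 1, 200), t_handoff = 1e-6)
  y0 <- numeric(nrow(gen$A))
  for (nm in names(surv)) y0[match(nm, gen$states)] <- surv[[nm]]
  ode <- deSolve::lsoda(
    y = y0, times = c(1e-6, 1e-3, 1, 200),
    func = function(t, y, p) list(as.numeric(gen$A %*% y)),
    rtol = 1e-10, atol = 1e-12)
  n <- length(gen$states)
  fe_ode <- rowSums(ode[, 1 + n + seq_along(gen$fe_ids), drop = FALSE])
  expect_equal(out$fe3$G, fe_ode, tolerance = 1e-4)
})

test_that("OH branching at 1 mM cystamine starves the ferrous channel", {
  b <- branching_fractions(c(3.4e8, 1.7e10), c(1e-3, 1e-3))
  expect_lte(b[1], 0.02)
})

test_that("a trapped cycle without decay is detected", {
  sp <- tibble::tibble(
    name = c("A", "B", "Fe2p"), charge = c(0L, 0L, 2L),
    diffusion_coefficient = 1, is_bulk = c(FALSE, FALSE, TRUE),
    conc = c(0, 0, 1e-3),
    nH = 0L, nO = 0L, nS = 0L, nN = 0L, nC = 0L, nFe = c(0L, 0L, 1L))
  rx <- dplyr::bind_rows(
    frickeirt:::new_reaction_row("C1", c("A", "Fe2p"), c("B", "Fe2p"), 1e6),
    frickeirt:::new_reaction_row("C2", c("B", "Fe2p"), c("A", "Fe2p"), 1e6))
  net <- reaction_network(sp, rx)
  expect_error(
    propagate_bulk_stage(c(A = 1), net, bulk_solution(0),
                         t_grid = c(1e-6, 1), t_handoff = 1e-6),
    "cyclic")
})

test_that("channel completion times are ordered RS < HO2 < H2O2/RSSR+", {
  kin <- cached_kinetics("cysta", let = 9.3, cystamine_conc = 1e-3,
                         replicates = 3, seed = 5, segment_um = 1)
  t95 <- function(id) {
    ch <- dplyr::filter(kin$channels, .data$reaction == id)
    fin <- ch$dG[nrow(ch)]
    if (fin <= 0) return(NA_real_)
    min(ch$t_s[ch$dG >= 0.95 * fin])
  }
  # thiyl channel completes in microseconds, HO2 by ~10 ms, the Fenton and
  # radical-cation channels on the tens-of-seconds scale
  expect_lt(t95("16"), 1e-4)
  expect_lt(t95("7"), 0.05)
  expect_gt(t95("7"), 1e-4)
  expect_gt(t95("8"), 5)
  expect_gt(t95("20"), 5)
  expect_lt(t95("8"), 200)
})
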