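test_that("LET-energy mapping hits the tabulated anchors and is monotone", {
  expect_equal(let_for_energy(500), 9.3)
  expect_equal(let_for_energy(300), 11.7)
  expect_equal(let_for_energy(70), 34.5)
  expect_equal(let_for_energy(6), 248)
  e <- seq(6, 500, length.out = 60)
  expect_true(all(diff(let_for_energy(e)) < 0))
  expect_error(let_for_energy(5), "6-500")
  expect_error(let_for_energy(600), "6-500")
  expect_error(beam_spec(energy_per_nucleon = 70, let = 34.5), "exactly one")
  expect_error(beam_spec(), "exactly one")
})

test_that("deposited energy tracks LET times segment length", {
  # 248 keV/um x 1.5 um = 3.72e5 eV, within event-sampling fluctuation
  trk <- generate_track(beam_spec(energy_per_nucleon = 6, segment_um = 1.5),
                        seed = 3)
  expected <- 248 * 1.5 * 1000
  lambda <- expected / trk$params$mean_energy_per_event
  expect_lt(abs(trk$deposited_eV - expected),
            5 * sqrt(lambda) * trk$params$mean_energy_per_event)
})

test_that("particle counts sit in the protocol window and scale with LET x length", {
  p <- default_track_params()
  counts <- purrr::map_dbl(c(9.3, 34.5, 248), function(l) {
    nrow(generate_track(beam_spec(let = l), p, seed = 5)$particles)
  })
  expect_true(all(counts >= 5000 & counts <= 100000))
  n1 <- nrow(generate_track(beam_spec(let = 10, segment_um = 2), p, seed = 7)$particles)
  n2 <- nrow(generate_track(beam_spec(let = 100, segment_um = 2), p, seed = 8)$particles)
  n3 <- nrow(generate_track(beam_spec(let = 10, segment_um = 4), p, seed = 9)$particles)
  expect_equal(n2 / n1, 10, tolerance = 0.15)
  expect_equal(n3 / n1, 2, tolerance = 0.15)
})

test_that("same seed reproduces the segment exactly", {
  b <- beam_spec(let = 34.5, segment_um = 0.5)
  t1 <- generate_track(b, seed = 42)
  t2 <- generate_track(b, seed = 42)
  expect_identical(t1$particles, t2$particles)
  expect_identical(t1$deposited_eV, t2$deposited_eV)
  p_mi <- track_params(mi_probability = 0.1)
  m1 <- generate_track(b, p_mi, seed = 42)
  m2 <- generate_track(b, p_mi, seed = 42)
  expect_identical(m1$particles, m2$particles)
})

test_that("every generated event is charge- and element-balanced", {
  for (mi in c(0, 0.15)) {
    trk <- generate_track(beam_spec(let = 100, segment_um = 0.2),
                          track_params(mi_probability = mi), seed = 11)
    sp <- default_species()
    d <- dplyr::left_join(trk$particles, sp, by = c(species = "name"))
    per_event <- dplyr::summarise(
      dplyr::group_by(d, .data$event),
      charge = sum(.data$charge), H = sum(.data$nH), O = sum(.data$nO),
      .groups = "drop")
    # residues must be pure implicit water/protons: nH - 2 nO - charge = 0
    expect_true(all(per_event$H - 2 * per_event$O - per_event$charge == 0))
    expect_true(all(per_event$charge == 0))
  }
})

test_that("the MI channel converts ionization slots and only those", {
  b <- beam_spec(let = 248, segment_um = 0.05)
  off <- generate_track(b, track_params(mi_probability = 0), seed = 13)
  expect_identical(sum(off$particles$species == "O3P"), 0L)
  on <- generate_track(b, track_params(mi_probability = 0.3), seed = 13)
  n_mi <- sum(on$particles$species == "O3P")
  expect_gt(n_mi, 0)
  # each double ionization: two OH slots consumed, one O(3P) emitted,
  # electrons and hydronium untouched
  expect_identical(sum(on$particles$species == "OH") + 2L * n_mi,
                   sum(off$particles$species == "OH"))
  expect_identical(sum(on$particles$species == "e_aq"),
                   sum(off$particles$species == "e_aq"))
  expect_identical(nrow(off$particles), nrow(on$particles) + n_mi)
  # seed pairing: every MI-arm particle except the ejected O(3P) fragment
  # (fresh Coulomb-explosion displacement) shares its position with the
  # off arm
  shared <- dplyr::filter(on$particles, .data$species != "O3P")
  expect_true(all(shared$x %in% off$particles$x))
})

test_that("track structure tightens from spur strings to a column with LET", {
  p <- default_track_params()
  ratio <- purrr::map_dbl(c(2, 30, 248), function(l) {
    trk <- generate_track(beam_spec(let = l, segment_um = 1), p, seed = 17)
    radial <- sqrt(trk$particles$y^2 + trk$particles$z^2)
    spacing <- p$mean_energy_per_event / l   # nm between deposition events
    stats::median(radial) / spacing
  })
  expect_true(all(diff(ratio) > 0))
})

test_that("calibration validates its budget and returns frozen-format params", {
  expect_error(calibrate_track_model(list(g_values = c(H = 3.7, OH = 2.9,
                                                       H2O2 = 0.8)),
                                     maxit = 0), "budget")
  expect_error(calibrate_track_model(list(), maxit = 5), "g_values")
})
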