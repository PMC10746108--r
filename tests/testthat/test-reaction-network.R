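test_that("default scheme carries the established rate constants", {
  net <- default_scheme()
  k <- setNames(net$reactions$k25, net$reactions$id)
  expect_identical(unname(k[as.character(6:21)]),
                   c(3.4e8, 7.9e5, 52, 1.3e7, 4.1e10, 8e9, 1.7e10, 4.2e9,
                     2e9, 1e7, 2.5e8, 1e6, 2e9, 7.9e5, 2e6, 2.5e9))
  # cystamine outcompetes ferrous for OH by a factor of exactly 50
  expect_identical(k[["12"]] / k[["6"]], 50)
})

test_that("ferric ion is a terminal product of the scheme", {
  net <- default_scheme()
  as_reactant <- sum(purrr::map_lgl(net$reactions$reactants, ~ "Fe3p" %in% .x))
  as_product <- sum(purrr::map_lgl(net$reactions$products, ~ "Fe3p" %in% .x))
  expect_identical(as_reactant, 0L)
  expect_gte(as_product, 6L)
})

test_that("every default reaction balances with implicit water/protons", {
  net <- default_scheme()
  for (i in seq_len(nrow(net$reactions))) {
    b <- frickeirt:::balance_one(net, i)
    expect_true(b$ok, label = paste("reaction", net$reactions$id[i], "balances"))
  }
})

test_that("network validation rejects bad input naming the culprit", {
  net <- default_scheme()
  bad <- net
  bad$reactions <- dplyr::bind_rows(
    net$reactions,
    frickeirt:::new_reaction_row("X1", c("OH", "X"), "H2O2", 1e9))
  expect_error(validate_network(bad), "X1|unknown species")
  bad2 <- net
  bad2$reactions <- dplyr::bind_rows(
    net$reactions,
    frickeirt:::new_reaction_row("X2", c("OH", "OH"), c("H2O2", "H2"), 1e9))
  expect_error(validate_network(bad2), "X2")
  bad3 <- net
  bad3$reactions$k25[3] <- -1
  expect_error(validate_network(bad3), "k25")
})

test_that("ionic-strength correction follows the extended Debye-Huckel form", {
  # neutral reactant and infinite dilution are identities
  expect_identical(correct_for_ionic_strength(5e9, 0, 2, 0.5), 5e9)
  expect_identical(correct_for_ionic_strength(5e9, -1, 3, 0), 5e9)
  # direct evaluation of the stated formula for zA=+1, zB=+2, I=0.1
  f <- 10^(1.02 * 2 * sqrt(0.1) / (1 + sqrt(0.1)))
  expect_equal(correct_for_ionic_strength(1, 1, 2, 0.1), f, tolerance = 1e-12)
  expect_equal(f, 3.091, tolerance = 1e-3)
  # symmetric in the charges, monotone in I for fixed sign
  expect_equal(correct_for_ionic_strength(1, 1, 2, 0.3),
               correct_for_ionic_strength(1, 2, 1, 0.3))
  is_ <- c(0.01, 0.1, 0.5, 1)
  up <- correct_for_ionic_strength(1, 1, 1, is_)
  dn <- correct_for_ionic_strength(1, -1, 1, is_)
  expect_true(all(diff(up) > 0) && all(diff(dn) < 0))
  expect_error(correct_for_ionic_strength(1, 1, 1, -0.1), ">= 0")
  # the electron self-recombination is exempt in the default scheme
  net <- default_scheme()
  expect_true(net$reactions$no_ionic[net$reactions$id == "W1"])
  kc <- frickeirt:::corrected_k(net, bulk_solution())
  expect_identical(kc[net$reactions$id == "W1"],
                   net$reactions$k25[net$reactions$id == "W1"])
})

test_that("scavenging times reproduce the microsecond competition scales", {
  expect_equal(scavenging_time(4.1e10, 1e-4), 0.25e-6, tolerance = 0.03)
  expect_equal(scavenging_time(8e9, 1e-4), 1.25e-6, tolerance = 1e-12)
  expect_equal(scavenging_time(1.7e10, 1e-4), 0.6e-6, tolerance = 0.02)
  expect_error(scavenging_time(0, 1e-4), "> 0")
  expect_error(scavenging_time(1e9, -1), "> 0")
})

test_that("branching fractions are normalized competition weights", {
  b <- branching_fractions(c(3.4e8, 1.7e10), c(1e-3, 1e-3))
  expect_equal(b[1], 1 / 51, tolerance = 1e-12)
  expect_equal(sum(b), 1, tolerance = 1e-12)
  expect_identical(branching_fractions(5e9, 0.1), 1)
  expect_equal(branching_fractions(c(2e9, 2e9), c(1, 1)), c(0.5, 0.5))
  # property: sums to one across random channel sets
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    expect_equal(sum(branching_fractions(runif(n, 0, 1e10), runif(n))), 1,
                 tolerance = 1e-12)
  }
  expect_error(branching_fractions(c(0, 0), c(1, 1)), "positive")
})

test_that("encounter radii invert the Smoluchowski relation", {
  expect_equal(diffusion_reaction_radius(1.7e10, 5), 0.449, tolerance = 0.01)
  # identity: a rate constant built from R = 1 nm maps back to 1 nm
  k1 <- 1 * 4 * pi * 3 / k_molar_to_engine(1)
  expect_equal(diffusion_reaction_radius(k1, 3), 1, tolerance = 1e-12)
  # doubling D halves R
  expect_equal(diffusion_reaction_radius(1e10, 4),
               diffusion_reaction_radius(1e10, 2) / 2)
  expect_error(diffusion_reaction_radius(-1, 1), "> 0")
})

test_that("bulk solution computes the fixed-speciation ionic strength", {
  expect_equal(bulk_solution(0)$ionic_strength, 0.404, tolerance = 1e-12)
  expect_equal(bulk_solution(1)$ionic_strength, 3.404, tolerance = 1e-12)
  expect_equal(bulk_solution(0, ionic_strength = 0.9)$ionic_strength, 0.9)
  expect_error(bulk_solution(-1), ">= 0")
})
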