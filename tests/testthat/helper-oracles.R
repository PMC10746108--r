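# Brute-force Brownian-dynamics oracles (test-scale only) and toy fixtures.

# Rate constant (M^-1 s^-1) whose Smoluchowski radius is exactly R_nm for a
# pair with mutual diffusion coefficient D nm^2/ns.
k_for_radius <- function(R_nm, D) R_nm * 4 * pi * D / k_molar_to_engine(1)

# First-passage times of an isolated pair by explicit random flight of the
# relative coordinate (diffusion coefficient = mutual D), with a Brownian
# bridge correction for within-step contact crossings.
bd_pair_times <- function(n, r0, R, D, dt = 5e-4, t_max = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- cbind(rep(r0, n), 0, 0)
  times <- rep(Inf, n)
  alive <- rep(TRUE, n)
  sd_step <- sqrt(2 * D * dt)
  nstep <- ceiling(t_max / dt)
  for (s in seq_len(nstep)) {
    idx <- which(alive)
    if (length(idx) == 0) break
    r_old <- sqrt(rowSums(pos[idx, , drop = FALSE]^2))
    pos[idx, ] <- pos[idx, , drop = FALSE] +
      matrix(rnorm(3 * length(idx), 0, sd_step), ncol = 3)
    r_new <- sqrt(rowSums(pos[idx, , drop = FALSE]^2))
    hit <- r_new <= R
    # bridge: probability the radial excursion touched R inside the step
    miss <- !hit
    if (any(miss)) {
      p_bridge <- exp(-(pmax(r_old[miss] - R, 0) * pmax(r_new[miss] - R, 0)) /
                        (D * dt))
      hit[miss] <- runif(sum(miss)) < p_bridge
    }
    if (any(hit)) {
      times[idx[hit]] <- s * dt
      alive[idx[hit]] <- FALSE
    }
  }
  times
}

# Multi-particle random-flight simulator for toy configurations, vectorized
# across replicates: all pairs of alive particles react at contact radius
# R_pair (products inert). Returns the number of executed reactions per
# replicate by t_max.
bd_multi_reaction_counts <- function(n_rep, positions, D, R_pair,
                                     dt = 5e-3, t_max = 20, seed = 1) {
  set.seed(seed)
  npart <- nrow(positions)
  pairs <- utils::combn(npart, 2)
  npair <- ncol(pairs)
  sd_step <- sqrt(2 * D * dt)
  nstep <- ceiling(t_max / dt)
  # pos[rep, part, axis] flattened as three (n_rep x npart) matrices
  px <- matrix(positions[, 1], n_rep, npart, byrow = TRUE)
  py <- matrix(positions[, 2], n_rep, npart, byrow = TRUE)
  pz <- matrix(positions[, 3], n_rep, npart, byrow = TRUE)
  alive <- matrix(TRUE, n_rep, npart)
  counts <- integer(n_rep)
  dist_pair <- function(mx, my, mz, i, j)
    sqrt((mx[, i] - mx[, j])^2 + (my[, i] - my[, j])^2 + (mz[, i] - mz[, j])^2)
  r_old <- vapply(seq_len(npair), function(p)
    dist_pair(px, py, pz, pairs[1, p], pairs[2, p]), numeric(n_rep))
  for (s in seq_len(nstep)) {
    px <- px + matrix(rnorm(n_rep * npart, 0, sd_step), n_rep, npart)
    py <- py + matrix(rnorm(n_rep * npart, 0, sd_step), n_rep, npart)
    pz <- pz + matrix(rnorm(n_rep * npart, 0, sd_step), n_rep, npart)
    for (p in seq_len(npair)) {
      i <- pairs[1, p]; j <- pairs[2, p]
      ok <- alive[, i] & alive[, j]
      if (!any(ok)) next
      r_new <- dist_pair(px, py, pz, i, j)
      # mutual diffusion of the separation is 2D; bridge-corrected contact
      p_hit <- ifelse(r_new <= R_pair, 1,
                      exp(-(pmax(r_old[, p] - R_pair, 0) *
                              pmax(r_new - R_pair, 0)) / (2 * D * dt)))
      hit <- ok & (runif(n_rep) < p_hit)
      if (any(hit)) {
        alive[hit, i] <- FALSE
        alive[hit, j] <- FALSE
        counts[hit] <- counts[hit] + 1L
      }
      r_old[, p] <- r_new
    }
  }
  counts
}

# Toy network: identical neutral species A with a single self-reaction
# A + A -> P at contact radius R_nm (D per particle, mutual 2D).
toy_self_network <- function(R_nm = 0.8, D = 1) {
  sp <- tibble::tibble(
    name = c("A", "P"), charge = 0L,
    diffusion_coefficient = c(D, D), is_bulk = FALSE, conc = 0,
    nH = 0L, nO = 0L, nS = 0L, nN = 0L, nC = 0L, nFe = 0L)
  rx <- frickeirt:::new_reaction_row("T1", c("A", "A"), "P",
                                     k_for_radius(R_nm, 2 * D))
  reaction_network(sp, rx)
}

# Fabricated track segment holding given particles in a periodic box of
# length L_nm (for driving the engine with hand-placed configurations).
toy_track <- function(species, x, y, z, L_nm = 1000, deposited_eV = 100) {
  structure(list(
    particles = tibble::tibble(species = species, x = x, y = y, z = z,
                               event = 1L, origin = "toy"),
    event_x = 0, let = 1, length_nm = L_nm, deposited_eV = deposited_eV,
    n_events = 1L, beam = NULL, params = NULL, seed = NULL
  ), class = "track_segment")
}

# Small standard kinetics run reused across tests (cached per session).
cached_kinetics <- local({
  cache <- new.env()
  function(key = "lowlet", ...) {
    if (is.null(cache[[key]])) cache[[key]] <- simulate_fricke_kinetics(...)
    cache[[key]]
  }
})
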