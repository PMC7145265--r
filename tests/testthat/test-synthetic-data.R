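test_that("reference model reproduces the calibrated thermodynamics", {
  m <- build_reference_model(protonated = TRUE, temperature = 300)
  # Boltzmann arithmetic oracle: pi = exp(-G/kT)/Z at kT = 0.5962 kcal/mol
  kT <- 0.59616
  w <- exp(-c(0, 0.59, 2.55, 2.55) / kT)
  expect_equal(unname(m$stationary), w / sum(w), tolerance = 1e-10)
  expect_equal(unname(round(m$stationary, 4)),
               c(0.7146, 0.2656, 0.0099, 0.0099))
  # pi_O ~ 1%, and the configured barriers are preserved
  expect_lt(abs(m$stationary[["O"]] - 0.01), 2e-3)
  expect_equal(unname(m$barriers[c("C_oi->C_o", "C_o->U")]), c(2.0, 5.0))
  # stationary distribution of K equals the Boltzmann weights (eigen route)
  expect_equal(unname(ctmc_stationary(m$rate_matrix)),
               unname(m$stationary), tolerance = 1e-8)
})

test_that("generator structure: rows sum to zero, detailed balance, U gating", {
  for (prot in c(TRUE, FALSE)) {
    for (temp in c(280, 300, 320)) {
      m <- build_reference_model(protonated = prot, temperature = temp)
      K <- m$rate_matrix
      expect_lt(max(abs(rowSums(K))), 1e-12)
      off <- K[row(K) != col(K)]
      expect_true(all(off >= 0))
      expect_lt(detailed_balance_residual(K, m$stationary), 1e-10)
      expect_identical("U" %in% m$state_labels, prot)
    }
  }
  # protonated: U may transition forward to any other state
  m <- build_reference_model(TRUE)
  expect_true(all(m$rate_matrix["U", c("C_oi", "C_o", "O")] > 0))
})

test_that("reference model rejects invalid physics", {
  expect_error(build_reference_model(temperature = -1), "temperature")
  expect_error(build_reference_model(
    free_energies = c(C_oi = 0, C_o = 3, O = 4, U = 4),
    barriers = c("C_oi->C_o" = 2.0, "C_o->O" = 4.5, "C_o->U" = 5.0)),
    "barrier")
})

test_that("CTMC sampler: stationarity, determinism, grid bound", {
  m <- build_reference_model(FALSE)
  # single-frame paths are draws from pi
  p1 <- sample_ctmc(m, n_traj = 3000, n_steps = 1, dt = 0.1, seed = 4)
  freq <- tabulate(unlist(p1), nbins = 3) / 3000
  se <- sqrt(m$stationary * (1 - m$stationary) / 3000)
  expect_true(all(abs(freq - m$stationary) < 3 * se + 1e-9))

  # 2-state model: long-path occupancy converges to pi within 3 binomial SDs
  # (effective sample size = number of dwell segments, not frames)
  K2 <- matrix(c(-0.2, 0.2, 0.4, -0.4), 2, 2, byrow = TRUE)
  m2 <- list(rate_matrix = K2, stationary = c(2, 1) / 3,
             state_labels = c("a", "b"))
  p2 <- sample_ctmc(m2, n_traj = 1, n_steps = 60000, dt = 0.1, seed = 9)[[1]]
  f1 <- mean(p2 == 1)
  n_segments <- sum(diff(p2) != 0) + 1
  expect_lt(abs(f1 - 2 / 3), 3 * sqrt((2 / 9) / n_segments))

  # determinism under seed
  pa <- sample_ctmc(m, 5, 500, dt = 0.1, seed = 77)
  pb <- sample_ctmc(m, 5, 500, dt = 0.1, seed = 77)
  expect_identical(pa, pb)

  # dt too coarse is refused with the bound named
  expect_error(sample_ctmc(build_reference_model(TRUE), 1, 10, dt = 5,
                           seed = 1), "0.1")
})

test_that("emission: degenerate concentration, wrap shift, state isolation", {
  states <- c("A", "B")
  mu <- matrix(c(10, 10, -40, 140), 2, 2, byrow = TRUE,
               dimnames = list(c("f1", "f2"), states))
  # kappa = Inf: every frame equals the state mean
  em_inf <- emission_model(mu, kappa = Inf)
  paths <- list(c(1L, 1L, 2L))
  attr(paths, "state_labels") <- states
  f <- emit_features(paths, em_inf, seed = 1)[[1]]
  expect_equal(unname(f[, "f2"]), c(-40, -40, 140))

  # shifting a mean by 360 degrees leaves the output unchanged
  em_a <- emission_model(mu, kappa = 20)
  mu_shift <- mu; mu_shift["f1", "A"] <- mu_shift["f1", "A"] + 360
  em_b <- emission_model(mu_shift, kappa = 20)
  long <- list(rep(1L, 2000)); attr(long, "state_labels") <- states
  fa <- emit_features(long, em_a, seed = 5)[[1]]
  fb <- emit_features(long, em_b, seed = 5)[[1]]
  expect_equal(fa, fb)

  # states differing only in f2: f1 statistically identical across states
  balanced <- list(rep(c(1L, 2L), each = 4000))
  attr(balanced, "state_labels") <- states
  fx <- emit_features(balanced, emission_model(mu, kappa = 14.6),
                      seed = 8)[[1]]
  m1 <- circ_mean(fx[1:4000, "f1"]); m2 <- circ_mean(fx[4001:8000, "f1"])
  expect_lt(abs(m1 - m2), 2)        # ~15-degree SD, n = 4000 per state
  expect_error(emit_features(list(c(1L, 5L)), em_a, seed = 1), "state")
})

test_that("default emission model matches the archetype loading pattern", {
  em <- default_emission_model()
  expect_identical(em$discriminative,
                   c("psi:I170-G169", "psi:G169-S168", "chi1:E211"))
  # the two psi features separate C_oi from the rest; all open-like agree
  expect_equal(unname(em$mean["psi:I170-G169", c("C_o", "O", "U")]),
               rep(120, 3))
  expect_false(em$mean["psi:I170-G169", "C_oi"] ==
               em$mean["psi:I170-G169", "C_o"])
  # chi1(E211) has three distinct modes: {C_oi, C_o} vs O vs U
  chi <- em$mean["chi1:E211", ]
  expect_equal(unname(chi["C_oi"]), unname(chi["C_o"]))
  expect_equal(length(unique(chi)), 3)
  # every non-discriminative feature is identical across states
  other <- setdiff(rownames(em$mean), em$discriminative)
  expect_true(all(apply(em$mean[other, ], 1,
                        function(r) length(unique(r)) == 1)))
  # emitted angles respect the wrap invariant
  p <- list(rep(4L, 500)); attr(p, "state_labels") <- em$states
  f <- emit_features(p, em, seed = 2)[[1]]
  expect_true(all(f >= -180 & f < 180))
})

test_that("pooled chi1(E211) shows three rotamer modes under protonation", {
  m <- build_reference_model(TRUE)
  p <- sample_ctmc(m, n_traj = 6, n_steps = 4000, dt = 0.1, seed = 31)
  em <- default_emission_model()
  f <- emit_features(p, em, seed = 32)
  states <- unlist(p); chi <- unlist(lapply(f, function(x) x[, "chi1:E211"]))
  for (s in 1:4) {
    mode <- em$mean["chi1:E211", em$states[s]]
    sel <- states == s
    if (!any(sel)) next
    expect_lt(abs(circ_mean(chi[sel]) - mode), 5)
  }
  # all three modes populated in pooled data
  pooled_modes <- c(-90, 30, 150)
  counts <- vapply(pooled_modes, function(mu)
    sum(abs(wrap_angle(chi - mu)) < 45), numeric(1))
  expect_true(all(counts > 0))
})

test_that("Langevin: degenerate, harmonic, and stability behaviour", {
  w <- double_well(a4 = 2, a2 = -4)           # symmetric, barrier 2
  expect_equal(w$barrier_left, 2, tolerance = 1e-12)
  # zero diffusion from the minimum: constant trajectory
  s0 <- langevin_spec(w, diffusion = 0, dt = 1e-3, n_steps = 100, seed = 1)
  x <- sample_langevin(s0, x0 = w$minima[1])
  expect_true(all(x == w$minima[1]))
  # harmonic well: sample variance = kT/kappa within 5% at n = 1e6
  kap <- 8; kT <- 0.59616
  sh <- langevin_spec(harmonic_well(kap), diffusion = 1, dt = 5e-3,
                      n_steps = 1e6, kT = kT, seed = 12)
  xh <- sample_langevin(sh, x0 = 0)
  expect_lt(abs(var(xh) - kT / kap) / (kT / kap), 0.05)
  # unstable time step refused
  expect_error(sample_langevin(langevin_spec(w, dt = 1, n_steps = 10,
                                             seed = 1)), "stability")
})

test_that("double-well calibration recovers barrier and offset in closed form", {
  w <- calibrate_double_well(barrier = 5.0, offset = 1.96)
  expect_equal(w$barrier_left, 5.0, tolerance = 1e-5)
  expect_equal(w$offset, 1.96, tolerance = 1e-5)
  g <- well_geometry(w$coef)      # closed-form recovery from coefficients
  expect_equal(g$barrier_left, w$barrier_left)
  expect_error(calibrate_double_well(1, offset = 2))
})

test_that("pore fixtures encode their analytic ground truth", {
  cyl <- make_pore_fixture("cylinder", ring_radius = 4.5, atom_radius = 1.5)
  expect_equal(cyl$true_radius(c(-5, 0, 5)), rep(3.0, 3))
  hg <- make_pore_fixture("hourglass", waist = 1.5, curvature = 0.05)
  expect_equal(hg$true_radius(0), 1.5)
  expect_equal(min(hg$true_radius(seq(-10, 10, 0.1))), 1.5)
  bl <- make_pore_fixture("blocked", ring_radius = 4.5, atom_radius = 1.5)
  expect_true(any(bl$atoms$x == 0 & bl$atoms$y == 0))
  expect_lt(bl$true_radius(0), 0)
  # PDB + sidecar round trip preserves geometry
  f <- tempfile(fileext = ".pdb")
  write_pore_fixture(cyl, f)
  p <- bio3d::read.pdb(f)
  expect_equal(nrow(p$atom), nrow(cyl$atoms))
  r <- read.csv(sub("\\.pdb$", ".radii.csv", f))
  expect_equal(r$radius, cyl$atoms$radius)
})

test_that("ion fixture frequencies match their generating probabilities", {
  sites <- rbind(S_ext = c(0, 0, 10), S_cen = c(0, 0, 0), S_int = c(0, 0, -10))
  probs <- rbind(O = c(0.93, 0.04, 0.04), C_oi = c(0, 0, 0.5))
  colnames(probs) <- rownames(sites)
  ens <- make_ion_fixture(sites, site_radius = 2.5, occupancy_probs = probs,
                          n_samples = 1000, seed = 3)
  occ <- occupancy_table(ens, sites, site_radius = 2.5)
  expect_lt(abs(occ["O", "S_ext"] - 0.93), 0.03)
  expect_equal(unname(occ["C_oi", c("S_ext", "S_cen")]), c(0, 0))
  # binomial 3-SD band at p = 0.5
  expect_lt(abs(occ["C_oi", "S_int"] - 0.5), 3 * sqrt(0.25 / 1000))
  # overlapping sites warn
  sites2 <- rbind(a = c(0, 0, 0), b = c(0, 0, 1))
  probs2 <- matrix(0.5, 1, 2, dimnames = list("s", c("a", "b")))
  expect_warning(make_ion_fixture(sites2, 2.5, probs2, 10, seed = 1),
                 "overlap")
})
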