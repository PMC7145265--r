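test_that("transition counting enumerates sliding-window pairs", {
  # path 1,1,2,2 at lag 1: (1,1), (1,2), (2,2)
  C <- count_transitions(c(1L, 1L, 2L, 2L), lag = 1)
  expect_equal(C, matrix(c(1L, 0L, 1L, 1L), 2, 2))
  # lag = length - 1: exactly one count
  expect_equal(sum(count_transitions(c(1L, 2L, 1L, 2L), lag = 3)), 1)
  # total counts identity over multiple trajectories
  set.seed(61)
  d <- lapply(c(50, 80, 120), function(n) sample.int(4, n, replace = TRUE))
  lag <- 7
  expect_equal(sum(count_transitions(d, lag)),
               sum(vapply(d, length, integer(1)) - lag))
  expect_error(count_transitions(c(1L, 2L), lag = 5), "lag")
})

test_that("largest connected set matches a brute-force reachability oracle", {
  # fully connected
  C <- matrix(5L, 3, 3)
  expect_equal(largest_connected_set(C), 1:3)
  # two disjoint blocks, sizes 3 and 2: the better-sampled 3-block wins
  C <- matrix(0L, 5, 5)
  C[1:3, 1:3] <- 4L; C[4:5, 4:5] <- 2L
  expect_equal(suppressMessages(largest_connected_set(C)), 1:3)
  # a directed chain has only singleton components
  C <- matrix(0L, 4, 4)
  C[cbind(1:3, 2:4)] <- 3L
  C[2, 2] <- 10L
  expect_equal(suppressMessages(largest_connected_set(C)), 2L)
  # randomized graphs against the oracle
  set.seed(62)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    C <- matrix(rpois(n * n, 0.45), n, n)
    expect_equal(suppressMessages(largest_connected_set(C)),
                 oracle_scc_largest(C))
  }
})

test_that("reversible MLE: exact symmetric case and optimizer oracle", {
  C <- matrix(c(90L, 10L, 10L, 90L), 2, 2)
  m <- mle_reversible(C)
  expect_equal(m$transition_matrix,
               matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), tolerance = 1e-9)
  expect_equal(m$stationary, c(0.5, 0.5), tolerance = 1e-9)
  # non-symmetric 3-state counts vs direct likelihood maximisation
  set.seed(63)
  for (i in 1:5) {
    C3 <- matrix(rpois(9, 20) + 1L, 3, 3)
    m3 <- mle_reversible(C3)
    o3 <- oracle_reversible_mle(C3)
    expect_equal(m3$transition_matrix, o3$T, tolerance = 1e-6)
    expect_equal(m3$stationary, o3$pi, tolerance = 1e-6)
  }
})

test_that("every estimated model is reversible with a real spectrum", {
  set.seed(64)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    C <- matrix(rpois(n * n, 3), n, n)
    m <- suppressMessages(mle_reversible(C))
    Tm <- m$transition_matrix
    expect_lt(max(abs(rowSums(Tm) - 1)), 1e-10)
    expect_lt(detailed_balance_residual(Tm, m$stationary), 1e-8)
    expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
    expect_true(all(abs(Im(eigen(Tm)$values)) < 1e-10))
  }
  expect_error(mle_reversible(matrix(c(90L, 10L, 40L, 60L), 2, 2),
                              max_iter = 1), "converge")
})

test_that("implied timescales: closed form and lag-independence", {
  # T = [[0.95, 0.05], [0.05, 0.95]] at lag 1: t2 = -1/ln(0.9) = 9.491
  m <- mle_reversible(matrix(c(95L, 5L, 5L, 95L), 2, 2), lag_frames = 1)
  expect_equal(-1 / log(m$eigenvalues[2]), 9.4912, tolerance = 1e-4)
  # Markovian synthetic dtrajs: t2 flat in lag, near the generator value
  K <- matrix(c(-0.05, 0.05, 0.1, -0.1), 2, 2, byrow = TRUE)
  gen <- list(rate_matrix = K, stationary = c(2, 1) / 3,
              state_labels = c("a", "b"))
  d <- sample_ctmc(gen, n_traj = 10, n_steps = 20000, dt = 1, seed = 65)
  its <- implied_timescales(d, lags = c(2, 4, 8), n_timescales = 1)
  t_true <- 1 / 0.15
  expect_true(all(abs(its$timescale_frames - t_true) / t_true < 0.15))
  expect_true(all(its$converged[its$lag_frames < 8]))
})

test_that("timescales are robust to doubling the microstate count", {
  res <- small_pipeline()
  r <- res$conditions$protonated
  dtrajs_fine <- r$dtrajs
  # re-cluster the same projections at half k
  coarse <- fit_minibatch_kmeans(r$projections, k = 30, seed = 99,
                                 n_iter = 60)
  lag <- res$config$msm_lag_frames
  t_fine <- implied_timescales(dtrajs_fine, lags = lag, n_timescales = 1)
  t_coarse <- implied_timescales(coarse$assignments, lags = lag,
                                 n_timescales = 1)
  expect_lt(abs(t_fine$timescale_frames[1] - t_coarse$timescale_frames[1]) /
            t_fine$timescale_frames[1], 0.2)
})

test_that("bootstrap: identity-multiset limit, SD scaling, defaults", {
  # identical trajectories: every resample equals the full data
  d0 <- c(rep(1L, 30), rep(2L, 30), rep(1L, 40))
  d <- list(d0, d0, d0)
  b <- bootstrap_msms(d, lag = 1, n_boot = 5, seed = 66)
  for (m in b$models)
    expect_equal(m$transition_matrix, b$mle$transition_matrix,
                 tolerance = 1e-12)
  expect_equal(formals(bootstrap_msms)$n_boot, 100)
  # error bars shrink roughly like 1/sqrt(n_traj)
  K <- matrix(c(-0.02, 0.02, 0.04, -0.04), 2, 2, byrow = TRUE)
  gen <- list(rate_matrix = K, stationary = c(2, 1) / 3,
              state_labels = c("a", "b"))
  d_small <- sample_ctmc(gen, 20, 500, dt = 1, seed = 67)
  d_large <- sample_ctmc(gen, 80, 500, dt = 1, seed = 68)
  b_small <- bootstrap_msms(d_small, lag = 1, n_boot = 60, seed = 69)
  b_large <- bootstrap_msms(d_large, lag = 1, n_boot = 60, seed = 70)
  ratio <- mean(b_small$pi_sd) / mean(b_large$pi_sd)
  expect_gt(ratio, 1.2)          # expected ~2 with Monte-Carlo slack
  expect_lt(ratio, 3.4)
})

test_that("free energies follow Boltzmann inversion with zero minimum", {
  expect_equal(free_energy(rep(0.25, 4)), rep(0, 4))
  g <- free_energy(c(0.99, 0.01), kT = 0.5962)
  expect_equal(g[2], 2.74, tolerance = 0.01)
  expect_equal(g[1], 0)
  expect_warning(g0 <- free_energy(c(1, 0)), "zero")
  expect_true(is.infinite(g0[2]))
  # population ~1% sits in the 2-3 kcal/mol band at 300 K
  g_o <- free_energy(c(0.715, 0.275, 0.01))
  expect_gt(g_o[3], 2); expect_lt(g_o[3], 3)
})

test_that("MSM-weighted profiles recover basin free energies and barriers", {
  # two-state chain with unequal sampling: reweighting must fix the bias
  K <- matrix(c(-0.02, 0.02, 0.08, -0.08), 2, 2, byrow = TRUE)
  pi_true <- c(0.8, 0.2)
  gen <- list(rate_matrix = K, stationary = pi_true,
              state_labels = c("a", "b"))
  d <- sample_ctmc(gen, 20, 2000, dt = 1, seed = 71)
  C <- count_transitions(d, 5)
  msm <- mle_reversible(C, lag_frames = 5)
  w <- frame_weights(msm, d)
  expect_equal(length(w), 20)
  # frames of one microstate carry equal weight summing to pi of that state
  w_all <- unlist(w); s_all <- unlist(d)
  expect_equal(sum(w_all[s_all == 1]), msm$stationary[1], tolerance = 1e-12)
  # projected free energy along a coordinate separating the states
  set.seed(73)
  x <- ifelse(s_all == 1, rnorm(length(s_all), -1, 0.45),
              rnorm(length(s_all), 1, 0.45))
  fep <- free_energy_profile(x, weights = w_all, kT = 0.5962, bins = 60)
  bar <- profile_barrier(fep, from = -1, to = 1)
  dg_est <- bar$to_min[["free_energy"]] - bar$from_min[["free_energy"]]
  dg_true <- -0.5962 * log(pi_true[2] / pi_true[1])
  expect_lt(abs(dg_est - dg_true), 0.25)
  expect_gt(bar$barrier, dg_true)   # top lies above the shallow basin
  # single-basin data: no barrier to annotate
  fep1 <- free_energy_profile(rnorm(5000), bins = 40)
  expect_error(profile_barrier(fep1), "fewer than two basins")
})

test_that("Chapman-Kolmogorov holds on Markovian fixture data", {
  m0 <- build_reference_model(TRUE)
  d <- sample_ctmc(m0, 30, 4000, dt = 0.1, seed = 72)
  tau <- 10
  m1 <- mle_reversible(count_transitions(d, tau), lag_frames = tau)
  m2 <- mle_reversible(count_transitions(d, 2 * tau), lag_frames = 2 * tau)
  P_pred <- m1$transition_matrix %*% m1$transition_matrix
  expect_lt(max(abs(diag(P_pred) - diag(m2$transition_matrix))), 0.05)
})
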