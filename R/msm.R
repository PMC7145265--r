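#' Sliding-window transition counts
#'
#' @param dtrajs List of integer state trajectories (1-based), or one vector.
#' @param lag Lag in frames (>= 1).
#' @param n_states Number of states (default: maximum observed index).
#' @return Integer count matrix `C` with `C[i, j]` = number of observed
#'   `i -> j` transitions at the given lag.
#' @export
count_transitions <- function(dtrajs, lag, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(lag >= 1)
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, integer(1)))
  n <- as.integer(n_states)
  counts <- numeric(n * n)
  usable <- FALSE
  for (d in dtrajs) {
    T <- length(d)
    if (T <= lag) next
    usable <- TRUE
    from <- d[seq_len(T - lag)]
    to <- d[(lag + 1):T]
    idx <- from + n * (to - 1L)
    tab <- tabulate(idx, nbins = n * n)
    counts <- counts + tab
  }
  if (!usable) stop("lag is not shorter than any trajectory")
  matrix(as.integer(counts), n, n)
}

#' Largest (strongly) connected set of a count matrix
#'
#' Strongly connected components of the directed count graph; returns the
#' component with the largest total counts.  States outside the set are
#' reported with a message.
#'
#' @param counts Square count matrix.
#' @return Sorted integer vector of state indices.
#' @export
largest_connected_set <- function(counts) {
  n <- nrow(counts)
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  stats_for <- function(cid) {
    m <- which(comp == cid)
    c(sum(counts[m, m, drop = FALSE]), length(m), -min(m))
  }
  tab <- vapply(seq_len(max(comp)), stats_for, numeric(3))
  # deterministic choice: most counts, then most states, then lowest index
  ord <- order(tab[1, ], tab[2, ], tab[3, ], decreasing = TRUE)
  best <- which(comp == ord[1])
  dropped <- setdiff(seq_len(n), best)
  observed <- which(rowSums(counts) + colSums(counts) > 0)
  if (length(intersect(dropped, observed)))
    message(sprintf("ergodic trimming: %d observed state(s) outside the largest connected set",
                    length(intersect(dropped, observed))))
  sort(best)
}

#' Reversible maximum-likelihood Markov state model
#'
#' Maximum-likelihood transition matrix under the detailed-balance constraint
#' via the standard iterative fixed point on symmetric edge weights:
#' `x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)`, iterated until the
#' log-likelihood change falls below `tol`.  The stationary distribution is
#' given by the converged row sums and verified against the leading left
#' eigenvector.
#'
#' @param counts Count matrix (will be restricted to its largest connected
#'   set unless `active` is supplied).
#' @param lag_frames Lag used to build the counts (frames).
#' @param frame_ns Physical time per frame in nanoseconds (for reporting).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum fixed-point iterations.
#' @param active Optional pre-computed active set.
#' @return Object of class `msm_model`: `transition_matrix`, `stationary`,
#'   `eigenvalues`, `active` (original state indices), `mapping` (original
#'   index -> active index or NA), `lag_frames`, `lag_ns`, `counts`.
#' @export
mle_reversible <- function(counts, lag_frames = 1, frame_ns = 1,
                           tol = 1e-10, max_iter = 10000, active = NULL) {
  if (is.null(active)) active <- largest_connected_set(counts)
  C <- counts[active, active, drop = FALSE]
  n <- nrow(C)
  if (n < 1 || sum(C) == 0) stop("no transitions on the active set")
  Csym <- C + t(C)
  x <- Csym / sum(Csym)
  ci <- rowSums(C)
  loglik <- function(Tm) {
    sel <- C > 0
    sum(C[sel] * log(Tm[sel]))
  }
  Tm <- x / rowSums(x)
  ll_old <- loglik(Tm)
  iter <- 0
  repeat {
    iter <- iter + 1
    xi <- rowSums(x)
    q <- ci / xi
    denom <- outer(q, q, "+")
    x_new <- Csym / denom
    x_new[Csym == 0] <- 0
    x <- x_new / sum(x_new)
    Tm <- x / rowSums(x)
    ll <- loglik(Tm)
    if (abs(ll - ll_old) < tol) break
    if (iter >= max_iter)
      stop(sprintf("reversible MLE did not converge in %d iterations (residual %.3g)",
                   max_iter, abs(ll - ll_old)))
    ll_old <- ll
  }
  pi_hat <- rowSums(x)
  pi_hat <- pi_hat / sum(pi_hat)
  # verify against the leading left eigenvector
  ev <- eigen(t(Tm))
  i1 <- which.max(Re(ev$values))
  pi_eig <- abs(Re(ev$vectors[, i1])); pi_eig <- pi_eig / sum(pi_eig)
  stopifnot(max(abs(pi_hat - pi_eig)) < 1e-6)
  mapping <- rep(NA_integer_, nrow(counts))
  mapping[active] <- seq_len(n)
  structure(list(transition_matrix = Tm, stationary = pi_hat,
                 eigenvalues = msm_eigenvalues(Tm, pi_hat),
                 active = active, mapping = mapping,
                 lag_frames = lag_frames, lag_ns = lag_frames * frame_ns,
                 frame_ns = frame_ns, counts = C),
            class = "msm_model")
}

# Real spectrum of a reversible transition matrix via the similarity
# transform B = D^{1/2} T D^{-1/2} (symmetric when detailed balance holds).
msm_eigenvalues <- function(Tm, pi) {
  d <- sqrt(pi)
  B <- (d * Tm) %*% diag(1 / d)
  sort(eigen((B + t(B)) / 2, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

# Right eigenvectors of a reversible T, pi-orthonormal, constant vector first.
msm_right_eigenvectors <- function(Tm, pi, n) {
  d <- sqrt(pi)
  B <- (d * Tm) %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  V <- e$vectors[, ord[seq_len(n)], drop = FALSE] / d
  # normalise: sum_i pi_i V_ik^2 = 1; fix sign of the constant vector
  nrm <- sqrt(colSums(pi * V^2))
  V <- sweep(V, 2, nrm, "/")
  if (V[1, 1] < 0) V[, 1] <- -V[, 1]
  list(values = e$values[ord[seq_len(n)]], vectors = V)
}

#' Implied relaxation timescales across lag times
#'
#' `t_i(tau) = -tau / ln lambda_i(tau)` for the top `n_timescales`
#' non-stationary eigenvalues of the reversible MSM at each lag.
#' Non-positive eigenvalues yield `NA` timescales (reported, not dropped).
#' A convergence flag marks lags whose timescales agree with the next lag
#' within `rel_tol`.
#'
#' @param dtrajs List of integer state trajectories.
#' @param lags Integer vector of lag times (frames).
#' @param n_timescales Number of timescales to report.
#' @param frame_ns Physical time per frame (ns).
#' @param n_states Optional number of states.
#' @param rel_tol Relative tolerance for the convergence flag.
#' @return Data frame: `lag_frames`, `timescale_index`, `timescale_frames`,
#'   `timescale_ns`, `converged`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 5, frame_ns = 1,
                               n_states = NULL, rel_tol = 0.1) {
  rows <- lapply(lags, function(tau) {
    C <- count_transitions(dtrajs, tau, n_states)
    m <- mle_reversible(C, lag_frames = tau, frame_ns = frame_ns)
    lam <- m$eigenvalues[-1]
    lam <- lam[seq_len(min(n_timescales, length(lam)))]
    ts <- ifelse(lam > 0 & lam < 1, -tau / log(lam), NA_real_)
    data.frame(lag_frames = tau, timescale_index = seq_along(ts),
               timescale_frames = ts, timescale_ns = ts * frame_ns)
  })
  out <- do.call(rbind, rows)
  out$converged <- NA
  for (i in seq_along(lags)[-length(lags)]) {
    a <- out$timescale_frames[out$lag_frames == lags[i]]
    b <- out$timescale_frames[out$lag_frames == lags[i + 1]]
    m <- min(length(a), length(b))
    ok <- all(abs(a[1:m] - b[1:m]) <= rel_tol * pmax(abs(b[1:m]), 1e-12),
              na.rm = TRUE)
    out$converged[out$lag_frames == lags[i]] <- ok
  }
  out
}

#' Bootstrap ensemble of Markov state models
#'
#' Resamples whole trajectories with replacement (preserving within-trajectory
#' autocorrelation), re-estimates the reversible MSM on each replicate's
#' largest connected subset of the full-data active set (sharing the full-data
#' state definition), and reports per-state stationary SDs aligned on the
#' full active set.  Replicates whose connected subset loses more than
#' `max_mass_loss` of the full-model stationary mass are dropped and counted.
#'
#' @param dtrajs List of integer state trajectories (>= 2).
#' @param lag Lag in frames.
#' @param n_boot Number of bootstrap models (default 100).
#' @param seed Integer RNG seed.
#' @param frame_ns Physical time per frame (ns).
#' @param n_states Optional number of states.
#' @param max_mass_loss Largest tolerated stationary-mass loss before a
#'   replicate is dropped (default 0.01).
#' @return Object of class `msm_bootstrap`: `mle` (full-data model),
#'   `models` (list of `msm_model`), `pi_sd` (bootstrap SD of the stationary
#'   distribution, aligned on the full active set), `n_dropped`.
#' @export
bootstrap_msms <- function(dtrajs, lag, n_boot = 100, seed = 1, frame_ns = 1,
                           n_states = NULL, max_mass_loss = 0.01) {
  stopifnot(length(dtrajs) >= 2)
  if (is.null(n_states)) n_states <- max(vapply(dtrajs, max, integer(1)))
  per_traj <- lapply(dtrajs, count_transitions, lag = lag, n_states = n_states)
  C_full <- Reduce(`+`, per_traj)
  mle <- mle_reversible(C_full, lag_frames = lag, frame_ns = frame_ns)
  active <- mle$active
  models <- with_seed(seed, lapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(dtrajs), replace = TRUE)
    Cb <- Reduce(`+`, per_traj[idx])
    sub <- tryCatch(suppressMessages(
      largest_connected_set(Cb[active, active, drop = FALSE])),
      error = function(e) integer(0))
    if (!length(sub)) return(NULL)
    if (sum(mle$stationary[sub]) < 1 - max_mass_loss) return(NULL)
    tryCatch(suppressMessages(
      mle_reversible(Cb, lag_frames = lag, frame_ns = frame_ns,
                     active = active[sub])),
      error = function(e) NULL)
  }))
  n_dropped <- sum(vapply(models, is.null, logical(1)))
  if (n_dropped > 0)
    message(sprintf("%d bootstrap replicate(s) lost connectivity and were dropped",
                    n_dropped))
  models <- Filter(Negate(is.null), models)
  # align stationary vectors on the full active set (absent states -> 0)
  pis <- do.call(rbind, lapply(models, function(m) {
    v <- numeric(length(active))
    v[match(m$active, active)] <- m$stationary
    v
  }))
  structure(list(mle = mle, models = models,
                 pi_sd = apply(pis, 2, sd), n_dropped = n_dropped),
            class = "msm_bootstrap")
}

#' Free energies from a stationary distribution
#'
#' Boltzmann inversion `dG_i = -kT ln(pi_i / max_j pi_j)`; the minimum is
#' exactly 0.  Zero-population states are reported as `Inf` with a warning.
#'
#' @param pi Stationary probabilities (normalised).
#' @param kT Thermal energy in kcal/mol.
#' @return Numeric vector of free energies (kcal/mol).
#' @export
free_energy <- function(pi, kT = kT_kcal(300)) {
  stopifnot(abs(sum(pi) - 1) < 1e-6, all(pi >= 0))
  if (any(pi == 0)) warning("zero-population state(s): free energy is +Inf")
  -kT * log(pi / max(pi))
}
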