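# Fill the PCCA+ transform matrix A from its free block so that the
# memberships chi = Psi %*% A are non-negative with rows summing to 1
# (standard feasibility construction over the dominant-eigenvector simplex).
pcca_fill_A <- function(A, Psi) {
  n <- ncol(A)
  if (n > 1) {
    A[1, 2:n] <- vapply(2:n, function(j)
      -min(Psi[, 2:n, drop = FALSE] %*% A[2:n, j, drop = FALSE]), numeric(1))
    A[2:n, 1] <- -rowSums(A[2:n, 2:n, drop = FALSE])
  }
  A[1, 1] <- 1 - sum(A[1, -1])
  A
}

# Inner-simplex vertex search: pick the n rows of Psi that best span the
# simplex (farthest-point heuristic with orthogonal deflation).
pcca_vertex_search <- function(Psi) {
  n <- ncol(Psi)
  idx <- integer(n)
  idx[1] <- which.max(rowSums(Psi^2))
  for (k in 2:n) {
    # deflate against already chosen vertices (projection in row space)
    B <- Psi[idx[1:(k - 1)], , drop = FALSE]
    P <- t(B) %*% solve(B %*% t(B) + 1e-12 * diag(k - 1), B)
    R <- Psi - Psi %*% P
    idx[k] <- which.max(rowSums(R^2))
  }
  idx
}

#' PCCA+ fuzzy coarse-graining of a Markov state model
#'
#' Maps the top-n right eigenvectors of the reversible transition matrix onto
#' a probability simplex: an inner-simplex vertex search provides the initial
#' transform, which is then refined by feasibility-constrained maximisation
#' of the crispness objective `trace(diag(1/wbar) chi^T diag(pi) chi)`.
#' Memberships are in `[0, 1]` with rows summing to 1; crisp assignments are
#' the row arg-max.
#'
#' @param msm An `msm_model`.
#' @param n_macrostates Number of macrostates (>= 2), at most the number of
#'   eigenvalues close to 1 (an eigenvalue gap is required below the
#'   requested n).
#' @return Object of class `macro_model`: `membership` (microstates x
#'   macrostates), `crisp` (per active microstate), `populations`,
#'   `n_macrostates`, `msm`.
#' @export
pcca_plus <- function(msm, n_macrostates) {
  n <- n_macrostates
  stopifnot(n >= 2)
  Tm <- msm$transition_matrix
  pi <- msm$stationary
  if (n > nrow(Tm)) stop("more macrostates requested than microstates")
  lam <- msm$eigenvalues
  if (length(lam) > n && lam[n] <= 0)
    stop(sprintf("requested n = %d exceeds the spectral support (lambda_%d = %.3g <= 0)",
                 n, n, lam[n]))
  eg <- msm_right_eigenvectors(Tm, pi, n)
  Psi <- eg$vectors
  Psi[, 1] <- 1                          # constant eigenvector, exactly
  idx <- pcca_vertex_search(Psi)
  A0 <- solve(Psi[idx, , drop = FALSE])
  A0 <- pcca_fill_A(A0, Psi)
  objective <- function(free) {
    A <- A0
    A[2:n, 2:n] <- matrix(free, n - 1, n - 1)
    A <- pcca_fill_A(A, Psi)
    chi <- Psi %*% A
    if (min(chi) < -1e-9) return(1e6)
    wbar <- colSums(pi * chi)
    if (any(wbar <= 0)) return(1e6)
    -sum(colSums(pi * chi^2) / wbar)
  }
  par0 <- as.vector(A0[2:n, 2:n])
  fit <- if (length(par0) == 1) {
    o <- stats::optimize(function(p) objective(p),
                         interval = par0 + c(-10, 10) * max(1, abs(par0)))
    list(par = o$minimum)
  } else {
    optim(par0, objective, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-10))
  }
  A <- A0
  A[2:n, 2:n] <- matrix(fit$par, n - 1, n - 1)
  A <- pcca_fill_A(A, Psi)
  chi <- Psi %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  crisp <- max.col(chi, ties.method = "first")
  pops <- vapply(seq_len(n), function(k) sum(pi[crisp == k]), numeric(1))
  structure(list(membership = chi, crisp = crisp, populations = pops,
                 n_macrostates = n, msm = msm),
            class = "macro_model")
}

#' Choose the number of macrostates from the implied-timescale spectrum
#'
#' Counts the relaxation processes that are resolved at the model's lag time
#' (implied timescale longer than the lag, i.e. eigenvalue above `1/e`) and
#' returns one more than that count — the spectral gap between metastable
#' exchange and intra-basin mixing.  The full timescale/ratio table is
#' attached so the user can inspect the gap structure and override.
#'
#' @param msm An `msm_model`.
#' @param max_n Maximum number of macrostates to consider.
#' @return Integer n (>= 2), with attribute `gap_table` (data frame of
#'   timescales and successive ratios).
#' @export
choose_n_macrostates <- function(msm, max_n = 6) {
  lam <- msm$eigenvalues
  stopifnot(length(lam) >= 3)
  lam2 <- lam[2:min(max_n + 1, length(lam))]
  ts <- ifelse(lam2 > 0 & lam2 < 1, -msm$lag_frames / log(lam2), 0)
  n_resolved <- sum(ts > msm$lag_frames)
  n <- max(2L, min(as.integer(n_resolved) + 1L, max_n))
  ratio <- ts[-length(ts)] / pmax(ts[-1], 1e-12)
  attr(n, "gap_table") <- data.frame(process = seq_along(ts),
                                     timescale_frames = ts,
                                     resolved = ts > msm$lag_frames,
                                     ratio_to_next = c(ratio, NA))
  n
}

#' Bootstrap uncertainty of macrostate populations
#'
#' Aggregates each bootstrap model's microstate stationary distribution over
#' the fixed crisp macrostate assignment and reports the spread.
#'
#' @param macro A `macro_model` (from the full-data MSM).
#' @param bootstrap An `msm_bootstrap` sharing the same active set.
#' @return Data frame: `macrostate`, `population`, `sd`, `lo`, `hi`
#'   (2.5/97.5 percentiles across bootstrap models).
#' @export
macro_population_bands <- function(macro, bootstrap) {
  full_active <- macro$msm$active
  pops <- vapply(bootstrap$models, function(m) {
    v <- numeric(length(full_active))
    v[match(m$active, full_active)] <- m$stationary
    vapply(seq_len(macro$n_macrostates), function(k)
      sum(v[macro$crisp == k]), numeric(1))
  }, numeric(macro$n_macrostates))
  pops <- matrix(pops, nrow = macro$n_macrostates)
  data.frame(macrostate = seq_len(macro$n_macrostates),
             population = macro$populations,
             sd = apply(pops, 1, sd),
             lo = apply(pops, 1, stats::quantile, 0.025),
             hi = apply(pops, 1, stats::quantile, 0.975))
}

#' Map microstate trajectories to macrostate trajectories
#'
#' @param macro A `macro_model`.
#' @param dtrajs List of integer microstate trajectories (original indices).
#' @return List of integer macrostate trajectories; frames outside the MSM
#'   active set are `NA`.
#' @export
macro_dtrajs <- function(macro, dtrajs) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  map <- rep(NA_integer_, length(macro$msm$mapping))
  ok <- !is.na(macro$msm$mapping)
  map[ok] <- macro$crisp[macro$msm$mapping[ok]]
  lapply(dtrajs, function(d) map[d])
}

# expm for a reversible generator via the symmetric similarity transform.
rev_generator_expm <- function(K, pi, tau) {
  d <- sqrt(pi)
  B <- (d * K) %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / d) %*% e$vectors %*% (exp(tau * e$values) * t(e$vectors)) %*%
    diag(d)
  P
}

#' Maximum-likelihood continuous-time rate matrix among macrostates
#'
#' Estimates the generator K (off-diagonals >= 0, rows summing to 0,
#' detailed balance under the macrostate populations) by maximising the
#' likelihood of the observed lag-tau transition counts under
#' `P = expm(K tau)`.  The estimate is initialised from the matrix logarithm
#' of the empirical macrostate transition matrix projected onto the feasible
#' cone (negative off-diagonal rates clipped); if that matrix is not
#' embeddable the projected initialiser simply serves as the starting point
#' of the constrained fit, and the result is flagged.  Edges with no observed
#' transitions in either direction are excluded from the parameterisation and
#' reported as "not observed at this sampling depth", never as rate 0.
#'
#' @param mtrajs List of integer macrostate trajectories (NA allowed; frames
#'   outside the active set are skipped at counting).
#' @param lag Lag in frames for the transition counts.
#' @param frame_ns Physical time per frame (ns); rates are reported per ns.
#' @param n_states Number of macrostates.
#' @param pi_macro Optional macrostate stationary distribution (default: from
#'   the reversible MLE of the macro counts).
#' @return Object of class `rate_matrix`: `K_per_ns`, `K_per_frame`,
#'   `stationary`, `observed_edges` (logical matrix), `counts`, `embeddable`,
#'   `loglik`.
#' @export
estimate_rate_matrix <- function(mtrajs, lag, frame_ns = 1, n_states = NULL,
                                 pi_macro = NULL) {
  mtrajs <- lapply(mtrajs, function(d) d[!is.na(d)])
  C <- count_transitions(mtrajs, lag, n_states)
  n <- nrow(C)
  if (is.null(pi_macro)) {
    m <- suppressMessages(mle_reversible(C, lag_frames = lag))
    pi_macro <- rep(0, n); pi_macro[m$active] <- m$stationary
    pi_macro <- pi_macro / sum(pi_macro)
  }
  obs <- (C + t(C)) > 0; diag(obs) <- FALSE
  edges <- which(obs & upper.tri(obs), arr.ind = TRUE)
  if (nrow(edges) == 0) {
    K <- matrix(0, n, n)
    return(structure(list(K_per_ns = K, K_per_frame = K,
                          stationary = pi_macro, observed_edges = obs,
                          counts = C, embeddable = NA, loglik = NA),
                     class = "rate_matrix"))
  }
  Tm_emp <- C / pmax(rowSums(C), 1)
  # initial K from the (projected) matrix logarithm of the empirical T
  K0 <- tryCatch({
    e <- eigen(Tm_emp)
    L <- Re(e$vectors %*% (log(as.complex(e$values)) * solve(e$vectors))) / lag
    L
  }, error = function(e) NULL)
  embeddable <- !is.null(K0) && all(K0[row(K0) != col(K0)] > -1e-8)
  if (is.null(K0)) K0 <- (Tm_emp - diag(n)) / lag
  # symmetric edge weights s_ij = pi_i K_ij >= 0; parameterise log s on edges
  s0 <- vapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1]; j <- edges[r, 2]
    max(0.5 * (pi_macro[i] * max(K0[i, j], 1e-8) +
               pi_macro[j] * max(K0[j, i], 1e-8)), 1e-10)
  }, numeric(1))
  build_K <- function(theta) {
    K <- matrix(0, n, n)
    s <- exp(theta)
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      K[i, j] <- s[r] / pi_macro[i]
      K[j, i] <- s[r] / pi_macro[j]
    }
    diag(K) <- -rowSums(K)
    K
  }
  negll <- function(theta) {
    K <- build_K(theta)
    P <- rev_generator_expm(K, pi_macro, lag)
    if (any(!is.finite(P)) || any(P[C > 0] <= 0)) return(1e10)
    -sum(C[C > 0] * log(P[C > 0]))
  }
  fit <- optim(log(s0), negll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  K_frame <- build_K(fit$par)
  structure(list(K_per_ns = K_frame / frame_ns, K_per_frame = K_frame,
                 stationary = pi_macro, observed_edges = obs, counts = C,
                 embeddable = embeddable, loglik = -fit$value),
            class = "rate_matrix")
}

#' Node/edge summary of the macrostate kinetic network
#'
#' @param rate A `rate_matrix`.
#' @param labels Optional macrostate labels.
#' @param kT Thermal energy for the node free energies.
#' @param rate_sd Optional matrix of bootstrap SDs for the rates.
#' @return List of data frames `nodes` (label, population, free energy) and
#'   `edges` (from, to, rate per ns, counts, observed flag); edges with no
#'   observed transitions are listed with `observed = FALSE` and `NA` rate.
#' @export
kinetic_network_summary <- function(rate, labels = NULL, kT = kT_kcal(300),
                                    rate_sd = NULL) {
  n <- nrow(rate$K_per_ns)
  if (is.null(labels)) labels <- paste0("macro", seq_len(n))
  nodes <- data.frame(label = labels, population = rate$stationary,
                      free_energy = free_energy(rate$stationary, kT))
  pairs <- which(row(diag(n)) != col(diag(n)), arr.ind = TRUE)
  edges <- data.frame(from = labels[pairs[, 1]], to = labels[pairs[, 2]],
                      rate_per_ns = ifelse(rate$observed_edges[pairs],
                                           rate$K_per_ns[pairs], NA_real_),
                      counts = rate$counts[pairs],
                      observed = rate$observed_edges[pairs])
  if (!is.null(rate_sd)) edges$rate_sd <- rate_sd[pairs]
  list(nodes = nodes, edges = edges)
}

#' Label macrostates by matching emission archetypes
#'
#' Computes the circular mean of each discriminative feature over the frames
#' assigned to each macrostate, and matches macrostates to emission-model
#' states by minimal total circular distance over all assignments.
#'
#' @param macro A `macro_model`.
#' @param features List of feature matrices.
#' @param dtrajs Matching list of microstate trajectories.
#' @param emission An `emission_model` (provides the archetype means).
#' @return Character vector: emission-state label per macrostate.
#' @export
label_macrostates <- function(macro, features, dtrajs, emission) {
  mt <- macro_dtrajs(macro, dtrajs)
  feats <- emission$discriminative
  n <- macro$n_macrostates
  ang <- do.call(rbind, lapply(features, function(f)
    unclass(f)[, feats, drop = FALSE]))
  lab <- unlist(mt)
  sig <- matrix(NA_real_, n, length(feats),
                dimnames = list(NULL, feats))
  for (k in seq_len(n)) {
    sel <- !is.na(lab) & lab == k
    a <- ang[sel, , drop = FALSE] * pi / 180
    sig[k, ] <- atan2(colMeans(sin(a)), colMeans(cos(a))) * 180 / pi
  }
  arche <- t(emission$mean[feats, , drop = FALSE])   # states x features
  circ_d <- function(a, b) abs(wrap_angle(a - b))
  states <- rownames(arche)
  # best assignment over all injective label mappings (n <= 4: enumerate)
  perms <- all_injections(length(states), n)
  best <- NULL; best_cost <- Inf
  for (p in perms) {
    cost <- sum(vapply(seq_len(n), function(k)
      sum(circ_d(sig[k, ], arche[p[k], ])), numeric(1)))
    if (cost < best_cost) { best_cost <- cost; best <- p }
  }
  states[best]
}

# All injective maps from n macrostates into m archetype states.
all_injections <- function(m, n) {
  if (n > m) stop("more macrostates than archetype states")
  combs <- utils::combn(m, n, simplify = FALSE)
  out <- list()
  for (cb in combs) {
    perm_idx <- perms_of(cb)
    out <- c(out, perm_idx)
  }
  out
}

perms_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}
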