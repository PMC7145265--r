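#' Calibrated reference kinetic model of selectivity-filter gating
#'
#' Builds the four-state (or three-state, deprotonated) continuous-time Markov
#' jump model used as ground truth by the synthetic-data generator.  States:
#' `C_oi` (both gates closed, global minimum), `C_o` (inner gate open), `O`
#' (putative open) and `U` (occluded; exists only when the external-gate
#' glutamate is protonated).  Basin free energies default to
#' \{0, 0.59, 2.55, 2.55\} kcal/mol, which places `C_o` less than 1 kcal/mol
#' above `C_oi`, puts `O` and `U` in the 2-3 kcal/mol band, and gives the `O`
#' and `U` states equilibrium populations of about 1\%.
#'
#' Forward rates follow an Arrhenius law `k = nu * exp(-dG_barrier / kT)` with
#' the barrier measured from the origin basin's minimum; reverse rates are
#' fixed by detailed balance, so the stationary distribution of the generator
#' is exactly the Boltzmann distribution of the basin free energies.
#' Attempt prefactors are per process: the backbone rotation
#' (`C_oi -> C_o`) uses `nu = 1` per unit time while the side-chain rotamer
#' flips (`C_o -> O`, `C_o -> U`) default to `nu = 50`, reflecting the faster
#' attempt frequency of a rotamer flip relative to a collective backbone
#' rearrangement; this ordering makes the backbone exchange the slowest
#' relaxation, as observed for the real channel.
#'
#' Under the protonated condition, small direct `U -> C_oi` and `U -> O`
#' escape edges are added (with reverse rates again from detailed balance), so
#' that `U` may transition forward to any other state.
#'
#' @param protonated Logical; include the `U` state and its edges?
#' @param temperature Temperature in kelvin (> 0).
#' @param free_energies Named numeric, kcal/mol per state; minimum must be 0.
#' @param barriers Named numeric, kcal/mol per forward edge
#'   (`"C_oi->C_o"`, `"C_o->O"`, `"C_o->U"`), measured from the origin basin.
#' @param prefactors Named numeric attempt frequencies per unit time for the
#'   same edges.
#' @param u_escape_rates Named numeric rates per unit time for the small
#'   direct `U->C_oi` and `U->O` edges (protonated only).
#' @return An object of class `ref_kinetic_model` with elements
#'   `state_labels`, `free_energies`, `barriers`, `rate_matrix` (generator K,
#'   rows sum to 0), `stationary` (Boltzmann weights), `temperature`, `kT`,
#'   `protonated`.
#' @examples
#' m <- build_reference_model(protonated = TRUE)
#' round(m$stationary, 4)  # ~ (0.715, 0.266, 0.010, 0.010)
#' @export
build_reference_model <- function(protonated = TRUE, temperature = 300,
    free_energies = c(C_oi = 0, C_o = 0.59, O = 2.55, U = 2.55),
    barriers = c("C_oi->C_o" = 2.0, "C_o->O" = 4.5, "C_o->U" = 5.0),
    prefactors = c("C_oi->C_o" = 1, "C_o->O" = 50, "C_o->U" = 50),
    u_escape_rates = c("U->C_oi" = 0.002, "U->O" = 0.002)) {
  if (!is.numeric(temperature) || length(temperature) != 1 || temperature <= 0)
    stop("temperature must be a positive scalar (kelvin)")
  kT <- kT_kcal(temperature)

  labels <- c("C_oi", "C_o", "O", "U")
  if (!protonated) {
    labels <- setdiff(labels, "U")
    free_energies <- free_energies[labels]
    barriers <- barriers[!grepl("U", names(barriers))]
  }
  if (!all(labels %in% names(free_energies)))
    stop("free_energies must name every state")
  G <- free_energies[labels]
  if (abs(min(G)) > 1e-12) stop("minimum free energy must be 0")

  n <- length(labels)
  K <- matrix(0, n, n, dimnames = list(labels, labels))
  edges <- strsplit(names(barriers), "->", fixed = TRUE)
  for (i in seq_along(barriers)) {
    from <- edges[[i]][1]; to <- edges[[i]][2]
    dG <- G[to] - G[from]
    if (barriers[i] < dG - 1e-12)
      stop(sprintf("barrier %s (%.3g) is below the free-energy difference (%.3g)",
                   names(barriers)[i], barriers[i], dG))
    nu <- prefactors[names(barriers)[i]]
    if (is.na(nu)) nu <- 1
    ts_energy <- G[from] + barriers[i]            # transition-state energy
    K[from, to] <- nu * exp(-barriers[i] / kT)
    K[to, from] <- nu * exp(-(ts_energy - G[to]) / kT)
  }
  if (protonated) {
    for (nm in names(u_escape_rates)) {
      e <- strsplit(nm, "->", fixed = TRUE)[[1]]
      from <- e[1]; to <- e[2]
      k <- u_escape_rates[[nm]]
      K[from, to] <- K[from, to] + k
      # reverse by detailed balance: pi_from k = pi_to k_rev
      K[to, from] <- K[to, from] + k * exp(-(G[from] - G[to]) / kT)
    }
  }
  diag(K) <- 0
  diag(K) <- -rowSums(K)

  pi_boltz <- exp(-G / kT); pi_boltz <- pi_boltz / sum(pi_boltz)
  res <- detailed_balance_residual(K, pi_boltz)
  stopifnot(res < 1e-12)

  structure(list(state_labels = labels, free_energies = G,
                 barriers = barriers, prefactors = prefactors,
                 rate_matrix = K, stationary = pi_boltz,
                 temperature = temperature, kT = kT,
                 protonated = protonated),
            class = "ref_kinetic_model")
}

#' Detailed-balance residual of a generator or transition matrix
#'
#' @param M Square matrix (generator K or transition matrix T).
#' @param pi Stationary distribution.
#' @return `max | pi_i M_ij - pi_j M_ji |` over off-diagonal pairs.
#' @export
detailed_balance_residual <- function(M, pi) {
  F <- pi * M            # recycles pi down columns: F_ij = pi_i M_ij
  D <- abs(F - t(F))
  diag(D) <- 0
  max(D)
}

#' Stationary distribution of a generator matrix
#'
#' Leading left null vector of K (solves pi K = 0, sum(pi) = 1).
#'
#' @param K Generator matrix (rows sum to 0).
#' @return Stationary probability vector.
#' @export
ctmc_stationary <- function(K) {
  e <- eigen(t(K))
  i <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, i]))
  setNames(v / sum(v), rownames(K))
}

#' @export
print.ref_kinetic_model <- function(x, ...) {
  cat(sprintf("Reference kinetic model (%s), %d states at %g K\n",
              if (x$protonated) "protonated" else "deprotonated",
              length(x$state_labels), x$temperature))
  cat("  stationary:", paste(sprintf("%s=%.4f", x$state_labels, x$stationary),
                             collapse = " "), "\n")
  invisible(x)
}

#' Sample discrete state paths from a continuous-time Markov chain
#'
#' Exact Gillespie jump simulation discretised onto a regular time grid (no
#' time-step bias in rare transitions).  Each path starts from the stationary
#' distribution.
#'
#' @param model A `ref_kinetic_model` (or a list with `rate_matrix` and
#'   `stationary`).
#' @param n_traj Number of independent trajectories.
#' @param n_steps Frames per trajectory.
#' @param dt Grid spacing in model time units; must satisfy
#'   `max |K_ii| * dt <= 0.1`.
#' @param seed Integer RNG seed (required; no global state is consumed).
#' @return List of integer vectors of 1-based state indices, with
#'   `attr(,"state_labels")` and `attr(,"dt")` set on the list.
#' @export
sample_ctmc <- function(model, n_traj, n_steps, dt = 0.1, seed) {
  K <- model$rate_matrix
  bound <- 0.1 / max(abs(diag(K)))
  if (dt > bound + 1e-12)
    stop(sprintf(paste0("dt = %g too coarse: max|K_ii| * dt must be <= 0.1, ",
                        "requiring dt <= %.4g"), dt, bound))
  out <- with_seed(seed,
    lapply(seq_len(n_traj), function(j)
      gillespie_path(K, model$stationary, as.integer(n_steps), dt)))
  attr(out, "state_labels") <- model$state_labels
  attr(out, "dt") <- dt
  out
}
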