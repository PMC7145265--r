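#' One-dimensional free-energy profile from (weighted) samples
#'
#' Histograms the coordinate into `bins` equal-width bins, applies Boltzmann
#' inversion `F = -kT ln(w)` to the (weighted) bin masses, and shifts the
#' minimum to 0.  Bins whose raw sample count falls below `count_floor` are
#' flagged as unsampled, never interpolated silently.
#'
#' @param x Numeric coordinate samples (e.g. a tIC projection, or a Langevin
#'   trajectory).
#' @param weights Optional per-sample weights (e.g. MSM frame weights).
#' @param kT Thermal energy (kcal/mol).
#' @param bins Number of bins (default 72).
#' @param count_floor Minimum raw count for a bin to be considered sampled.
#' @param range Optional coordinate range (default: data range).
#' @return Object of class `free_energy_profile`: data frame `profile`
#'   (`mid`, `free_energy`, `count`, `sampled`) plus `kT`, `bin_width`.
#' @export
free_energy_profile <- function(x, weights = NULL, kT = kT_kcal(300),
                                bins = 72, count_floor = 10, range = NULL) {
  stopifnot(length(x) > 0, bins >= 4)
  if (is.null(weights)) weights <- rep(1, length(x))
  stopifnot(length(weights) == length(x))
  if (is.null(range)) range <- base::range(x)
  br <- seq(range[1], range[2], length.out = bins + 1)
  bin <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  w <- vapply(seq_len(bins), function(b) sum(weights[bin == b]), numeric(1))
  cnt <- tabulate(bin, nbins = bins)
  Fv <- ifelse(w > 0, -kT * log(w), Inf)
  Fv <- Fv - min(Fv[cnt >= count_floor], na.rm = TRUE)
  structure(list(profile = data.frame(mid = (br[-1] + br[-(bins + 1)]) / 2,
                                      free_energy = Fv, count = cnt,
                                      sampled = cnt >= count_floor),
                 kT = kT, bin_width = diff(br)[1]),
            class = "free_energy_profile")
}

# Local minima of a profile restricted to sampled bins, filtered by
# topographic prominence (the smaller of the rises separating the minimum
# from lower terrain on either side) and sorted by depth.  The prominence
# floor suppresses counting-noise wiggles.
profile_minima <- function(fep, prominence = 0.5) {
  p <- fep$profile[fep$profile$sampled, ]
  f <- p$free_energy
  n <- length(f)
  if (n < 3) return(p[integer(0), ])
  is_min <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) f[i - 1] else Inf
    right <- if (i < n) f[i + 1] else Inf
    f[i] <= left && f[i] <= right && (f[i] < left || f[i] < right)
  }, logical(1))
  prom <- function(i) {
    rise_side <- function(idx_seq) {
      if (!length(idx_seq)) return(Inf)      # profile edge acts as a wall
      top <- -Inf
      for (j in idx_seq) {
        top <- max(top, f[j])
        if (f[j] < f[i]) break
      }
      top - f[i]
    }
    left_idx <- if (i > 1) rev(seq_len(i - 1)) else integer(0)
    right_idx <- if (i < n) seq(i + 1, n) else integer(0)
    min(rise_side(left_idx), rise_side(right_idx))
  }
  keep <- which(is_min)
  if (length(keep) > 1) {
    pr <- vapply(keep, function(i) {
      if (f[i] <= min(f)) Inf else prom(i)
    }, numeric(1))
    keep <- keep[pr >= prominence]
  }
  mins <- p[keep, ]
  mins[order(mins$free_energy), ]
}

#' Barrier height between two basins of a 1-D free-energy profile
#'
#' Finds the basin minima (the two deepest local minima of the sampled
#' profile unless positions are supplied), and reports the maximum profile
#' value on the path between them minus the origin-basin minimum — i.e. the
#' barrier measured from the origin basin.  Unsampled bins between the basins
#' raise an error ("unsampled" gap) rather than being bridged.
#'
#' @param fep A `free_energy_profile`.
#' @param from,to Optional approximate basin positions; the nearest local
#'   minima are used.  By default `from` is the deeper (global) basin.
#' @return List: `barrier` (kcal/mol), `from_min`, `to_min`, `top` (positions
#'   and energies).
#' @export
profile_barrier <- function(fep, from = NULL, to = NULL) {
  mins <- profile_minima(fep)
  if (nrow(mins) < 2)
    stop("no barrier: profile has fewer than two basins")
  pick <- function(target, default_row) {
    if (is.null(target)) return(mins[default_row, ])
    mins[which.min(abs(mins$mid - target)), ]
  }
  a <- pick(from, 1)
  b <- pick(to, 2)
  if (a$mid == b$mid) b <- mins[which(mins$mid != a$mid)[1], ]
  lo <- min(a$mid, b$mid); hi <- max(a$mid, b$mid)
  span <- fep$profile[fep$profile$mid >= lo & fep$profile$mid <= hi, ]
  if (any(!span$sampled))
    stop("unsampled bins between the basins; cannot measure the barrier")
  i_top <- which.max(span$free_energy)
  list(barrier = span$free_energy[i_top] - a$free_energy,
       from_min = c(mid = a$mid, free_energy = a$free_energy),
       to_min = c(mid = b$mid, free_energy = b$free_energy),
       top = c(mid = span$mid[i_top], free_energy = span$free_energy[i_top]))
}

#' Per-frame MSM weights for landscape reweighting
#'
#' Weight of a frame in microstate s is `pi_s / count(s)`, so every
#' microstate contributes its stationary probability regardless of how often
#' it was sampled.
#'
#' @param msm An `msm_model`.
#' @param dtrajs List of integer microstate trajectories (original indices).
#' @return List of numeric weight vectors matching `dtrajs`; frames outside
#'   the active set get weight 0.
#' @export
frame_weights <- function(msm, dtrajs) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  all_states <- unlist(dtrajs)
  counts <- tabulate(all_states, nbins = length(msm$mapping))
  w_state <- rep(0, length(msm$mapping))
  ok <- !is.na(msm$mapping)
  w_state[ok] <- msm$stationary[msm$mapping[ok]] / pmax(counts[ok], 1)
  lapply(dtrajs, function(d) w_state[d])
}

#' MSM-weighted free-energy profile along a projected coordinate
#'
#' Convenience wrapper: computes frame weights from the MSM and histograms
#' the chosen tICA component.  Bootstrap error bands are attached when a
#' bootstrap ensemble is given (SD of per-bin free energies across models).
#'
#' @param projections List of projection matrices (frames x tICs).
#' @param dtrajs Matching list of microstate trajectories.
#' @param msm An `msm_model`.
#' @param component Which tIC column to project onto.
#' @param kT Thermal energy (kcal/mol).
#' @param bins Number of bins.
#' @param bootstrap Optional `msm_bootstrap` for error bands.
#' @return A `free_energy_profile` (with an `error` column when bootstrapped).
#' @export
project_free_energy <- function(projections, dtrajs, msm, component = 1,
                                kT = kT_kcal(300), bins = 72,
                                bootstrap = NULL) {
  if (is.matrix(projections)) projections <- list(projections)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  x <- unlist(lapply(projections, function(p) p[, component]))
  w <- unlist(frame_weights(msm, dtrajs))
  fep <- free_energy_profile(x, weights = w, kT = kT, bins = bins)
  if (!is.null(bootstrap)) {
    rng <- base::range(x)
    Fb <- vapply(bootstrap$models, function(m) {
      wb <- unlist(frame_weights(m, dtrajs))
      free_energy_profile(x, weights = wb, kT = kT, bins = bins,
                          range = rng)$profile$free_energy
    }, numeric(bins))
    fep$profile$error <- apply(Fb, 1, function(v) sd(v[is.finite(v)]))
  }
  fep
}
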