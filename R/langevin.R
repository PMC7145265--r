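#' Tilted quartic double-well potential
#'
#' `U(x) = a4 x^4 + a2 x^2 + a1 x`, shifted so the deeper minimum is at 0.
#' With `a4 = h`, `a2 = -2h`, `a1 = 0` this is the symmetric double well
#' `h (x^2-1)^2 - h` with barrier exactly `h` kcal/mol from either basin.
#' Critical points are the real roots of the cubic `4 a4 x^3 + 2 a2 x + a1`,
#' so the barrier and the well offset are recoverable in closed form from the
#' coefficients (see [well_geometry()]).
#'
#' @param a4,a2,a1 Quartic, quadratic and linear coefficients (kcal/mol).
#' @return Object of class `well_potential` with `coef`, and the analytic
#'   `minima`, `saddle`, `barrier_left` / `barrier_right` (kcal/mol, measured
#'   from each basin) and `offset` (right-minus-left basin energy).
#' @export
double_well <- function(a4, a2, a1 = 0) {
  stopifnot(a4 > 0, a2 < 0)
  g <- well_geometry(c(a4 = a4, a2 = a2, a1 = a1))
  structure(c(list(coef = c(a4 = a4, a2 = a2, a1 = a1)), g),
            class = "well_potential")
}

#' Critical-point geometry of a tilted quartic
#'
#' Solves `U'(x) = 0` exactly (cubic, via [polyroot()]) and reports the two
#' minima, the saddle, the barrier from each basin and the basin offset.
#'
#' @param coef Named numeric `c(a4=, a2=, a1=)`.
#' @return List with `minima` (x-positions, left then right), `saddle`,
#'   `barrier_left`, `barrier_right`, `offset`.
#' @export
well_geometry <- function(coef) {
  a4 <- coef[["a4"]]; a2 <- coef[["a2"]]; a1 <- coef[["a1"]]
  U <- function(x) a4 * x^4 + a2 * x^2 + a1 * x
  r <- polyroot(c(a1, 2 * a2, 0, 4 * a4))
  x <- sort(Re(r[abs(Im(r)) < 1e-8 * (1 + abs(Re(r)))]))
  if (length(x) != 3)
    stop("potential is not a double well (fewer than 3 real critical points)")
  xmin <- x[c(1, 3)]; xts <- x[2]
  list(minima = xmin, saddle = xts,
       barrier_left = U(xts) - U(xmin[1]),
       barrier_right = U(xts) - U(xmin[2]),
       offset = U(xmin[2]) - U(xmin[1]))
}

#' Calibrate a tilted quartic to a target barrier and basin offset
#'
#' Deterministic least-squares on the closed-form barrier/offset of
#' [well_geometry()]; the returned potential has the requested barrier from
#' the deeper (left) basin and basin offset to numerical precision.
#'
#' @param barrier Target barrier from the left basin (kcal/mol).
#' @param offset Target right-minus-left basin energy (kcal/mol, >= 0).
#' @return A `well_potential`.
#' @examples
#' w <- calibrate_double_well(2.0)         # symmetric, barrier exactly 2
#' w$barrier_left
#' @export
calibrate_double_well <- function(barrier, offset = 0) {
  stopifnot(barrier > 0, offset >= 0, barrier > offset)
  if (offset == 0) return(double_well(a4 = barrier, a2 = -2 * barrier))
  # nested exact solves on the closed-form geometry: the barrier from the
  # left basin is monotone in the quartic scale h for fixed tilt s (> 0,
  # which raises the right well), and the basin offset is monotone in s.
  geom <- function(h, s) tryCatch(
    well_geometry(c(a4 = h, a2 = -2 * h, a1 = s)),
    error = function(e) NULL)
  h_for <- function(s) {
    f <- function(h) {
      g <- geom(h, s)
      if (is.null(g)) return(barrier)       # push away from degenerate wells
      g$barrier_left - barrier
    }
    tryCatch(uniroot(f, c(abs(s) * 0.8 + 1e-6, barrier * 4),
                     tol = 1e-12)$root,
             error = function(e) NA_real_)
  }
  off_err <- function(s) {
    h <- h_for(s)
    if (is.na(h)) return(offset)  # tilt too strong: wells merged, overshoot
    geom(h, s)$offset - offset
  }
  s_star <- uniroot(off_err, c(1e-8, barrier * 0.95), tol = 1e-12)$root
  h_star <- h_for(s_star)
  w <- double_well(a4 = h_star, a2 = -2 * h_star, a1 = s_star)
  if (abs(w$barrier_left - barrier) > 1e-6 || abs(w$offset - offset) > 1e-6)
    stop("double-well calibration did not converge")
  w
}

#' Specification of an overdamped Langevin run
#'
#' @param potential A `well_potential`.
#' @param diffusion Diffusion coefficient D (length^2 per time).
#' @param dt Time step.
#' @param n_steps Number of recorded steps.
#' @param kT Thermal energy (kcal/mol).
#' @param seed Integer RNG seed.
#' @return Object of class `langevin_spec`.
#' @export
langevin_spec <- function(potential, diffusion = 1, dt = 1e-3, n_steps = 1e6,
                          kT = kT_kcal(300), seed = 1) {
  stopifnot(inherits(potential, "well_potential"), diffusion >= 0, dt > 0,
            n_steps >= 1, kT > 0)
  structure(list(potential = potential, diffusion = diffusion, dt = dt,
                 n_steps = as.integer(n_steps), kT = kT, seed = seed),
            class = "langevin_spec")
}

# Maximum curvature |U''| over the critical points, used for the stability
# bound dt * D * max|U''| / kT <= 0.2 of the Euler-Maruyama integrator.
max_curvature <- function(potential) {
  cf <- potential$coef
  xs <- c(potential$minima, potential$saddle)
  xs <- xs[!is.na(xs)]
  max(abs(12 * cf[["a4"]] * xs^2 + 2 * cf[["a2"]]))
}

#' Harmonic well potential
#'
#' `U(x) = (kappa/2) (x - center)^2` as a `well_potential`, for validating
#' the Langevin sampler against the closed-form Gaussian stationary law
#' (variance `kT / kappa`).
#'
#' @param kappa Force constant (kcal/mol per length^2).
#' @param center Minimum position.
#' @return A `well_potential` with a single minimum and no saddle.
#' @export
harmonic_well <- function(kappa, center = 0) {
  stopifnot(kappa > 0)
  structure(list(coef = c(a4 = 0, a2 = kappa / 2, a1 = -kappa * center),
                 minima = center, saddle = NA_real_,
                 barrier_left = NA_real_, barrier_right = NA_real_,
                 offset = NA_real_),
            class = "well_potential")
}

#' Recover a barrier height from a Langevin free-energy surrogate
#'
#' Calibrates a tilted quartic double well to the requested barrier (from the
#' origin basin) and basin offset, samples an overdamped Euler-Maruyama
#' trajectory started in the origin basin, histograms it into `bins` bins,
#' applies Boltzmann inversion and reads the barrier as the maximum of the
#' profile between the two basin minima minus the origin-basin minimum —
#' the same read-out used for landscape barriers along a slow coordinate.
#'
#' @param barrier Target barrier (kcal/mol, from the origin basin).
#' @param offset Basin free-energy offset (kcal/mol).
#' @param n_steps Euler-Maruyama steps.
#' @param seed Integer RNG seed.
#' @param bins Histogram bins (default 72).
#' @param kT Thermal energy (kcal/mol).
#' @param diffusion Diffusion coefficient.
#' @param dt Time step; default 90% of the stability bound.
#' @return List: `barrier_true` (analytic), `barrier_est` (recovered),
#'   `profile` (the `free_energy_profile`), `potential`.
#' @export
langevin_barrier_recovery <- function(barrier, offset = 0, n_steps = 1e6,
                                      seed = 1, bins = 72, kT = kT_kcal(300),
                                      diffusion = 1, dt = NULL) {
  w <- calibrate_double_well(barrier, offset)
  if (is.null(dt)) dt <- 0.9 * 0.2 * kT / (diffusion * max_curvature(w))
  spec <- langevin_spec(w, diffusion = diffusion, dt = dt, n_steps = n_steps,
                        kT = kT, seed = seed)
  x <- sample_langevin(spec, x0 = w$minima[1])
  fep <- free_energy_profile(x, kT = kT, bins = bins)
  bar <- profile_barrier(fep, from = w$minima[1], to = w$minima[2])
  list(barrier_true = w$barrier_left, barrier_est = bar$barrier,
       profile = fep, potential = w)
}

#' Sample an overdamped Langevin trajectory
#'
#' Euler-Maruyama integration of `dx = -(D/kT) U'(x) dt + sqrt(2 D dt) eta`;
#' the stationary law is Boltzmann, `p(x) ~ exp(-U(x)/kT)`.  The initial
#' point is drawn from the Boltzmann distribution on a fine grid (or fixed
#' via `x0`).  Refuses time steps violating the stability bound
#' `dt * D * max|U''| / kT <= 0.2`.
#'
#' @param spec A `langevin_spec`.
#' @param x0 Optional fixed initial position.
#' @return Numeric trajectory of length `n_steps`, with the spec attached as
#'   `attr(,"spec")`.
#' @export
sample_langevin <- function(spec, x0 = NULL) {
  pot <- spec$potential; cf <- pot$coef
  if (spec$diffusion > 0) {
    bound <- 0.2 * spec$kT / (spec$diffusion * max_curvature(pot))
    if (spec$dt > bound)
      stop(sprintf(paste0("unstable time step: dt = %g exceeds the stability ",
                          "bound 0.2*kT/(D*max|U''|) = %.3g"), spec$dt, bound))
  }
  with_seed(spec$seed, {
    if (is.null(x0)) {
      span <- max(diff(range(pot$minima)), 1)
      xs <- seq(pot$minima[1] - span, pot$minima[2] + span, length.out = 4096)
      w <- exp(-(cf[["a4"]] * xs^4 + cf[["a2"]] * xs^2 + cf[["a1"]] * xs) / spec$kT)
      x0 <- sample(xs, 1, prob = w)
    }
    x <- langevin_path(x0, cf[["a4"]], cf[["a2"]], cf[["a1"]],
                       spec$diffusion, spec$kT, spec$dt, spec$n_steps)
    attr(x, "spec") <- spec
    x
  })
}
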