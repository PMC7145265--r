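#' Von Mises random deviates
#'
#' Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler,
#' vectorised.  `kappa = Inf` gives a point mass at the mean; `kappa = 0`
#' the circular uniform distribution.
#'
#' @param n Number of deviates.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration (>= 0, may be `Inf`).
#' @return Angles in degrees, wrapped to `[-180, 180)`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(wrap_angle(mu), n))
  if (kappa <= 0) return(wrap_angle(runif(n, -180, 180)))
  mu_rad <- mu * pi / 180
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- ceiling((n - got) / 0.55) + 8L
    z <- cos(pi * runif(m))
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- runif(m)
    acc <- (cc * (2 - cc) - u2 > 0) | (cc > 0 & log(cc / u2) + 1 - cc >= 0)
    f <- f[acc]
    k <- min(length(f), n - got)
    if (k > 0) {
      u3 <- runif(k)
      th <- ifelse(u3 > 0.5, 1, -1) * acos(pmin(pmax(f[seq_len(k)], -1), 1))
      out[(got + 1):(got + k)] <- th + mu_rad
      got <- got + k
    }
  }
  wrap_angle(out * 180 / pi)
}

# One exact-Gillespie CTMC path discretised onto a dt grid; frame k records
# the state occupied at time (k-1)*dt.  Consumes the current RNG stream.
gillespie_path <- function(K, pi0, n_steps, dt) {
  n <- nrow(K)
  rates <- -diag(K)
  s <- sample.int(n, 1, prob = pi0)
  out <- integer(n_steps)
  filled <- 0L
  t <- 0
  repeat {
    t_next <- if (rates[s] > 0) t + rexp(1, rates[s]) else Inf
    # frames with (k-1)*dt < t_next still see state s
    k_hi <- if (is.infinite(t_next)) n_steps
            else min(n_steps, floor(t_next / dt - 1e-12) + 1L)
    if (k_hi > filled) {
      out[(filled + 1L):k_hi] <- s
      filled <- k_hi
    }
    if (filled >= n_steps) break
    p <- K[s, ]
    p[s] <- 0
    s <- sample.int(n, 1, prob = p)
    t <- t_next
  }
  out
}

# Euler-Maruyama on U(x) = a4 x^4 + a2 x^2 + a1 x with pre-drawn noise.
langevin_path <- function(x0, a4, a2, a1, D, kT, dt, n_steps) {
  out <- numeric(n_steps)
  x <- x0
  c1 <- D / kT * dt
  noise <- rnorm(n_steps) * sqrt(2 * D * dt)
  for (k in seq_len(n_steps)) {
    out[k] <- x
    x <- x - c1 * (4 * a4 * x^3 + 2 * a2 * x + a1) + noise[k]
  }
  out
}
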