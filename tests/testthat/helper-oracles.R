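# Independent oracles used across the suite.  Each re-derives a quantity by a
# different route than the implementation under test.

# Dihedral via the one-line atan2 form
# atan2(|b2| * b1 . (b2 x b3), (b1 x b2) . (b2 x b3)).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  y <- sqrt(sum(b2^2)) * sum(b1 * cr(b2, b3))
  x <- sum(cr(b1, b2) * cr(b2, b3))
  ang <- atan2(y, x) * 180 / pi
  ((ang + 180) %% 360) - 180
}

# Strongly connected components by brute-force reachability (matrix powers).
oracle_scc_largest <- function(counts) {
  n <- nrow(counts)
  A <- (counts > 0) | diag(n) > 0
  R <- A
  for (i in seq_len(n)) R <- (R %*% A + R) > 0     # transitive closure
  comp <- integer(n)
  cid <- 0
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cid <- cid + 1
    comp[R[i, ] & R[, i]] <- cid
  }
  tab <- vapply(seq_len(cid), function(cc) {
    m <- which(comp == cc)
    c(sum(counts[m, m, drop = FALSE]), length(m), -min(m))
  }, numeric(3))
  ord <- order(tab[1, ], tab[2, ], tab[3, ], decreasing = TRUE)
  sort(which(comp == ord[1]))
}

# Reversible-MLE oracle: direct numerical maximisation of the transition
# likelihood over symmetric edge weights (log-parameterised upper triangle
# plus diagonal), for small n.
oracle_reversible_mle <- function(C) {
  n <- nrow(C)
  iu <- which(upper.tri(C, diag = TRUE), arr.ind = TRUE)
  make_T <- function(theta) {
    x <- matrix(0, n, n)
    x[iu] <- exp(theta)
    x <- x + t(x) - diag(diag(x))
    Tm <- x / rowSums(x)
    list(T = Tm, pi = rowSums(x) / sum(x))
  }
  negll <- function(theta) {
    Tm <- make_T(theta)$T
    if (any(Tm[C > 0] <= 0)) return(1e10)
    -sum(C[C > 0] * log(Tm[C > 0]))
  }
  theta0 <- log(pmax((C + t(C))[iu], 0.5))
  fit <- optim(theta0, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  make_T(fit$par)
}

# Random 3-D rotation matrix.
random_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Circular mean in degrees.
circ_mean <- function(deg) {
  r <- deg * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}
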