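# Orthonormal basis perpendicular to a direction vector.
plane_basis <- function(d) {
  d <- d / sqrt(sum(d^2))
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  list(u = u, v = v, d = d)
}

# Clearance radius (distance to nearest atom surface) for a set of candidate
# centres; xyz is the atom coordinate matrix, R the atom radii.
clearance <- function(pts, xyz, R) {
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * pts %*% t(xyz)
  sqrt(pmax(d2, 0)) - matrix(R, nrow(pts), length(R), byrow = TRUE)
}

#' Pore-radius profile along a conduction pathway
#'
#' At each arc-length position s along the pathway, reports the radius of the
#' largest sphere that can be centred in the plane perpendicular to the path
#' without overlapping any atom: `r(s) = max_p min_i (|p - x_i| - R_i)`,
#' maximised over in-plane centre positions p by a coarse grid search
#' followed by iterative grid refinement.  The search is confined to a disk
#' of radius `max_search`; an optimum on the disk boundary is flagged
#' `open_funnel`.  Negative radii (an atom blocks the slice) are flagged
#' impassable.
#'
#' The pathway may be a straight axis or a polyline; two polylines sharing an
#' origin reproduce the extracellular/intracellular half-profiles used for
#' channel pores, with s measured signed from the shared reference point.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` and `radius` (or a
#'   `pore_fixture`).
#' @param path Two-row matrix (start and end point, straight path) or an
#'   n x 3 polyline matrix.
#' @param step Spacing of profile samples along the path (angstrom).
#' @param max_search Maximum in-plane displacement of the sphere centre.
#' @param grid Coarse in-plane grid spacing.
#' @param refine_tol Final in-plane resolution of the refinement.
#' @param origin Arc length is reported relative to the path point nearest
#'   this reference (default: the path start).
#' @return Object of class `pore_profile`: data frame `profile` with columns
#'   `s`, `radius`, `impassable`, `open_funnel`, plus `bottleneck`
#'   (`s`, `radius` at the global minimum over passable slices).
#' @export
pore_profile <- function(atoms, path, step = 0.5, max_search = 3,
                         grid = 0.25, refine_tol = 0.01, origin = NULL) {
  if (inherits(atoms, "pore_fixture")) atoms <- atoms$atoms
  stopifnot(nrow(atoms) >= 4, step > 0)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atoms$radius
  path <- as.matrix(path)
  seg <- diff(path)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  ss <- seq(0, total, by = step)
  point_at <- function(s) {
    k <- max(which(cum <= s + 1e-12)); k <- min(k, nrow(seg))
    t <- (s - cum[k]) / seg_len[k]
    list(p = path[k, ] + t * seg[k, ], d = seg[k, ] / seg_len[k])
  }
  s0 <- 0
  if (!is.null(origin)) {
    d_to_origin <- vapply(ss, function(s)
      sum((point_at(s)$p - origin)^2), numeric(1))
    s0 <- ss[which.min(d_to_origin)]
  }
  res <- lapply(ss, function(s) {
    pa <- point_at(s)
    b <- plane_basis(pa$d)
    h <- grid
    center <- c(0, 0)
    best <- NULL
    half <- max_search
    repeat {
      gx <- seq(-half, half, by = h)
      gg <- expand.grid(a = gx + center[1], b = gx + center[2])
      keep <- gg$a^2 + gg$b^2 <= max_search^2 + 1e-9
      gg <- gg[keep, , drop = FALSE]
      pts <- cbind(pa$p[1] + gg$a * b$u[1] + gg$b * b$v[1],
                   pa$p[2] + gg$a * b$u[2] + gg$b * b$v[2],
                   pa$p[3] + gg$a * b$u[3] + gg$b * b$v[3])
      cl <- clearance(pts, xyz, R)
      rmin <- apply(cl, 1, min)
      i <- which.max(rmin)
      best <- list(r = rmin[i], a = gg$a[i], b = gg$b[i])
      if (h <= refine_tol) break
      center <- c(best$a, best$b)
      half <- 2 * h
      h <- h / 4
    }
    on_boundary <- best$a^2 + best$b^2 >= (max_search - 2 * refine_tol)^2
    c(radius = best$r, open_funnel = as.numeric(on_boundary))
  })
  prof <- data.frame(s = ss - s0,
                     radius = vapply(res, `[[`, numeric(1), "radius"),
                     open_funnel = vapply(res, `[[`, numeric(1),
                                          "open_funnel") > 0)
  prof$impassable <- prof$radius <= 0
  pass <- prof[!prof$impassable & !prof$open_funnel, ]
  bott <- if (nrow(pass)) pass[which.min(pass$radius), c("s", "radius")]
          else data.frame(s = NA_real_, radius = NA_real_)
  structure(list(profile = prof,
                 bottleneck = c(s = bott$s[1], radius = bott$radius[1]),
                 step = step),
            class = "pore_profile")
}

#' Length of pathway narrower than a threshold radius
#'
#' Computes, on the profile's s-grid with linear interpolation at threshold
#' crossings, the total and the longest contiguous arc length over which the
#' pore radius is below `threshold` (e.g. the ~1.8-angstrom radius of a
#' chloride ion).  Impassable slices count as below threshold.
#'
#' @param profile A `pore_profile` (or its `profile` data frame).
#' @param threshold Radius threshold in angstrom.
#' @return List with `total` and `longest` lengths (angstrom) and the
#'   `segments` data frame (`s_start`, `s_end`).
#' @export
subthreshold_extent <- function(profile, threshold = 1.8) {
  p <- if (inherits(profile, "pore_profile")) profile$profile else profile
  stopifnot(nrow(p) > 0)
  s <- p$s; r <- p$radius
  below <- r < threshold
  segs <- list()
  i <- 1; n <- length(s)
  cross <- function(i1, i2) {   # interpolated s where r crosses threshold
    s[i1] + (threshold - r[i1]) * (s[i2] - s[i1]) / (r[i2] - r[i1])
  }
  while (i <= n) {
    if (!below[i]) { i <- i + 1; next }
    j <- i
    while (j < n && below[j + 1]) j <- j + 1
    s_start <- if (i == 1) s[1] else cross(i - 1, i)
    s_end <- if (j == n) s[n] else cross(j, j + 1)
    segs[[length(segs) + 1]] <- c(s_start, s_end)
    i <- j + 1
  }
  if (!length(segs))
    return(list(total = 0, longest = 0,
                segments = data.frame(s_start = numeric(0),
                                      s_end = numeric(0))))
  m <- do.call(rbind, segs)
  lens <- m[, 2] - m[, 1]
  list(total = sum(lens), longest = max(lens),
       segments = data.frame(s_start = m[, 1], s_end = m[, 2]))
}

#' Sample conformations from a macrostate under the MSM
#'
#' Draws microstates proportionally to the stationary distribution restricted
#' to the macrostate, then frames uniformly within each microstate.
#'
#' @param msm An `msm_model`.
#' @param macro A `macro_model`.
#' @param frame_index List mapping each microstate (original index) to the
#'   frame identifiers it contains (any vector type).
#' @param state Macrostate index (or label, if `labels` given).
#' @param n Number of conformations (default 1000).
#' @param seed Integer RNG seed.
#' @param labels Optional macrostate labels for name lookup.
#' @return Vector of `n` sampled frame identifiers.
#' @export
sample_macrostate_ensemble <- function(msm, macro, frame_index, state,
                                       n = 1000, seed = 1, labels = NULL) {
  if (is.character(state)) {
    stopifnot(!is.null(labels))
    state <- match(state, labels)
  }
  members_active <- which(macro$crisp == state)
  if (!length(members_active)) stop("empty macrostate")
  members <- msm$active[members_active]
  pi_m <- msm$stationary[members_active]
  has_frames <- vapply(members, function(s)
    length(frame_index[[s]]) > 0, logical(1))
  members <- members[has_frames]; pi_m <- pi_m[has_frames]
  if (!length(members)) stop("empty macrostate: no frames indexed")
  with_seed(seed, {
    micro <- members[sample.int(length(members), n, replace = TRUE,
                                prob = pi_m)]
    vapply(micro, function(s) {
      fr <- frame_index[[s]]
      fr[sample.int(length(fr), 1)]
    }, frame_index[[members[1]]][1])
  })
}

#' Binding-site occupancy table
#'
#' For each macrostate ensemble, the empirical frequency with which each
#' binding site holds at least one ion: the fraction of conformations with an
#' ion centre inside the site sphere.
#'
#' @param ensembles Named list (per state) of lists of ion-coordinate
#'   matrices (possibly 0-row), e.g. from [make_ion_fixture()].
#' @param sites Named 3-column matrix of site centres.
#' @param site_radius Site sphere radius (angstrom), scalar or per site.
#' @return Matrix of frequencies, states x sites.
#' @export
occupancy_table <- function(ensembles, sites, site_radius = 2.5) {
  stopifnot(is.matrix(sites), ncol(sites) == 3, nrow(sites) >= 1)
  if (length(site_radius) == 1) site_radius <- rep(site_radius, nrow(sites))
  out <- matrix(0, length(ensembles), nrow(sites),
                dimnames = list(names(ensembles), rownames(sites)))
  for (s in seq_along(ensembles)) {
    hits <- matrix(FALSE, length(ensembles[[s]]), nrow(sites))
    for (c_i in seq_along(ensembles[[s]])) {
      ions <- ensembles[[s]][[c_i]]
      if (!is.matrix(ions) || nrow(ions) == 0) next
      for (j in seq_len(nrow(sites))) {
        d2 <- rowSums(sweep(ions, 2, sites[j, ])^2)
        hits[c_i, j] <- any(d2 <= site_radius[j]^2)
      }
    }
    out[s, ] <- colMeans(hits)
  }
  out
}

#' Weighted Ramachandran (phi/psi) density on the torus
#'
#' Wrap-aware 2-D weighted histogram of a backbone dihedral pair, normalised
#' to total probability 1, with highest-density contour levels at the stated
#' probability mass fractions.
#'
#' @param phi,psi Angle vectors in degrees (any real values; wrapped).
#' @param weights Optional per-frame weights (e.g. MSM frame weights).
#' @param bins Bins per axis (default 60).
#' @param mass_levels Probability mass fractions for contour levels.
#' @return Object of class `rama_density`: `phi_mid`, `psi_mid`, `density`
#'   (bins x bins, sums to 1), `levels` (density thresholds enclosing each
#'   mass fraction).
#' @export
ramachandran_density <- function(phi, psi, weights = NULL, bins = 60,
                                 mass_levels = c(0.5, 0.8, 0.95)) {
  stopifnot(length(phi) == length(psi))
  if (is.null(weights)) weights <- rep(1, length(phi))
  phi <- wrap_angle(phi); psi <- wrap_angle(psi)
  br <- seq(-180, 180, length.out = bins + 1)
  bi <- findInterval(phi, br, rightmost.closed = TRUE, all.inside = TRUE)
  bj <- findInterval(psi, br, rightmost.closed = TRUE, all.inside = TRUE)
  dens <- matrix(0, bins, bins)
  idx <- bi + (bj - 1) * bins
  agg <- vapply(split(weights, idx), sum, numeric(1))
  dens[as.integer(names(agg))] <- agg
  dens <- dens / sum(dens)
  sorted <- sort(as.vector(dens), decreasing = TRUE)
  cum <- cumsum(sorted)
  levels <- vapply(mass_levels, function(m) {
    sorted[which(cum >= m)[1]]
  }, numeric(1))
  structure(list(phi_mid = (br[-1] + br[-(bins + 1)]) / 2,
                 psi_mid = (br[-1] + br[-(bins + 1)]) / 2,
                 density = dens,
                 levels = setNames(levels, paste0("p", mass_levels * 100))),
            class = "rama_density")
}
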