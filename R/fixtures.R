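#' Analytic pore geometry fixtures
#'
#' Builds rings of spherical atoms centred on the z-axis whose maximal
#' inscribed-sphere radius along the axis is known in closed form, for
#' validating the pore profiler.
#'
#' \describe{
#' \item{cylinder}{rings of constant radius `ring_radius`; true pore radius
#'   is `ring_radius - atom_radius` everywhere inside.}
#' \item{hourglass}{parabolic rings `R(z) = waist_ring + curvature * z^2`;
#'   the true pore radius at height z is `R(z) - atom_radius`, with analytic
#'   minimum `waist_ring - atom_radius` at z = 0.}
#' \item{blocked}{a cylinder with one extra on-axis atom at z = 0, making
#'   that slice impassable.}
#' }
#'
#' @param kind One of `"cylinder"`, `"hourglass"`, `"blocked"`.
#' @param ring_radius Ring radius in angstrom (cylinder/blocked).
#' @param atom_radius Atom (van der Waals) radius in angstrom.
#' @param length Axial extent in angstrom (centred on 0).
#' @param spacing Axial distance between rings.
#' @param n_per_ring Atoms per ring.
#' @param waist True pore radius at the hourglass waist (angstrom); the ring
#'   radius at z = 0 is `waist + atom_radius`.
#' @param curvature Parabolic opening rate of the hourglass (1/angstrom).
#' @return Object of class `pore_fixture`: data frame `atoms` (x, y, z,
#'   radius, element), `true_radius` (function of z), and the parameters.
#' @export
make_pore_fixture <- function(kind = c("cylinder", "hourglass", "blocked"),
                              ring_radius = 4.5, atom_radius = 1.5,
                              length = 20, spacing = 0.5, n_per_ring = 24,
                              waist = 1.5, curvature = 0.05) {
  kind <- match.arg(kind)
  stopifnot(ring_radius > 0, atom_radius > 0, length > 0, spacing > 0,
            n_per_ring >= 8, waist > 0, curvature >= 0)
  zs <- seq(-length / 2, length / 2, by = spacing)
  ang <- seq(0, 2 * pi, length.out = n_per_ring + 1)[-(n_per_ring + 1)]
  rr <- switch(kind,
    cylinder = rep(ring_radius, length(zs)),
    blocked  = rep(ring_radius, length(zs)),
    hourglass = waist + atom_radius + curvature * zs^2)
  atoms <- do.call(rbind, lapply(seq_along(zs), function(i) {
    data.frame(x = rr[i] * cos(ang), y = rr[i] * sin(ang), z = zs[i],
               radius = atom_radius, element = "C")
  }))
  if (kind == "blocked")
    atoms <- rbind(atoms, data.frame(x = 0, y = 0, z = 0,
                                     radius = atom_radius, element = "C"))
  true_radius <- switch(kind,
    cylinder = function(z) rep(ring_radius - atom_radius, length(z)),
    hourglass = function(z) waist + curvature * z^2,
    blocked = function(z) ifelse(abs(z) < atom_radius, -1,
                                 ring_radius - atom_radius))
  structure(list(atoms = atoms, true_radius = true_radius, kind = kind,
                 ring_radius = ring_radius, atom_radius = atom_radius,
                 waist = waist, curvature = curvature, length = length),
            class = "pore_fixture")
}

#' Write a pore fixture as PDB plus a sidecar radius table
#'
#' @param fixture A `pore_fixture`.
#' @param pdb_file Output PDB path.
#' @param radii_file Output CSV path for per-atom radii (default: the PDB
#'   path with extension `.radii.csv`).
#' @return Invisibly, the PDB path.
#' @export
write_pore_fixture <- function(fixture, pdb_file,
                               radii_file = sub("\\.pdb$", ".radii.csv",
                                                pdb_file)) {
  a <- fixture$atoms
  n <- nrow(a)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(file = pdb_file, xyz = xyz,
                   resno = seq_len(n), resid = rep("RNG", n),
                   eleno = seq_len(n), elety = rep("C", n),
                   chain = rep("A", n))
  write.csv(data.frame(eleno = seq_len(n), radius = a$radius),
            radii_file, row.names = FALSE)
  invisible(pdb_file)
}

#' Ion-placement fixture with known per-site occupancy probabilities
#'
#' For each macrostate, samples `n_samples` conformations; in each, every
#' binding site independently contains one ion with its stated probability,
#' placed uniformly inside the site sphere.  Calibrated occupancy tables can
#' then be recovered by [occupancy_table()].
#'
#' @param site_centers Named 3-column matrix of site centres (rows =
#'   sites, e.g. `S_ext`, `S_cen`, `S_int`).
#' @param site_radius Site sphere radius in angstrom.
#' @param occupancy_probs States x sites matrix of probabilities in `[0, 1]`,
#'   with dimnames.
#' @param n_samples Conformations per state.
#' @param seed Integer RNG seed.
#' @return Named list (per state) of lists of ion-coordinate matrices (one
#'   per conformation; 0 rows when no ion present).
#' @export
make_ion_fixture <- function(site_centers, site_radius = 2.5,
                             occupancy_probs, n_samples = 1000, seed = 1) {
  stopifnot(is.matrix(site_centers), ncol(site_centers) == 3,
            is.matrix(occupancy_probs),
            all(occupancy_probs >= 0), all(occupancy_probs <= 1),
            ncol(occupancy_probs) == nrow(site_centers))
  d <- as.matrix(stats::dist(site_centers))
  if (any(d[upper.tri(d)] < 2 * site_radius))
    warning("binding-site spheres overlap; occupancies may correlate")
  states <- rownames(occupancy_probs)
  with_seed(seed, setNames(lapply(states, function(s) {
    lapply(seq_len(n_samples), function(i) {
      present <- runif(nrow(site_centers)) < occupancy_probs[s, ]
      if (!any(present)) return(matrix(numeric(0), 0, 3))
      do.call(rbind, lapply(which(present), function(j) {
        # uniform point in a sphere: scaled direction with r ~ R * U^(1/3)
        v <- rnorm(3); v <- v / sqrt(sum(v^2))
        site_centers[j, ] + v * site_radius * runif(1)^(1 / 3)
      }))
    })
  }), states))
}
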