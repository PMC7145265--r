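straight_path <- function(z0, z1) rbind(c(0, 0, z0), c(0, 0, z1))

test_that("pore profiler is exact on the cylinder fixture", {
  cyl <- make_pore_fixture("cylinder", ring_radius = 4.5, atom_radius = 1.5,
                           length = 12)
  pp <- pore_profile(cyl, straight_path(-4, 4), step = 0.5, max_search = 2)
  interior <- pp$profile
  expect_true(all(abs(interior$radius - 3.0) < 0.05))
  expect_false(any(interior$impassable))
})

test_that("a single off-axis atom gives the textbook clearance", {
  # atoms at distance 4 from the axis, radius 1.5; probe held on the axis
  atoms <- data.frame(x = c(4, -4, 0, 0), y = c(0, 0, 4, -4), z = 0,
                      radius = 1.5)
  pp <- pore_profile(atoms, straight_path(-0.2, 0.2), step = 0.2,
                     max_search = 1e-6)
  expect_equal(pp$profile$radius[pp$profile$s == 0.2], 2.5,
               tolerance = 1e-5)   # the slice through the atom plane
})

test_that("hourglass bottleneck and sub-threshold extent match the curve", {
  hg <- make_pore_fixture("hourglass", waist = 1.5, curvature = 0.05,
                          length = 24, atom_radius = 1.5)
  pp <- pore_profile(hg, straight_path(-10, 10), step = 0.5, max_search = 2,
                     origin = c(0, 0, 0))
  expect_equal(unname(pp$bottleneck["radius"]), 1.5, tolerance = 0.05)
  expect_lt(abs(pp$bottleneck["s"]), 0.5)
  # radius drops below the 1.8-angstrom chloride radius for |z| < sqrt(0.3/0.05)
  ext <- subthreshold_extent(pp, threshold = 1.8)
  true_len <- 2 * sqrt(0.3 / 0.05)
  expect_lt(abs(ext$longest - true_len), 0.5 + 0.05 / 0.05)
})

test_that("a blocked pore is reported impassable at the blocking slice", {
  bl <- make_pore_fixture("blocked", ring_radius = 4.5, atom_radius = 1.5,
                          length = 12)
  pp <- pore_profile(bl, straight_path(-4, 4), step = 0.5, max_search = 0.5)
  at_block <- abs(pp$profile$s - 4) < 0.3     # s runs from 0 at z = -4
  expect_true(any(pp$profile$impassable[at_block]))
  expect_false(any(pp$profile$impassable[abs(pp$profile$s - 1) < 0.3]))
})

test_that("pore radius shrinks under atom inflation, survives rotation", {
  cyl <- make_pore_fixture("cylinder", ring_radius = 4.0, atom_radius = 1.2,
                           length = 8)
  path <- straight_path(-2, 2)
  p0 <- pore_profile(cyl, path, step = 1, max_search = 1.5)
  fat <- cyl$atoms; fat$radius <- fat$radius + 0.4
  p1 <- pore_profile(fat, path, step = 1, max_search = 1.5)
  expect_true(all(p1$profile$radius <= p0$profile$radius + 1e-9))
  # rigid-body transformation of atoms and path leaves the profile unchanged
  set.seed(90)
  R <- random_rotation(); t0 <- c(3, -2, 5)
  rot <- cyl$atoms
  xyz <- t(R %*% t(as.matrix(rot[, c("x", "y", "z")]))) +
    matrix(t0, nrow(rot), 3, byrow = TRUE)
  rot[, c("x", "y", "z")] <- xyz
  path_r <- t(R %*% t(path)) + matrix(t0, 2, 3, byrow = TRUE)
  p2 <- pore_profile(rot, path_r, step = 1, max_search = 1.5)
  expect_equal(p2$profile$radius, p0$profile$radius, tolerance = 0.02)
})

test_that("sub-threshold extents are computed with interpolation", {
  flat <- data.frame(s = seq(0, 30, 0.5), radius = 3, impassable = FALSE)
  expect_equal(subthreshold_extent(flat, 1.8)$total, 0)
  # rectangular dip of width 19
  dip <- flat
  dip$radius[dip$s > 5 & dip$s <= 24] <- 1.0
  ext <- subthreshold_extent(dip, 1.8)
  expect_lt(abs(ext$longest - 19), 0.5)
  # two dips: 5 and 7 angstrom
  two <- flat
  two$radius[two$s >= 2 & two$s <= 7] <- 1.0
  two$radius[two$s >= 14 & two$s <= 21] <- 1.0
  ext2 <- subthreshold_extent(two, 1.8)
  expect_equal(ext2$longest, 7, tolerance = 0.8)
  expect_equal(ext2$total, 12, tolerance = 1.6)
  expect_equal(nrow(ext2$segments), 2)
})

test_that("macrostate ensembles sample frames proportionally to pi", {
  # one microstate, one frame: that frame n times
  msm1 <- structure(list(active = 1L, mapping = 1L, stationary = 1),
                    class = "msm_model")
  mac1 <- structure(list(crisp = 1L, n_macrostates = 1), class = "macro_model")
  fr <- sample_macrostate_ensemble(msm1, mac1, list(`1` = 42L), state = 1,
                                   n = 50, seed = 1)
  expect_true(all(fr == 42L))
  # two microstates with pi ratio 9:1 inside one macrostate
  msm2 <- structure(list(active = 1:2, mapping = 1:2,
                         stationary = c(0.9, 0.1)),
                    class = "msm_model")
  mac2 <- structure(list(crisp = c(1L, 1L), n_macrostates = 1),
                    class = "macro_model")
  idx <- list(1:100, 101:200)
  fr2 <- sample_macrostate_ensemble(msm2, mac2, idx, state = 1, n = 2000,
                                    seed = 2)
  frac <- mean(fr2 <= 100)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.09 / 2000))
  expect_equal(formals(sample_macrostate_ensemble)$n, 1000)
  expect_error(sample_macrostate_ensemble(msm2, mac2, idx, state = 2,
                                          n = 10, seed = 1))
})

test_that("occupancy frequencies behave like the generating Bernoulli law", {
  sites <- rbind(S_ext = c(0, 0, 8), S_cen = c(0, 0, 0))
  # an ion exactly at the centre in every conformation -> frequency 1
  ens <- list(O = lapply(1:50, function(i) rbind(c(0, 0, 8))))
  occ <- occupancy_table(ens, sites, site_radius = 2.5)
  expect_equal(unname(occ["O", ]), c(1, 0))
  # Bernoulli(0.3) fixture at n = 1000
  probs <- matrix(c(0.3, 0.6), 1, 2, dimnames = list("s", rownames(sites)))
  ens2 <- make_ion_fixture(sites, 2.5, probs, n_samples = 1000, seed = 5)
  occ2 <- occupancy_table(ens2, sites, 2.5)
  expect_lt(abs(occ2["s", "S_ext"] - 0.3), 0.04)
  expect_true(all(occ2 >= 0 & occ2 <= 1))
  # growing the site sphere never decreases occupancy
  occ3 <- occupancy_table(ens2, sites, 4)
  expect_true(all(occ3 >= occ2 - 1e-12))
})

test_that("Ramachandran density is a wrap-aware probability distribution", {
  # all frames identical: a single occupied bin
  rd <- ramachandran_density(rep(-60, 100), rep(120, 100), bins = 36)
  expect_equal(sum(rd$density > 0), 1)
  expect_equal(sum(rd$density), 1)
  # two basins with 3:1 weights
  set.seed(91)
  n <- 8000
  basin <- rep(c(1, 2), c(6000, 2000))
  phi <- ifelse(basin == 1, rnorm(n, -60, 10), rnorm(n, 60, 10))
  psi <- ifelse(basin == 1, rnorm(n, 140, 10), rnorm(n, -40, 10))
  rd2 <- ramachandran_density(phi, psi, bins = 36)
  expect_equal(sum(rd2$density), 1)
  w1 <- sum(rd2$density[rd2$phi_mid < 0, ])
  expect_lt(abs(w1 - 0.75), 0.03)
  # shifting inputs by 360 degrees changes nothing
  rd3 <- ramachandran_density(phi + 360, psi - 360, bins = 36)
  expect_equal(rd3$density, rd2$density)
  # contour levels decrease with enclosed mass and are attainable
  expect_true(all(diff(rd2$levels) <= 0))
})

test_that("per-macrostate backbone densities occupy distinct wells", {
  res <- small_pipeline()
  r <- res$conditions$protonated
  feats <- do.call(rbind, r$features_disc)
  mt <- unlist(macro_dtrajs(r$macro, r$dtrajs))
  lab <- r$labels[mt]
  sel_coi <- !is.na(lab) & lab == "C_oi"
  sel_o <- !is.na(lab) & lab == "O"
  d_coi <- ramachandran_density(feats[sel_coi, "psi:G169-S168"],
                                feats[sel_coi, "psi:I170-G169"], bins = 24)
  d_o <- ramachandran_density(feats[sel_o, "psi:G169-S168"],
                              feats[sel_o, "psi:I170-G169"], bins = 24)
  peak <- function(d) {
    i <- which(d$density == max(d$density), arr.ind = TRUE)[1, ]
    c(d$phi_mid[i[1]], d$psi_mid[i[2]])
  }
  expect_gt(max(abs(peak(d_coi) - peak(d_o))), 90)
})
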