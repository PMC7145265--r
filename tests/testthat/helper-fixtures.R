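# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small end-to-end pipeline run used by several module tests.
small_pipeline <- function() {
  memo("small_pipeline", function() {
    cfg <- pipeline_config(n_traj = 30, n_steps = 3000, k = 60, n_boot = 25,
                           kmeans_iter = 60, seeds = 11)
    run_pipeline(cfg)
  })
}

# Calibration-scale pipeline run backing the recovery checks: 80
# trajectories x 6000 frames per condition, 324 microstates, 100 bootstrap
# models — the study conditions at reduced depth.
calibration_pipeline <- function() {
  memo("calibration_pipeline", function() {
    cfg <- pipeline_config(n_traj = 80, n_steps = 6000, k = 324, n_boot = 100,
                           kmeans_iter = 100, seeds = 2024)
    run_pipeline(cfg)
  })
}

# Synthetic 3-residue peptide as a multi-model PDB written programmatically;
# coordinates are arbitrary but non-degenerate, so every dihedral is defined.
write_test_peptide <- function(path, n_models = 2, seed = 42) {
  # residues: ALA 1, SER 2, GLY 3; backbone N/CA/C (+O omitted) plus CB/OG
  atoms <- data.frame(
    resno = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 3, 3, 3),
    resid = c(rep("ALA", 4), rep("SER", 5), rep("GLY", 3)),
    elety = c("N", "CA", "C", "CB", "N", "CA", "C", "CB", "OG",
              "N", "CA", "C"))
  set.seed(seed)
  xyz <- do.call(rbind, lapply(seq_len(n_models), function(m) {
    base <- cbind(seq_len(nrow(atoms)) * 1.4,
                  sin(seq_len(nrow(atoms)) + m),
                  cos(seq_len(nrow(atoms)) * 0.7 + m))
    as.numeric(t(base + matrix(rnorm(nrow(atoms) * 3, sd = 0.05),
                               ncol = 3)))
  }))
  bio3d::write.pdb(file = path, xyz = xyz, resno = atoms$resno,
                   resid = atoms$resid, eleno = seq_len(nrow(atoms)),
                   elety = atoms$elety, chain = rep("A", nrow(atoms)))
  atoms
}
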