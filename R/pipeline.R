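#' Pipeline configuration
#'
#' Collects every tunable of the gating-analysis pipeline with the production
#' defaults: 2.88 ns per frame so that the 10-frame MSM lag equals 28.8 ns,
#' 324 microstates, 100 bootstrap models, automatic macrostate count by
#' spectral gap, and explicit seeds for every random stage.
#'
#' @param n_traj Trajectories per condition (synthetic generation); a single
#'   number, or a named vector with one entry per condition.
#' @param n_steps Frames per trajectory; scalar or named like `n_traj`.
#' @param dt CTMC grid spacing (model time units per frame).
#' @param frame_ns Declared physical time per frame (ns).
#' @param temperature Kelvin.
#' @param tica_lag Frames.
#' @param k Number of microstates.
#' @param msm_lag_ns MSM lag in ns; must be an integer number of frames.
#' @param n_boot Bootstrap models.
#' @param n_macrostates Integer or `"auto"` (spectral-gap choice).
#' @param conditions Character subset of `c("protonated", "deprotonated")`.
#' @param seeds Named list of integer seeds (`ctmc`, `emission`, `cluster`,
#'   `bootstrap`); a single integer seeds all stages reproducibly.
#' @param kmeans_batch,kmeans_iter Mini-batch k-means controls.
#' @return Object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(n_traj = 200, n_steps = 20000, dt = 0.1,
                            frame_ns = 2.88, temperature = 300,
                            tica_lag = 10, k = 324, msm_lag_ns = 28.8,
                            n_boot = 100, n_macrostates = "auto",
                            conditions = c("protonated", "deprotonated"),
                            seeds = 1, kmeans_batch = 1000,
                            kmeans_iter = 150) {
  if (is.numeric(seeds) && length(seeds) == 1) {
    base <- as.integer(seeds)
    seeds <- list(ctmc = base, emission = base + 1000L,
                  cluster = base + 2000L, bootstrap = base + 3000L)
  }
  stopifnot(all(c("ctmc", "emission", "cluster", "bootstrap") %in%
                names(seeds)))
  lag_frames <- msm_lag_ns / frame_ns
  if (abs(lag_frames - round(lag_frames)) > 1e-9)
    stop(sprintf("msm_lag_ns (%g) is not an integer number of frames at %g ns/frame",
                 msm_lag_ns, frame_ns))
  conditions <- match.arg(conditions, several.ok = TRUE)
  expand <- function(x) {
    x <- unlist(x)
    x <- setNames(as.integer(x), names(x))
    if (length(x) == 1) x <- setNames(rep(x, length(conditions)), conditions)
    stopifnot(all(conditions %in% names(x)))
    x[conditions]
  }
  n_traj <- expand(n_traj); n_steps <- expand(n_steps)
  structure(list(n_traj = n_traj, n_steps = n_steps,
                 dt = dt, frame_ns = frame_ns, temperature = temperature,
                 tica_lag = as.integer(tica_lag), k = as.integer(k),
                 msm_lag_ns = msm_lag_ns,
                 msm_lag_frames = as.integer(round(lag_frames)),
                 n_boot = as.integer(n_boot), n_macrostates = n_macrostates,
                 conditions = conditions, seeds = seeds,
                 kmeans_batch = as.integer(kmeans_batch),
                 kmeans_iter = as.integer(kmeans_iter)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips unchanged through serialization.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the config.
#' @export
write_config <- function(config, path) {
  obj <- unclass(config)
  # named atomic vectors must become maps to survive YAML round trips
  obj$n_traj <- as.list(obj$n_traj)
  obj$n_steps <- as.list(obj$n_steps)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(pipeline_config, obj[c("n_traj", "n_steps", "dt", "frame_ns",
                                 "temperature", "tica_lag", "k", "msm_lag_ns",
                                 "n_boot", "n_macrostates", "conditions",
                                 "kmeans_batch", "kmeans_iter")] |>
            c(list(seeds = obj$seeds)))
}

# md5 of an R object via its serialization (version 3, text-stable).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 3)
  unname(tools::md5sum(f))
}

#' Run the full gating-analysis pipeline on synthetic trajectories
#'
#' Generates trajectories from the calibrated reference kinetic model for the
#' requested protonation conditions, emits dihedral features, fits one shared
#' tICA model and one shared microstate decomposition over all conditions,
#' then per condition estimates the reversible MSM (with bootstrap),
#' coarse-grains with PCCA+ (automatic macrostate count by spectral gap
#' unless fixed), labels macrostates against the emission archetypes, and
#' estimates the macrostate rate matrix.  A manifest records the config,
#' seeds and hashes of every artifact, so identical configs give identical
#' manifests.
#'
#' @param config A `pipeline_config`.
#' @return Object of class `pipeline_result`: per-condition results
#'   (`msm`, `bootstrap`, `macro`, `labels`, `populations`, `free_energies`,
#'   `rates`, `network`, truth references), shared `tica` and `clustering`,
#'   and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  kT <- kT_kcal(config$temperature)
  conditions <- config$conditions

  models <- lapply(conditions, function(cond)
    build_reference_model(protonated = cond == "protonated",
                          temperature = config$temperature))
  names(models) <- conditions

  features <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    p <- sample_ctmc(models[[cond]], config$n_traj[[cond]],
                     config$n_steps[[cond]],
                     dt = config$dt, seed = config$seeds$ctmc + i)
    em <- default_emission_model(states = models[[cond]]$state_labels)
    features[[cond]] <- emit_features(p, em, seed = config$seeds$emission + i)
  }

  all_features <- do.call(c, unname(features))
  rm(features)
  tica <- fit_tica(all_features, lag = config$tica_lag)
  # transform trajectory-by-trajectory, keeping only the discriminative
  # feature columns for later macrostate labelling (bounds peak memory)
  disc <- default_emission_model()$discriminative
  proj_all <- vector("list", length(all_features))
  disc_features <- vector("list", length(all_features))
  for (i in seq_along(all_features)) {
    proj_all[[i]] <- tica_transform(tica, all_features[[i]])
    disc_features[[i]] <- unclass(all_features[[i]])[, disc, drop = FALSE]
    all_features[i] <- list(NULL)
  }
  gc(verbose = FALSE)
  clustering <- fit_minibatch_kmeans(proj_all, k = config$k,
                                     batch_size = config$kmeans_batch,
                                     n_iter = config$kmeans_iter,
                                     seed = config$seeds$cluster)
  idx <- split(seq_along(proj_all),
               rep(seq_along(conditions), times = config$n_traj[conditions]))

  results <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    dtrajs <- clustering$assignments[idx[[ci]]]
    proj <- proj_all[idx[[ci]]]
    boot <- bootstrap_msms(dtrajs, lag = config$msm_lag_frames,
                           n_boot = config$n_boot,
                           seed = config$seeds$bootstrap + ci,
                           frame_ns = config$frame_ns, n_states = config$k)
    msm <- boot$mle
    n_macro <- if (identical(config$n_macrostates, "auto"))
      as.integer(choose_n_macrostates(msm)) else as.integer(config$n_macrostates)
    macro <- pcca_plus(msm, n_macro)
    em <- default_emission_model(states = models[[cond]]$state_labels)
    labels <- label_macrostates(macro, disc_features[idx[[ci]]], dtrajs, em)
    mtrajs <- macro_dtrajs(macro, dtrajs)
    rates <- estimate_rate_matrix(mtrajs, lag = config$msm_lag_frames,
                                  frame_ns = config$frame_ns,
                                  n_states = n_macro,
                                  pi_macro = macro$populations)
    network <- kinetic_network_summary(rates, labels = labels, kT = kT)
    pops <- setNames(macro$populations, labels)
    results[[cond]] <- list(
      condition = cond, truth = models[[cond]],
      dtrajs = dtrajs, projections = proj,
      features_disc = disc_features[idx[[ci]]],
      msm = msm, bootstrap = boot, macro = macro, labels = labels,
      populations = pops,
      free_energies = free_energy(pops, kT),
      rates = rates, network = network)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("msmgating")),
    config = unclass(config),
    hashes = list(
      config = object_hash(unclass(config)),
      tica = object_hash(tica[c("eigenvalues", "eigenvectors", "mean")]),
      clustering = object_hash(clustering$centers),
      populations = object_hash(lapply(results, `[[`, "populations"))))
  structure(list(conditions = results, tica = tica, clustering = clustering,
                 config = config, kT = kT, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Gating-analysis pipeline result\n")
  for (cond in names(x$conditions)) {
    r <- x$conditions[[cond]]
    cat(sprintf("  %s: %d macrostates; populations: %s\n", cond,
                r$macro$n_macrostates,
                paste(sprintf("%s=%.4f", names(r$populations),
                              r$populations), collapse = " ")))
  }
  invisible(x)
}

#' Write a pipeline manifest as JSON
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(result, path) {
  jsonlite::write_json(result$manifest, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
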