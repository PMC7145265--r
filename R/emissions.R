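#' Selectivity-filter residue numbers
#'
#' The 17 filter residues (rCLC-2 numbering) used for featurization.
#'
#' @return Integer vector of residue numbers.
#' @export
sf_residues <- function() {
  c(167L, 168L, 169L, 170L, 171L, 209L, 210L, 211L, 212L, 213L,
    463L, 464L, 465L, 466L, 467L, 468L, 559L)
}

# One-letter codes for the filter residues where the identity matters to the
# analysis (gate residues); the remainder are synthetic placeholders ("X",
# treated as side-chain-bearing) since the generator only needs named columns.
sf_residue_codes <- function() {
  codes <- setNames(rep("X", 17), as.character(sf_residues()))
  codes[c("167", "168", "169", "170", "211", "559")] <-
    c("G", "S", "G", "I", "E", "Y")
  codes
}

# Feature names for the synthetic emission model, in residue-major,
# angle-kind-minor order.  Backbone names span the two residues the dihedral
# connects: phi of residue i is "phi:<res_i>-<res_{i-1}>", psi of residue i is
# "psi:<res_{i+1}>-<res_i>".  Glycines carry no chi angles; chi2 is emitted
# only for I170, E211 and Y559.
sf_feature_names <- function() {
  res <- sf_residues(); codes <- sf_residue_codes()
  tag <- function(r) {
    code <- codes[as.character(r)]
    if (is.na(code)) code <- "X"
    paste0(code, r)
  }
  nms <- character(0)
  for (r in res) {
    nms <- c(nms, sprintf("phi:%s-%s", tag(r), tag(r - 1L)))
    nms <- c(nms, sprintf("psi:%s-%s", tag(r + 1L), tag(r)))
    code <- codes[as.character(r)]
    if (code != "G") nms <- c(nms, sprintf("chi1:%s", tag(r)))
    if (r %in% c(170L, 211L, 559L)) nms <- c(nms, sprintf("chi2:%s", tag(r)))
  }
  nms
}

#' Von Mises emission model for the selectivity-filter feature set
#'
#' Per-state circular distributions over the 17-residue phi/psi/chi feature
#' set.  Exactly three features are discriminative, matching the loading
#' pattern of the slow dynamical modes of the channel:
#' \itemize{
#' \item `psi:I170-G169` and `psi:G169-S168` separate `C_oi` from
#'   \{`C_o`, `O`, `U`\} (backbone rotation of the inner gate);
#' \item `chi1:E211` takes three distinct modes separating
#'   \{`C_oi`, `C_o`\} vs `O` vs `U` (external-gate glutamate rotamer).
#' }
#' All other features are identically distributed across states.  The default
#' concentration `kappa = 14.59` gives a circular SD of about 15 degrees —
#' states separable but with realistic overlap.
#'
#' @param states Character vector of state labels (default all four).
#' @param kappa Von Mises concentration (default: 15-degree circular SD).
#' @return Object of class `emission_model`: `feature_names`, `states`,
#'   `mean` and `kappa` matrices (features x states), and
#'   `discriminative`, the names of the three informative features.
#' @export
default_emission_model <- function(states = c("C_oi", "C_o", "O", "U"),
                                   kappa = 1 / (15 * pi / 180)^2) {
  nms <- sf_feature_names()
  F <- length(nms); S <- length(states)
  # deterministic background means, shared across states
  base <- wrap_angle(-160 + 37 * seq_len(F))
  mu <- matrix(base, F, S, dimnames = list(nms, states))
  kap <- matrix(kappa, F, S, dimnames = list(nms, states))
  set_mu <- function(feature, state, value) {
    stopifnot(feature %in% nms, state %in% states)
    mu[feature, state] <<- value
  }
  open_like <- intersect(c("C_o", "O", "U"), states)
  if ("C_oi" %in% states) {
    mu["psi:I170-G169", ] <- 120; set_mu("psi:I170-G169", "C_oi", -60)
    mu["psi:G169-S168", ] <- 140; set_mu("psi:G169-S168", "C_oi", -40)
  }
  mu["chi1:E211", ] <- -90                       # shared C_oi / C_o rotamer
  if ("O" %in% states) set_mu("chi1:E211", "O", 30)
  if ("U" %in% states) set_mu("chi1:E211", "U", 150)
  structure(list(feature_names = nms, states = states,
                 mean = mu, kappa = kap,
                 discriminative = c("psi:I170-G169", "psi:G169-S168",
                                    "chi1:E211")),
            class = "emission_model")
}

#' Construct an emission model from explicit mean/concentration tables
#'
#' @param mean Features x states matrix of mean angles (degrees), with
#'   dimnames.
#' @param kappa Matrix of concentrations, same shape (or a scalar).
#' @param discriminative Optional character vector of informative features.
#' @return An `emission_model`.
#' @export
emission_model <- function(mean, kappa, discriminative = character(0)) {
  stopifnot(is.matrix(mean), !is.null(rownames(mean)), !is.null(colnames(mean)))
  if (length(kappa) == 1) kappa <- matrix(kappa, nrow(mean), ncol(mean),
                                          dimnames = dimnames(mean))
  stopifnot(all(dim(kappa) == dim(mean)))
  structure(list(feature_names = rownames(mean), states = colnames(mean),
                 mean = wrap_angle(mean), kappa = kappa,
                 discriminative = discriminative),
            class = "emission_model")
}

#' Emit dihedral feature matrices from discrete state paths
#'
#' For each frame, angles are drawn independently per feature from the
#' occupied state's von Mises distribution and wrapped to `[-180, 180)`.
#' `kappa = Inf` gives a point mass at the state mean.
#'
#' @param paths List of integer state paths (1-based indices into
#'   `attr(paths, "state_labels")`, as returned by [sample_ctmc()]), or of
#'   character vectors of state labels.
#' @param emission An `emission_model`.
#' @param seed Integer RNG seed.
#' @return List of `feature_matrix` objects (numeric matrices with named
#'   columns), one per path.
#' @export
emit_features <- function(paths, emission, seed) {
  labels <- attr(paths, "state_labels")
  idx_paths <- lapply(paths, function(p) {
    if (is.character(p)) p <- match(p, emission$states)
    else if (!is.null(labels)) p <- match(labels[p], emission$states)
    if (anyNA(p) || any(p < 1) || any(p > length(emission$states)))
      stop("path contains a state not present in the emission model")
    as.integer(p)
  })
  mu <- emission$mean; kap <- emission$kappa
  Fn <- length(emission$feature_names)
  with_seed(seed, lapply(idx_paths, function(p) {
    m <- matrix(0, length(p), Fn,
                dimnames = list(NULL, emission$feature_names))
    for (s in sort(unique(p))) {
      rows <- which(p == s)
      for (f in seq_len(Fn))
        m[rows, f] <- rvonmises(length(rows), mu[f, s], kap[f, s])
    }
    feature_matrix(m)
  }))
}
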