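#' Time-lagged independent component analysis
#'
#' Estimates the slowest linearly decorrelating coordinates of a feature time
#' series.  The instantaneous covariance `C0` and the symmetrized time-lagged
#' covariance `Ct = (Ct + Ct^T)/2` are accumulated over all trajectories from
#' mean-free data (means over the lagged pairs), and the generalized
#' eigenproblem `Ct v = lambda (C0 + ridge I) v` is solved via a Cholesky
#' reduction.  Eigenvectors are normalised to be C0-orthonormal and signed so
#' the largest-magnitude coefficient is positive; eigenvalues are sorted in
#' descending order.  The symmetrized estimator guarantees a real spectrum.
#'
#' @param features List of `feature_matrix` objects (or numeric matrices with
#'   identical column names), or a single matrix.
#' @param lag Lag time in frames (>= 1, shorter than every trajectory).
#' @param ridge Regularisation added to the diagonal of `C0`; default
#'   `1e-6 * trace(C0) / F`, which tolerates collinear dihedral columns.
#' @return Object of class `tica_model`: `lag`, `mean`, `C0`, `Ct`,
#'   `eigenvalues`, `eigenvectors` (columns = components), `ridge`,
#'   `feature_names`.  A `degenerate` attribute lists near-degenerate
#'   eigenvalue pairs (gap below 1e-6), which are also reported via a warning.
#' @export
fit_tica <- function(features, lag, ridge = NULL) {
  if (is.matrix(features)) features <- list(features)
  stopifnot(length(features) >= 1, lag >= 1)
  nms <- colnames(features[[1]])
  F <- length(nms)
  if (F < 2) stop("tICA requires at least 2 features")
  for (f in features) {
    if (!identical(colnames(f), nms)) stop("feature columns differ between trajectories")
    if (nrow(f) <= lag)
      stop(sprintf("lag (%d) must be shorter than every trajectory (found %d frames)",
                   lag, nrow(f)))
  }
  # pass 1: mean over all lagged-pair frames
  s <- numeric(F); n <- 0
  for (f in features) {
    T <- nrow(f)
    i0 <- seq_len(T - lag); it <- i0 + lag
    s <- s + colSums(f[i0, , drop = FALSE]) + colSums(f[it, , drop = FALSE])
    n <- n + 2 * (T - lag)
  }
  mu <- s / n
  # pass 2: covariances
  C0 <- matrix(0, F, F); Ct <- matrix(0, F, F)
  for (f in features) {
    T <- nrow(f)
    X0 <- sweep(f[seq_len(T - lag), , drop = FALSE], 2, mu)
    Xt <- sweep(f[(lag + 1):T, , drop = FALSE], 2, mu)
    C0 <- C0 + crossprod(X0) + crossprod(Xt)
    Ct <- Ct + crossprod(X0, Xt)
  }
  C0 <- C0 / n
  Ct <- (Ct + t(Ct)) / n          # symmetrize (n/2 pairs, two terms each)
  const <- which(diag(C0) < 1e-12)
  if (length(const))
    stop("all-constant feature(s): ", paste(nms[const], collapse = ", "))
  if (is.null(ridge)) ridge <- 1e-6 * sum(diag(C0)) / F
  R <- chol(C0 + ridge * diag(F))
  B <- backsolve(R, t(backsolve(R, t(Ct), transpose = TRUE)), transpose = TRUE)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- backsolve(R, e$vectors)
  # orthonormal in the (ridge-regularised) C0 metric; deterministic sign
  nrm <- sqrt(colSums(V * ((C0 + ridge * diag(F)) %*% V)))
  V <- sweep(V, 2, nrm, "/")
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  lam <- e$values
  gaps <- which(abs(diff(lam)) < 1e-6)
  if (length(gaps))
    warning("near-degenerate tICA eigenvalues at components: ",
            paste(gaps, collapse = ", "))
  rownames(V) <- nms
  structure(list(lag = lag, mean = mu, C0 = C0, Ct = Ct,
                 eigenvalues = lam, eigenvectors = V, ridge = ridge,
                 feature_names = nms, degenerate = gaps),
            class = "tica_model")
}

#' Project features onto tICA components
#'
#' Projects mean-free data onto all eigenvectors; with `kinetic_map = TRUE`
#' (the default) component i is scaled by its eigenvalue, so Euclidean
#' distance in the projected space approximates kinetic distance.
#'
#' @param model A `tica_model`.
#' @param features A matrix or list of matrices with the model's columns.
#' @param kinetic_map Scale components by their eigenvalues?
#' @return Projected matrix (or list of matrices), columns `tIC1`, `tIC2`, ...
#' @export
tica_transform <- function(model, features, kinetic_map = TRUE) {
  one <- function(f) {
    if (!identical(colnames(f), model$feature_names))
      stop("feature columns do not match the tICA model")
    Y <- sweep(unclass(f), 2, model$mean) %*% model$eigenvectors
    if (kinetic_map) Y <- sweep(Y, 2, model$eigenvalues, "*")
    colnames(Y) <- paste0("tIC", seq_len(ncol(Y)))
    Y
  }
  if (is.list(features)) lapply(features, one) else one(features)
}

#' High-loading features of a tICA component
#'
#' Features whose absolute coefficient exceeds
#' `mean(|coef|) + threshold_sd * sd(|coef|)`, sorted by magnitude.
#'
#' @param model A `tica_model`.
#' @param component Component index (1-based).
#' @param threshold_sd Threshold in standard deviations (default 2).
#' @return Data frame with columns `feature`, `coefficient`.
#' @export
top_loadings <- function(model, component, threshold_sd = 2) {
  stopifnot(component >= 1, component <= ncol(model$eigenvectors))
  v <- model$eigenvectors[, component]
  a <- abs(v)
  keep <- a > mean(a) + threshold_sd * sd(a)
  out <- data.frame(feature = names(v)[keep], coefficient = v[keep],
                    row.names = NULL)
  out[order(-abs(out$coefficient)), , drop = FALSE]
}

#' Serialize / restore a tICA model as JSON
#'
#' @param model A `tica_model`.
#' @param path JSON file path.
#' @return `write_tica` returns `path` invisibly; `read_tica` the model.
#' @export
write_tica <- function(model, path) {
  obj <- list(schema = "msmgating-tica v1", lag = model$lag,
              ridge = model$ridge, feature_names = model$feature_names,
              mean = model$mean, eigenvalues = model$eigenvalues,
              eigenvectors = model$eigenvectors,
              C0 = model$C0, Ct = model$Ct)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tica
#' @export
read_tica <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "msmgating-tica v1"))
    stop("schema mismatch in ", path)
  V <- obj$eigenvectors; rownames(V) <- obj$feature_names
  structure(list(lag = obj$lag, mean = setNames(obj$mean, obj$feature_names),
                 C0 = obj$C0, Ct = obj$Ct, eigenvalues = obj$eigenvalues,
                 eigenvectors = V, ridge = obj$ridge,
                 feature_names = obj$feature_names,
                 degenerate = integer(0)),
            class = "tica_model")
}
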