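# Blocked nearest-centre assignment.  Squared distances via the expansion
# |x|^2 - 2 x.c + |c|^2; ties broken deterministically by lowest centre index.
nearest_center <- function(X, centers, block = 50000L) {
  n <- nrow(X)
  out <- integer(n)
  d2 <- numeric(n)
  cc <- rowSums(centers^2)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    G <- X[idx, , drop = FALSE] %*% t(centers)
    D <- sweep(-2 * G, 2, cc, "+")          # |c|^2 - 2 x.c (drop |x|^2)
    j <- max.col(-D, ties.method = "first")
    out[idx] <- j
    d2[idx] <- D[cbind(seq_along(idx), j)] + rowSums(X[idx, , drop = FALSE]^2)
  }
  list(assign = out, d2 = pmax(d2, 0))
}

# k-means++ seeding on (a subsample of) the data.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  for (j in 2:k) {
    if (sum(d2) <= 0) i <- sample.int(n, 1)
    else i <- sample.int(n, 1, prob = d2)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[j, ])^2))
  }
  centers
}

#' Mini-batch k-means clustering of tICA projections
#'
#' Partitions kinetic-mapped projections into microstates.  k-means++
#' initialisation (on a subsample of at most `max(10 k, 20000)` points),
#' per-batch centre updates with per-centre learning rate `1/count`, then a
#' final full-pass assignment.  Empty clusters are repaired by reseeding to
#' the point currently farthest from its centre.  Deterministic under `seed`.
#'
#' @param projections Matrix or list of matrices (frames x components).
#' @param k Number of microstates (default 324).
#' @param batch_size Mini-batch size (default 1000).
#' @param n_iter Number of mini-batch iterations (default 150).
#' @param seed Integer RNG seed.
#' @param refine_iter Optional full-batch Lloyd refinement passes after the
#'   mini-batch phase (default 0).
#' @return Object of class `microstate_clustering`: `k`, `centers`,
#'   `assignments` (list of integer vectors, one per trajectory), `inertia`,
#'   `traj_lengths`.
#' @export
fit_minibatch_kmeans <- function(projections, k = 324, batch_size = 1000,
                                 n_iter = 150, seed = 1, refine_iter = 0) {
  if (is.matrix(projections)) projections <- list(projections)
  projections <- lapply(projections, unclass)
  lens <- vapply(projections, nrow, integer(1))
  n <- sum(lens)
  offsets <- c(0L, cumsum(lens))
  if (n == 0) stop("empty input")
  if (k > n) stop(sprintf("k = %d exceeds the number of frames (%d)", k, n))
  # gather rows by global index without concatenating the trajectories
  gather <- function(rows) {
    rows <- sort(rows)
    tr <- findInterval(rows - 1L, offsets, rightmost.closed = FALSE)
    do.call(rbind, lapply(unique(tr), function(t)
      projections[[t]][rows[tr == t] - offsets[t], , drop = FALSE]))
  }
  full_pass <- function(centers) {
    parts <- lapply(projections, nearest_center, centers = centers)
    list(assign = lapply(parts, `[[`, "assign"),
         d2 = lapply(parts, `[[`, "d2"))
  }
  with_seed(seed, {
    init_n <- min(n, max(10L * k, 20000L))
    init_rows <- if (init_n == n) seq_len(n) else sample.int(n, init_n)
    centers <- kmeanspp_init(gather(init_rows), k)
    counts <- rep(0, k)
    for (it in seq_len(n_iter)) {
      B <- gather(sample.int(n, min(batch_size, n)))
      a <- nearest_center(B, centers)$assign
      for (j in unique(a)) {
        sel <- a == j
        m <- sum(sel)
        counts[j] <- counts[j] + m
        eta <- m / counts[j]
        cm <- colMeans(B[sel, , drop = FALSE])
        centers[j, ] <- (1 - eta) * centers[j, ] + eta * cm
      }
    }
    full <- full_pass(centers)
    # repair empty clusters: reseed to the farthest-from-centre point
    repeat {
      occupied <- unique(unlist(full$assign, use.names = FALSE))
      empty <- setdiff(seq_len(k), occupied)
      if (!length(empty)) break
      far <- vapply(full$d2, which.max, integer(1))
      far_val <- vapply(seq_along(far), function(t) full$d2[[t]][far[t]],
                        numeric(1))
      t_star <- which.max(far_val)
      centers[empty[1], ] <- projections[[t_star]][far[t_star], ]
      full <- full_pass(centers)
    }
    for (it in seq_len(refine_iter)) {
      sums <- matrix(0, k, ncol(centers)); cnt <- numeric(k)
      for (t in seq_along(projections)) {
        a <- full$assign[[t]]
        cnt <- cnt + tabulate(a, nbins = k)
        rs <- rowsum(projections[[t]], group = a)   # keyed by cluster id
        sums[as.integer(rownames(rs)), ] <-
          sums[as.integer(rownames(rs)), , drop = FALSE] + rs
      }
      nonzero <- cnt > 0
      centers[nonzero, ] <- sums[nonzero, , drop = FALSE] / cnt[nonzero]
      full <- full_pass(centers)
    }
    structure(list(k = k, centers = centers, assignments = full$assign,
                   inertia = sum(vapply(full$d2, sum, numeric(1))),
                   traj_lengths = lens),
              class = "microstate_clustering")
  })
}

#' Assign frames to the nearest microstate centre
#'
#' Nearest-centre rule with ties broken by lowest centre index.
#'
#' @param clustering A `microstate_clustering`.
#' @param projections Matrix or list of matrices with the training dimension.
#' @return Integer vector (or list of vectors) of 1-based microstate indices.
#' @export
assign_clusters <- function(clustering, projections) {
  one <- function(P) {
    if (ncol(P) != ncol(clustering$centers))
      stop(sprintf("dimension mismatch: projections have %d columns, centers %d",
                   ncol(P), ncol(clustering$centers)))
    nearest_center(unclass(P), clustering$centers)$assign
  }
  if (is.list(projections)) lapply(projections, one) else one(projections)
}

#' Full-batch inertia of a clustering on given data
#'
#' @param clustering A `microstate_clustering`.
#' @param projections Matrix or list of matrices.
#' @return Total within-cluster sum of squared distances.
#' @export
kmeans_inertia <- function(clustering, projections) {
  if (is.list(projections)) projections <- do.call(rbind, lapply(projections, unclass))
  sum(nearest_center(unclass(projections), clustering$centers)$d2)
}
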