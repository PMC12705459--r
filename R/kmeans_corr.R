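#' Correlation distance between two activity patterns
#'
#' `1 - Pearson r`, the distance metric used for frame clustering. Ranges
#' from 0 (identical up to affine rescaling) to 2 (exactly anticorrelated).
#'
#' @param a,b numeric vectors with nonzero variance.
#' @return a scalar in [0, 2].
#' @export
correlation_distance <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation distance undefined for a zero-variance vector")
  1 - stats::cor(a, b)
}

# Row-standardize frames to mean 0 and unit Euclidean norm so that the
# correlation of two frames equals their dot product and 1 - r equals
# ||a - b||^2 / 2. `what` names the offending rows in errors.
row_standardize <- function(x, what = "frame") {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)
    stop("zero-variance ", what, "(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  x / nrm
}

#' Replicated k-means with correlation distance
#'
#' Realizes correlation-distance k-means by row-standardizing frames
#' (mean 0, unit norm) and running Lloyd iterations in the standardized
#' space with centroids re-standardized after every update — this exactly
#' reproduces the 1 - r geometry while keeping the update a closed-form
#' mean. Clustering is repeated `n_replicates` times from random frame
#' initializations and the solution with the smallest total within-cluster
#' correlation distance ("best separation of data") is kept. Empty clusters
#' are repaired deterministically by reseeding from the frame farthest from
#' its assigned centroid.
#'
#' @param data frames x N matrix (frames > k).
#' @param k number of clusters.
#' @param n_replicates random restarts (default 10).
#' @param max_iter Lloyd iteration cap per replicate.
#' @param seed integer seed governing initialization only.
#' @return a `partition` list: `labels` (1-based per frame), `centroids`
#'   (k x N means of the raw frames per cluster), `centroids_std`
#'   (standardized centroids used by the metric),
#'   `within_cluster_distance_total`, `converged`, `k`.
#' @export
run_kmeans <- function(data, k, n_replicates = 10L, max_iter = 100L,
                       seed = 1L) {
  data <- as.matrix(data)
  stopifnot(nrow(data) > k, k >= 1L, n_replicates >= 1L)
  xs <- row_standardize(data)
  best <- NULL
  for (r in seq_len(n_replicates)) {
    init <- with_seed(derive_seed(seed, "kmeans-init", r),
                      sample.int(nrow(xs), k))
    fit <- lloyd_corr(xs, k, init, max_iter)
    if (is.null(best) || fit$within < best$within) best <- fit
  }
  counts <- tabulate(best$labels, nbins = k)
  centroids <- rowsum(data, best$labels) / counts
  structure(list(labels = best$labels,
                 centroids = centroids,
                 centroids_std = best$centers,
                 within_cluster_distance_total = best$within,
                 converged = best$converged,
                 k = k),
            class = "partition")
}

# One Lloyd run on standardized rows; returns labels, standardized centers,
# total within-cluster 1-r distance.
lloyd_corr <- function(xs, k, init, max_iter) {
  centers <- xs[init, , drop = FALSE]
  labels <- integer(nrow(xs))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    sim <- xs %*% t(centers)                       # frames x k dot products
    new_labels <- max.col(sim, ties.method = "first")
    # empty-cluster repair: reseed from the worst-fit frame
    counts <- tabulate(new_labels, nbins = k)
    while (any(counts == 0L)) {
      assigned <- sim[cbind(seq_len(nrow(xs)), new_labels)]
      worst <- which.min(assigned)
      empty <- which(counts == 0L)[1L]
      centers[empty, ] <- xs[worst, ]
      sim[, empty] <- xs %*% centers[empty, ]
      new_labels <- max.col(sim, ties.method = "first")
      counts <- tabulate(new_labels, nbins = k)
    }
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    labels <- new_labels
    centers <- rowsum(xs, labels) / counts
    centers <- row_standardize(centers, what = "centroid")
  }
  if (!converged)
    warning("k-means did not converge within ", max_iter, " iterations")
  sim <- xs %*% t(centers)
  within <- sum(1 - sim[cbind(seq_len(nrow(xs)), labels)])
  list(labels = labels, centers = centers, within = within,
       converged = converged)
}
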