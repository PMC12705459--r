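#' Select the most stable partition by total AMI
#'
#' Given several partitions of the same frames (e.g. from independent
#' repetitions of best-of-replicates k-means), returns the one sharing the
#' greatest total adjusted mutual information with all others, together
#' with the full pairwise AMI matrix. Ties go to the lowest index.
#'
#' @param partitions list of `partition` objects (or plain label vectors).
#' @return list with `partition` (the selected element), `index`,
#'   `ami_matrix`.
#' @export
select_stable_partition <- function(partitions) {
  stopifnot(length(partitions) >= 2L)
  labs <- lapply(partitions, function(p)
    if (inherits(p, "partition")) p$labels else p)
  lens <- lengths(labs)
  if (length(unique(lens)) != 1L)
    stop("partitions cover different numbers of frames")
  am <- ami_matrix(labs)
  totals <- rowSums(am) - diag(am)
  idx <- which.max(totals)            # which.max takes the first maximum
  list(partition = partitions[[idx]], index = idx, ami_matrix = am)
}

# Explained variance of a partition in the standardized (correlation
# distance) space: 1 - within-cluster SS / total SS, both about means
# (cluster means and the grand mean respectively), so the value lies in
# [0, 1] and is nondecreasing in k for nested-quality solutions.
explained_variance <- function(xs, labels) {
  grand <- colMeans(xs)
  total <- sum(sweep(xs, 2L, grand)^2)
  counts <- tabulate(labels)
  means <- rowsum(xs, labels) / counts
  within <- sum((xs - means[labels, , drop = FALSE])^2)
  1 - within / total
}

#' Choose the number of states by the explained-variance elbow
#'
#' Runs replicated k-means for each k in `k_range`, records the fraction of
#' variance explained by clustering, and picks the elbow: the last k before
#' the incremental gain in explained variance drops below `gain_threshold`
#' (default 1%). If every gain clears the threshold the maximum of the
#' range is returned with a warning.
#'
#' @param data frames x N matrix.
#' @param k_range candidate k values (default 2:14).
#' @param gain_threshold minimum useful gain in explained variance.
#' @param n_replicates restarts per k.
#' @param max_iter Lloyd cap.
#' @param seed integer seed.
#' @return list with `k_star` and `explained_variance_by_k` (named numeric).
#' @export
choose_k <- function(data, k_range = 2:14, gain_threshold = 0.01,
                     n_replicates = 10L, max_iter = 100L, seed = 1L) {
  data <- as.matrix(data)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) > 1L, max(k_range) < nrow(data))
  xs <- row_standardize(data)
  ev <- vapply(k_range, function(k) {
    p <- run_kmeans(data, k, n_replicates = n_replicates,
                    max_iter = max_iter, seed = derive_seed(seed, "ev", k))
    explained_variance(xs, p$labels)
  }, numeric(1))
  names(ev) <- k_range
  # gain over k-1; for the first k in the range the reference is k = 1,
  # whose explained variance is 0 by definition
  gains <- diff(c(0, ev))
  below <- which(gains < gain_threshold)
  if (length(below) == 0L) {
    warning("no k in range had gain below ", gain_threshold,
            "; returning max of range")
    k_star <- max(k_range)
  } else {
    k_star <- max(k_range[below[1L]] - 1L, min(k_range))
  }
  list(k_star = k_star, explained_variance_by_k = ev)
}

#' Name state centroids by cosine similarity to network templates
#'
#' Each centroid (and its negation) is compared against the nine binary
#' network indicator vectors; the best of the 18 candidates gives the
#' network name with a "+" suffix if the centroid itself won and "-" if its
#' negation did. Exact ties break to the lexicographically first network
#' name with a warning.
#'
#' @param centroids k x N matrix.
#' @param parc a [parcellation()].
#' @return character vector of k signed labels, e.g. `"DMN+"`.
#' @export
label_states <- function(centroids, parc) {
  validate_parcellation(parc, ncol(centroids))
  ind <- network_indicators(parc)                  # 9 x N
  ind_unit <- ind / sqrt(rowSums(ind^2))
  vapply(seq_len(nrow(centroids)), function(j) {
    c0 <- centroids[j, ]
    nrm <- sqrt(sum(c0^2))
    if (nrm == 0) stop("all-zero centroid ", j, " cannot be labeled")
    cs <- as.numeric(ind_unit %*% (c0 / nrm))      # signed cosine per network
    cand <- c(cs, -cs)                             # +c then -c candidates
    names(cand) <- c(paste0(NETWORK_NAMES, "+"), paste0(NETWORK_NAMES, "-"))
    best <- max(cand)
    winners <- names(cand)[abs(cand - best) < 1e-12]
    if (length(winners) > 1L) {
      warning("cosine-similarity tie for centroid ", j, ": ",
              paste(winners, collapse = ", "), "; taking first by name")
      winners <- sort(winners)
    }
    winners[1L]
  }, character(1))
}

#' Assign frames of one subject to group states
#'
#' Each frame gets the group centroid with the minimum correlation
#' distance; ties go to the lowest state index. Zero-variance frames are
#' unassignable: they receive `NA` and a warning, and are excluded from
#' centroid averaging downstream.
#'
#' @param series frames x N matrix (a subject's demeaned series).
#' @param centroids k x N group centroids.
#' @return integer vector of 1-based state labels (NA = unassignable).
#' @export
assign_frames <- function(series, centroids) {
  series <- as.matrix(series)
  stopifnot(ncol(series) == ncol(centroids))
  cs <- row_standardize(centroids, what = "centroid")
  x <- series - rowMeans(series)
  nrm <- sqrt(rowSums(x^2))
  ok <- nrm > 0
  labels <- rep(NA_integer_, nrow(series))
  if (any(!ok))
    warning(sum(!ok), " zero-variance frame(s) left unassigned")
  if (any(ok)) {
    sim <- (x[ok, , drop = FALSE] / nrm[ok]) %*% t(cs)
    labels[ok] <- max.col(sim, ties.method = "first")
  }
  labels
}

#' Per-subject state centroids
#'
#' State centroid j is the mean of the subject's frames labeled j. States
#' the subject never visits are imputed from the group centroids and
#' recorded in `imputed_states` so the k x k transition structure is
#' preserved for every subject.
#'
#' @param series frames x N matrix.
#' @param labels per-frame 1-based state labels (NA allowed).
#' @param group_centroids k x N group centroids (imputation source).
#' @return list with `centroids` (k x N), `frames_per_state` (length k),
#'   `imputed_states` (integer indices).
#' @export
subject_centroids <- function(series, labels, group_centroids) {
  series <- as.matrix(series)
  k <- nrow(group_centroids)
  stopifnot(length(labels) == nrow(series),
            ncol(series) == ncol(group_centroids))
  counts <- tabulate(labels[!is.na(labels)], nbins = k)
  cent <- group_centroids
  for (j in which(counts > 0L)) {
    cent[j, ] <- colMeans(series[which(labels == j), , drop = FALSE])
  }
  list(centroids = cent, frames_per_state = counts,
       imputed_states = which(counts == 0L))
}

#' Extract group brain states from a cohort
#'
#' Concatenates all subjects' frames in manifest order, repeats
#' best-of-`n_replicates` k-means `stability_runs` times independently,
#' selects the partition with the greatest total AMI, names the states by
#' network templates, and computes per-subject labels (the group
#' partition's restriction) and centroids.
#'
#' @param series_list list of subject series (each with `$data` and
#'   `$subject_id`, as produced by the generator or [read_manifest()]).
#' @param parc a [parcellation()].
#' @param k number of states, or `"auto"` to run [choose_k()].
#' @param k_range,gain_threshold passed to [choose_k()] when `k = "auto"`.
#' @param n_replicates restarts within each clustering run.
#' @param stability_runs independent repetitions compared by AMI.
#' @param seed integer seed.
#' @return a `brain_state_set` list: `k`, `group_centroids`, `labels`
#'   (signed network names), `ami_matrix`, `selected_run`,
#'   `frame_labels` (per-subject list), `subject_centroids` (list),
#'   `explained_variance_by_k` (when k was chosen automatically).
#' @export
extract_brain_states <- function(series_list, parc, k = 4L,
                                 k_range = 2:14, gain_threshold = 0.01,
                                 n_replicates = 10L, stability_runs = 10L,
                                 seed = 1L) {
  stopifnot(length(series_list) >= 1L)
  data <- do.call(rbind, lapply(series_list, `[[`, "data"))
  validate_parcellation(parc, ncol(data))
  ev_by_k <- NULL
  if (identical(k, "auto")) {
    sel <- choose_k(data, k_range = k_range,
                    gain_threshold = gain_threshold,
                    n_replicates = n_replicates,
                    seed = derive_seed(seed, "choose-k"))
    k <- sel$k_star
    ev_by_k <- sel$explained_variance_by_k
  }
  k <- as.integer(k)
  runs <- lapply(seq_len(stability_runs), function(r)
    run_kmeans(data, k, n_replicates = n_replicates,
               seed = derive_seed(seed, "stability", r)))
  if (stability_runs >= 2L) {
    sel <- select_stable_partition(runs)
    part <- sel$partition
    amat <- sel$ami_matrix
    run_idx <- sel$index
  } else {
    part <- runs[[1L]]
    amat <- matrix(1, 1, 1)
    run_idx <- 1L
  }
  state_labels <- label_states(part$centroids, parc)
  # split the group partition back into per-subject label sequences
  n_frames <- vapply(series_list, function(s) nrow(s$data), integer(1))
  idx_end <- cumsum(n_frames)
  idx_start <- c(1L, utils::head(idx_end, -1L) + 1L)
  frame_labels <- lapply(seq_along(series_list), function(i)
    part$labels[idx_start[i]:idx_end[i]])
  subj_cent <- lapply(seq_along(series_list), function(i)
    subject_centroids(series_list[[i]]$data, frame_labels[[i]],
                      part$centroids))
  names(frame_labels) <- names(subj_cent) <-
    vapply(series_list, `[[`, character(1), "subject_id")
  structure(list(k = k, group_centroids = part$centroids,
                 labels = state_labels, partition = part,
                 ami_matrix = amat, selected_run = run_idx,
                 frame_labels = frame_labels,
                 subject_centroids = subj_cent,
                 explained_variance_by_k = ev_by_k),
            class = "brain_state_set")
}
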