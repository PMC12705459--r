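#' Aggregate a regional TE tensor to network and global levels
#'
#' Pairwise network TE sums the regional energies of each network's
#' regions; pairwise global TE sums over all regions. The mean TE at each
#' level is the arithmetic mean over all k^2 pairwise entries, persistence
#' (diagonal) included.
#'
#' @param tensor N x k x k regional TE array (see [pairwise_te()]).
#' @param parc a [parcellation()] covering the same N regions.
#' @return an `aggregated_te` list: `network_pairwise` (9 x k x k),
#'   `global_pairwise` (k x k), `mean_regional` (N), `mean_network` (9),
#'   `mean_global` (scalar).
#' @export
aggregate_te <- function(tensor, parc) {
  stopifnot(length(dim(tensor)) == 3L)
  n <- dim(tensor)[1L]; k <- dim(tensor)[2L]
  validate_parcellation(parc, n)
  flat <- matrix(tensor, nrow = n)                    # N x k^2
  ind <- network_indicators(parc)                     # 9 x N
  net_flat <- ind %*% flat                            # 9 x k^2
  network_pairwise <- array(net_flat, dim = c(length(NETWORK_NAMES), k, k),
                            dimnames = list(NETWORK_NAMES, NULL, NULL))
  global_pairwise <- matrix(colSums(flat), k, k)
  structure(list(network_pairwise = network_pairwise,
                 global_pairwise = global_pairwise,
                 mean_regional = rowMeans(flat),
                 mean_network = rowMeans(net_flat),
                 mean_global = mean(global_pairwise)),
            class = "aggregated_te")
}

#' Flag outlier subjects by the 1.5 x IQR rule on mean global TE
#'
#' Quartiles use the linear-interpolation convention (R quantile type 7);
#' subjects whose mean global TE falls outside
#' [Q1 - factor x IQR, Q3 + factor x IQR] are excluded before statistics.
#'
#' @param values named numeric vector of per-subject mean global TE
#'   (names = subject ids).
#' @param factor fence multiplier (default 1.5).
#' @return an `outlier_report` list: `lower_fence`, `upper_fence`,
#'   `excluded_subject_ids`, `n_excluded`, `kept_subject_ids`.
#' @export
exclude_outliers <- function(values, factor = 1.5) {
  stopifnot(length(values) >= 4L, factor >= 0)
  if (is.null(names(values)))
    names(values) <- as.character(seq_along(values))
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  width <- if (iqr == 0) 0 else factor * iqr   # avoid Inf * 0 at factor=Inf
  lower <- q[1L] - width
  upper <- q[2L] + width
  out <- values < lower | values > upper
  structure(list(lower_fence = lower, upper_fence = upper,
                 excluded_subject_ids = names(values)[out],
                 n_excluded = sum(out),
                 kept_subject_ids = names(values)[!out]),
            class = "outlier_report")
}
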