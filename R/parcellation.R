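#' Canonical network names
#'
#' The nine resting-state networks used for state labeling and network-level
#' aggregation: the seven cortical networks (visual, somatomotor, dorsal and
#' ventral attention, limbic, frontoparietal, default mode) plus subcortical
#' and cerebellar groups.
#'
#' @export
NETWORK_NAMES <- c("VIS", "SOM", "DAT", "VAT", "LIM", "FPN", "DMN",
                   "SUB", "CER")

#' Construct a parcellation scheme
#'
#' A parcellation assigns each of the N regions to exactly one of the nine
#' canonical networks. Region ids are contiguous 0-based integers (matching
#' the on-disk format); rows are ordered by region id.
#'
#' @param network character vector of length N with values in
#'   [NETWORK_NAMES].
#' @param region_name optional region names; defaults to
#'   `<network>_<within-network index>`.
#' @return a `data.frame` of class `parcellation` with columns
#'   `region_id`, `region_name`, `network`.
#' @export
parcellation <- function(network, region_name = NULL) {
  network <- as.character(network)
  bad <- setdiff(unique(network), NETWORK_NAMES)
  if (length(bad) > 0L)
    stop("unknown network name(s): ", paste(bad, collapse = ", "))
  n <- length(network)
  if (is.null(region_name)) {
    region_name <- paste0(network, "_",
                          stats::ave(seq_len(n), network, FUN = seq_along))
  }
  if (anyDuplicated(region_name))
    stop("region names must be unique")
  out <- data.frame(region_id = seq_len(n) - 1L,
                    region_name = as.character(region_name),
                    network = network,
                    stringsAsFactors = FALSE)
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Default synthetic 86-region parcellation
#'
#' Emulates the dimensionality of an 86-region FreeSurfer parcellation
#' (68 cortical + 18 subcortical/cerebellar regions) with network sizes
#' roughly proportional to the canonical seven-network cortical assignment
#' plus subcortical and cerebellar groups.
#'
#' @param n_regions total number of regions (default 86).
#' @return a [parcellation()].
#' @export
default_parcellation <- function(n_regions = 86L) {
  stopifnot(n_regions >= length(NETWORK_NAMES))
  # proportions chosen once to mirror the FS86/Yeo region counts
  prop <- c(VIS = 10, SOM = 10, DAT = 8, VAT = 8, LIM = 6, FPN = 12,
            DMN = 14, SUB = 14, CER = 4)
  sizes <- floor(prop / sum(prop) * n_regions)
  # distribute the remainder deterministically, largest networks first
  rem <- n_regions - sum(sizes)
  if (rem > 0L) {
    ord <- order(prop, decreasing = TRUE)
    sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
  }
  sizes[sizes == 0L] <- 1L
  while (sum(sizes) > n_regions) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1L
  }
  parcellation(rep(names(prop), times = sizes))
}

#' Binary indicator matrix of networks
#'
#' @param parc a [parcellation()].
#' @return a 9 x N 0/1 matrix, rows named by network.
#' @keywords internal
network_indicators <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  ind <- vapply(NETWORK_NAMES,
                function(nw) as.numeric(parc$network == nw),
                numeric(nrow(parc)))
  t(ind)
}

validate_parcellation <- function(parc, n_regions = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (!identical(parc$region_id, seq_len(nrow(parc)) - 1L))
    stop("region ids must be contiguous 0..N-1")
  if (!is.null(n_regions) && nrow(parc) != n_regions)
    stop("parcellation has ", nrow(parc), " regions; expected ", n_regions)
  invisible(parc)
}
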