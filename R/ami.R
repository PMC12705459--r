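#' Adjusted mutual information between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items:
#' AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI]), with the expected mutual
#' information taken under the permutation (hypergeometric) model and
#' arithmetic-mean normalization. AMI is symmetric, equals 1 for identical
#' partitions (up to label permutation), and is near 0 for independent
#' labelings.
#'
#' @param labels1,labels2 integer or factor vectors of equal length.
#' @return a scalar AMI value.
#' @export
ami <- function(labels1, labels2) {
  stopifnot(length(labels1) == length(labels2), length(labels1) > 0L)
  n <- length(labels1)
  tab <- table(labels1, labels2)
  a <- rowSums(tab)
  b <- colSums(tab)
  # entropies and observed MI (natural log)
  h1 <- -sum(ifelse(a > 0, a / n * log(a / n), 0))
  h2 <- -sum(ifelse(b > 0, b / n * log(b / n), 0))
  nij <- as.numeric(tab)
  eij <- outer(a, b) / n
  mi <- sum(ifelse(nij > 0, nij / n * log(nij / as.numeric(eij)), 0))
  # degenerate cases: single cluster on both sides
  if (max(h1, h2) == 0) return(1)
  emi <- expected_mi(a, b, n)
  denom <- (h1 + h2) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

# Expected MI under the hypergeometric model (Vinh et al. formulation),
# computed with log-gamma terms for numerical stability.
expected_mi <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nijs <- lo:hi
      term1 <- nijs / n * log(n * nijs / (ai * bj))
      lterm2 <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgn - lgamma(nijs + 1) - lgamma(ai - nijs + 1) -
        lgamma(bj - nijs + 1) - lgamma(n - ai - bj + nijs + 1)
      emi <- emi + sum(term1 * exp(lterm2))
    }
  }
  emi
}

#' Pairwise AMI matrix of a list of partitions
#'
#' @param label_list list of equal-length label vectors.
#' @return a symmetric matrix with unit diagonal.
#' @export
ami_matrix <- function(label_list) {
  m <- length(label_list)
  stopifnot(m >= 1L)
  out <- diag(1, m)
  if (m >= 2L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        out[i, j] <- out[j, i] <- ami(label_list[[i]], label_list[[j]])
      }
    }
  }
  out
}
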