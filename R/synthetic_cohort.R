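#' Generate a synthetic structural connectome
#'
#' Draws a weighted stochastic block model: regions are assigned to
#' `n_modules` communities, every potential edge is kept with probability
#' `density`, and kept edges receive log-normal weights, doubled within
#' modules. This produces the heavy-tailed, community-structured weights
#' typical of streamline-count connectomes. The matrix is symmetric,
#' nonnegative, zero on the diagonal, and guaranteed connected (the draw is
#' retried with perturbed sub-seeds a bounded number of times).
#'
#' @param n_regions number of regions N (>= 2).
#' @param n_modules number of communities (>= 1).
#' @param density edge retention probability in (0, 1].
#' @param weight_scale median edge weight.
#' @param seed integer seed.
#' @param max_retries connectivity retries before erroring.
#' @return an N x N numeric matrix.
#' @export
generate_connectome <- function(n_regions, n_modules, density,
                                weight_scale = 1, seed,
                                max_retries = 20L) {
  stopifnot(n_regions >= 2, n_modules >= 1, density > 0, density <= 1,
            weight_scale > 0)
  modules <- rep_len(seq_len(n_modules), n_regions)
  for (try in seq_len(max_retries)) {
    sc <- with_seed(derive_seed(seed, "connectome", try - 1L), {
      m <- matrix(0, n_regions, n_regions)
      ut <- which(upper.tri(m))
      keep <- stats::runif(length(ut)) < density
      w <- stats::rlnorm(length(ut), meanlog = log(weight_scale),
                         sdlog = 0.5)
      same <- outer(modules, modules, "==")[upper.tri(m)]
      w <- w * ifelse(same, 2, 1)
      m[ut] <- keep * w
      m + t(m)
    })
    if (is_connected(sc)) return(sc)
  }
  stop("connectome draw disconnected after ", max_retries,
       " retries (seed ", seed, "); increase density")
}

# breadth-first connectivity on the weighted adjacency matrix
is_connected <- function(sc) {
  n <- nrow(sc)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- which(colSums(sc[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Generate planted state centroids
#'
#' Planted states come in anticorrelated pairs mimicking meta-states:
#' centroid 2j-1 is +amplitude on all regions of the j-th template network
#' (DMN first, then VIS, FPN, SOM, ...) with small seeded Gaussian values
#' elsewhere, and centroid 2j is its exact negation. For odd k the last
#' centroid is an unpaired positive pattern on the next network (documented
#' fallback).
#'
#' @param parc a [parcellation()].
#' @param k number of states (<= 2 x number of networks).
#' @param amplitude activation magnitude on the template network (> 0).
#' @param seed integer seed for the off-network background values.
#' @return a k x N matrix.
#' @export
generate_state_centroids <- function(parc, k = 4L, amplitude = 1, seed = 1L) {
  validate_parcellation(parc)
  stopifnot(amplitude > 0)
  if (k > 2L * length(NETWORK_NAMES))
    stop("k = ", k, " exceeds 2 x ", length(NETWORK_NAMES), " networks")
  template_order <- c("DMN", "VIS", "FPN", "SOM", "VAT", "DAT", "LIM",
                      "SUB", "CER")
  n <- nrow(parc)
  cent <- matrix(0, k, n)
  n_pairs <- ceiling(k / 2)
  bg <- with_seed(derive_seed(seed, "centroid-bg"),
                  matrix(stats::rnorm(n_pairs * n, sd = amplitude / 20),
                         n_pairs, n))
  for (j in seq_len(n_pairs)) {
    on <- parc$network == template_order[j]
    v <- bg[j, ]
    v[on] <- amplitude
    cent[2L * j - 1L, ] <- v
    if (2L * j <= k) cent[2L * j, ] <- -v
  }
  cent
}

#' Bundle the ground truth of a synthetic cohort
#'
#' @param centroids k x N planted state centroids.
#' @param dwell_matrix k x k row-stochastic Markov transition matrix; the
#'   default has self-transition probability 0.85 with the remainder spread
#'   uniformly.
#' @param noise_sd frame-level Gaussian noise sd (> 0).
#' @param group_effect named list mapping `"<sex>.<fh_group>"` to a named
#'   numeric vector of per-network centroid scaling factors, e.g.
#'   `list("female.FH+" = c(DMN = 1.2))`. Missing entries mean no scaling.
#' @param seed integer master seed.
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(centroids, dwell_matrix = NULL, noise_sd = 0.5,
                            group_effect = list(), seed = 1L) {
  k <- nrow(centroids)
  if (is.null(dwell_matrix)) {
    stay <- 0.85
    dwell_matrix <- matrix((1 - stay) / (k - 1), k, k)
    diag(dwell_matrix) <- stay
  }
  stopifnot(nrow(dwell_matrix) == k, ncol(dwell_matrix) == k,
            all(dwell_matrix >= 0), noise_sd > 0)
  if (any(abs(rowSums(dwell_matrix) - 1) > 1e-10))
    stop("dwell_matrix rows must sum to 1")
  structure(list(true_centroids = centroids, dwell_matrix = dwell_matrix,
                 noise_sd = noise_sd, group_effect = group_effect,
                 seed = seed),
            class = "synthetic_truth")
}

#' Simulate one subject's state-switching time series
#'
#' A Markov chain over the planted states picks a state per frame; the frame
#' equals the subject's perturbed centroid for that state plus i.i.d.
#' Gaussian noise. Subject-level heterogeneity is an additive Gaussian
#' perturbation of the planted centroids. The returned series is demeaned
#' per region (the contract downstream stages assume); the raw pre-demeaning
#' matrix and the simulated state labels are returned alongside.
#'
#' @param truth a [synthetic_truth()].
#' @param n_frames number of frames (>= k).
#' @param subject_perturbation_sd sd of the additive centroid perturbation.
#' @param seed integer seed.
#' @param centroids optional override of the planted centroids (used to
#'   apply group effects); defaults to `truth$true_centroids`.
#' @param subject_id subject identifier.
#' @return list with `subject_id`, `data` (frames x N, demeaned), `raw`
#'   (pre-demeaning), `labels` (1-based state per frame),
#'   `subject_centroids` (the perturbed centroids).
#' @export
generate_subject_series <- function(truth, n_frames,
                                    subject_perturbation_sd = 0.1,
                                    seed = 1L,
                                    centroids = NULL,
                                    subject_id = "sub-001") {
  stopifnot(inherits(truth, "synthetic_truth"))
  cent <- centroids %||% truth$true_centroids
  k <- nrow(cent); n <- ncol(cent)
  stopifnot(n_frames >= k)
  with_seed(derive_seed(seed, "subject-series"), {
    pert <- cent + matrix(stats::rnorm(k * n, sd = subject_perturbation_sd),
                          k, n)
    labels <- integer(n_frames)
    labels[1L] <- sample.int(k, 1L)
    for (t in seq_len(n_frames - 1L))
      labels[t + 1L] <- sample.int(k, 1L,
                                   prob = truth$dwell_matrix[labels[t], ])
    raw <- pert[labels, , drop = FALSE] +
      matrix(stats::rnorm(n_frames * n, sd = truth$noise_sd), n_frames, n)
    data <- sweep(raw, 2L, colMeans(raw))
    list(subject_id = subject_id, data = data, raw = raw, labels = labels,
         subject_centroids = pert)
  })
}

#' Classify family-history group from a pedigree
#'
#' FH+ if at least one parent or at least two grandparents have an SUD
#' history; FH- if no parents or grandparents do; FH+/- if exactly one
#' grandparent does (and no parent). Vectorized.
#'
#' @param n_parents_sud integer(s) in 0..2.
#' @param n_grandparents_sud integer(s) in 0..4.
#' @return character vector in `c("FH+", "FH-", "FH+/-")`.
#' @export
classify_family_history <- function(n_parents_sud, n_grandparents_sud) {
  stopifnot(all(n_parents_sud %in% 0:2),
            all(n_grandparents_sud %in% 0:4),
            length(n_parents_sud) == length(n_grandparents_sud))
  ifelse(n_parents_sud >= 1 | n_grandparents_sud >= 2, "FH+",
         ifelse(n_grandparents_sud == 1, "FH+/-", "FH-"))
}

#' Family-history density (FHD)
#'
#' Continuous familial load: +1 per parent and +0.5 per grandparent with an
#' SUD history, range 0 (no history) to 4 (both parents and all four
#' grandparents). Vectorized.
#'
#' @inheritParams classify_family_history
#' @return numeric FHD score(s) in [0, 4].
#' @export
compute_fhd <- function(n_parents_sud, n_grandparents_sud) {
  stopifnot(all(n_parents_sud %in% 0:2),
            all(n_grandparents_sud %in% 0:4))
  1.0 * n_parents_sud + 0.5 * n_grandparents_sud
}

# Draw one pedigree consistent with a target FH group.
draw_pedigree <- function(group) {
  switch(group,
         "FH-" = c(0L, 0L),
         "FH+/-" = c(0L, 1L),
         "FH+" = {
           # mix of parent-driven and grandparent-driven positives
           if (stats::runif(1) < 0.7) {
             p <- sample(1:2, 1L, prob = c(0.8, 0.2))
             g <- sample(0:4, 1L, prob = c(0.4, 0.25, 0.2, 0.1, 0.05))
           } else {
             p <- 0L
             g <- sample(2:4, 1L, prob = c(0.7, 0.2, 0.1))
           }
           c(p, g)
         })
}

#' Generate a synthetic cohort
#'
#' Draws pedigrees (default frequencies match the study-scale class
#' imbalance: about 23% FH+, 62% FH-, 15% FH+/-), covariates from documented
#' default distributions, and per-subject state-switching series. Group
#' effects are applied by scaling the named networks' centroid entries for
#' each (sex, fh_group) cell before series generation, so a `group_effect`
#' of all 1 yields series whose law is independent of group labels.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param truth a [synthetic_truth()].
#' @param parc a [parcellation()].
#' @param n_frames frames per subject.
#' @param subject_perturbation_sd sd of subject-level centroid perturbation.
#' @param group_probs probabilities of FH+, FH-, FH+/- (in that order).
#' @param seed integer master seed.
#' @return list with `series` (list of subject series), `covariates`
#'   (data.frame), `labels` (list of ground-truth frame labels), `truth`.
#' @export
generate_cohort <- function(n_subjects, truth, parc,
                            n_frames = 200L,
                            subject_perturbation_sd = 0.1,
                            group_probs = c(0.231, 0.623, 0.146),
                            seed = 1L) {
  stopifnot(n_subjects >= 2, inherits(truth, "synthetic_truth"))
  validate_parcellation(parc, ncol(truth$true_centroids))
  cov <- generate_covariates(n_subjects, group_probs, seed)
  series <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cent <- apply_group_effect(truth$true_centroids, truth$group_effect,
                               cov$sex[i], cov$fh_group[i], parc)
    s <- generate_subject_series(truth, n_frames,
                                 subject_perturbation_sd,
                                 seed = derive_seed(seed, "cohort-subj", i),
                                 centroids = cent,
                                 subject_id = cov$subject_id[i])
    series[[i]] <- s
    labels[[i]] <- s$labels
  }
  list(series = series, covariates = cov, labels = labels, truth = truth)
}

#' Draw a synthetic covariate and pedigree table
#'
#' The covariate block of [generate_cohort()], exposed separately so that
#' statistics can be exercised on precomputed outcomes without simulating
#' time series. Default distributions follow the study-scale cohort
#' (sex ratio, age, income, education, race/ethnicity, scanner mix,
#' sex-dependent pubertal stage, log-normal in-scanner motion).
#'
#' @inheritParams generate_cohort
#' @return a data.frame with one row per subject.
#' @export
generate_covariates <- function(n_subjects,
                                group_probs = c(0.231, 0.623, 0.146),
                                seed = 1L) {
  with_seed(derive_seed(seed, "covariates"), {
    grp <- sample(c("FH+", "FH-", "FH+/-"), n_subjects, replace = TRUE,
                  prob = group_probs)
    ped <- t(vapply(grp, draw_pedigree, integer(2)))
    sex <- sample(c("female", "male"), n_subjects, replace = TRUE,
                  prob = c(0.531, 0.469))
    puberty <- ifelse(sex == "female",
                      sample(1:3, n_subjects, replace = TRUE,
                             prob = c(0.32, 0.26, 0.42)),
                      sample(1:3, n_subjects, replace = TRUE,
                             prob = c(0.76, 0.19, 0.05)))
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n_subjects)),
      sex = sex,
      n_parents_sud = ped[, 1L],
      n_grandparents_sud = ped[, 2L],
      fh_group = classify_family_history(ped[, 1L], ped[, 2L]),
      fhd = compute_fhd(ped[, 1L], ped[, 2L]),
      age_months = stats::rnorm(n_subjects, 120.2, 7.5),
      income_level = sample(1:3, n_subjects, replace = TRUE,
                            prob = c(0.226, 0.299, 0.475)),
      parental_education = sample(1:5, n_subjects, replace = TRUE,
                                  prob = c(0.026, 0.066, 0.098, 0.406,
                                           0.405)),
      race_ethnicity = sample(c("White", "Black", "Hispanic", "Asian",
                                "Other"), n_subjects, replace = TRUE,
                              prob = c(0.627, 0.076, 0.183, 0.020, 0.094)),
      parental_mental_health = stats::rbinom(n_subjects, 1L, 0.3),
      prenatal_exposure = stats::rbinom(n_subjects, 1L, 0.12),
      scanner_model = sample(c("GE750", "Prisma", "PrismaFit"),
                             n_subjects, replace = TRUE,
                             prob = c(0.278, 0.366, 0.356)),
      mean_fd = stats::rlnorm(n_subjects, meanlog = log(0.12), sdlog = 0.5),
      puberty_stage = puberty,
      stringsAsFactors = FALSE
    )
  })
}

# Scale centroid entries on the named networks for one (sex, group) cell.
apply_group_effect <- function(centroids, group_effect, sex, fh_group,
                               parc) {
  key <- paste(sex, fh_group, sep = ".")
  eff <- group_effect[[key]]
  if (is.null(eff)) return(centroids)
  out <- centroids
  for (nw in names(eff)) {
    idx <- which(parc$network == nw)
    out[, idx] <- out[, idx] * eff[[nw]]
  }
  out
}
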