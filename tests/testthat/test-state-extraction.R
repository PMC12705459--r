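test_that("correlation distance matches hand-computed values", {
  v <- c(1, 2, 3)
  expect_equal(correlation_distance(v, v), 0)
  expect_equal(correlation_distance(v, -v), 2)
  expect_equal(correlation_distance(c(1, 2, 3), c(3, 2, 1)), 2)
  expect_error(correlation_distance(c(1, 1, 1), v), "zero-variance")
})

test_that("AMI matches the scikit-learn oracle on frozen fixtures", {
  # expected values computed with sklearn.metrics.adjusted_mutual_info_score
  # (average_method='arithmetic') on these exact label vectors
  set.seed(42)
  a1 <- sample(1:3, 30, TRUE); b1 <- sample(1:4, 30, TRUE)
  a2 <- rep(1:4, each = 25); b2 <- a2[c(2:100, 1)]
  a3 <- sample(1:2, 15, TRUE); b3 <- sample(1:5, 15, TRUE)
  a4 <- rep(1:3, times = c(5, 10, 15)); b4 <- sample(1:3, 30, TRUE)
  expect_equal(ami(a1, b1), 0.0994526837, tolerance = 1e-9)
  expect_equal(ami(a2, b2), 0.8745893941, tolerance = 1e-9)
  expect_equal(ami(a3, b3), 0.0848623035, tolerance = 1e-9)
  expect_equal(ami(a4, b4), -0.0434312231, tolerance = 1e-9)
})

test_that("AMI is symmetric, 1 on self, and label-permutation invariant", {
  set.seed(11)
  for (i in 1:5) {
    a <- sample(1:4, 60, TRUE)
    b <- sample(1:3, 60, TRUE)
    expect_equal(ami(a, a), 1)
    expect_equal(ami(a, b), ami(b, a))
    perm <- sample(1:4)
    expect_equal(ami(perm[a], b), ami(a, b))
  }
})

test_that("k-means separates k distinct frames perfectly", {
  set.seed(2)
  pts <- matrix(rnorm(3 * 8), 3, 8)
  data <- pts[rep(1:3, each = 4), ]
  p <- run_kmeans(data, 3, n_replicates = 5, seed = 1)
  expect_equal(p$within_cluster_distance_total, 0, tolerance = 1e-12)
  expect_equal(ami(p$labels, rep(1:3, each = 4)), 1)
})

test_that("k-means recovers well-separated planted states", {
  w <- make_planted_data(n_subjects = 5, n_frames = 200, noise_sd = 0.3)
  p <- run_kmeans(w$data, 4, seed = 1)
  # >= 99% label agreement up to permutation (Hungarian-style matching)
  m <- match_centroids(p$centroids, w$truth$true_centroids)
  agree <- mean(m$perm[p$labels] == w$labels)
  expect_gte(agree, 0.99)
  # independent seeds agree almost perfectly
  p2 <- run_kmeans(w$data, 4, seed = 99)
  expect_gte(ami(p$labels, p2$labels), 0.99)
  # recovered centroids correlate highly with the planted ones
  expect_true(all(m$matched_cor >= 0.95))
})

test_that("best-of-replicates objective never worsens with more replicates", {
  w <- make_planted_data(n_subjects = 2, n_frames = 80, noise_sd = 0.8)
  objs <- vapply(c(1, 3, 5, 8), function(m)
    run_kmeans(w$data, 4, n_replicates = m,
               seed = 5)$within_cluster_distance_total,
    numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("stability selection maximizes total AMI with ties to lowest index", {
  lab <- rep(1:3, each = 10)
  same <- list(lab, lab, lab)
  sel <- select_stable_partition(same)
  expect_identical(sel$index, 1L)
  expect_true(all(abs(sel$ami_matrix - 1) < 1e-12))
  # nine identical + one random: one of the nine wins
  set.seed(8)
  parts <- c(replicate(9, lab, simplify = FALSE),
             list(sample(1:3, 30, TRUE)))
  sel2 <- select_stable_partition(parts)
  expect_lte(sel2$index, 9L)
  # a partition's AMI row is invariant to relabeling its clusters
  perm <- c(3L, 1L, 2L)
  sel3 <- select_stable_partition(c(parts[10], list(perm[lab]), parts[1]))
  expect_equal(sel3$ami_matrix[2, ], sel3$ami_matrix[3, ],
               tolerance = 1e-12)
})

test_that("elbow criterion recovers the planted k and honors thresholds", {
  w <- make_planted_data(n_subjects = 8, n_frames = 150, noise_sd = 0.4)
  ck <- choose_k(w$data, k_range = 2:8, n_replicates = 5, seed = 7)
  expect_identical(ck$k_star, 4L)
  # explained variance is nondecreasing within replicate tolerance
  expect_true(all(diff(ck$explained_variance_by_k) >= -1e-6))
  expect_true(all(ck$explained_variance_by_k >= 0 &
                    ck$explained_variance_by_k <= 1))
  # an unreachable threshold returns the first k of the range
  ck2 <- choose_k(w$data[1:300, ], k_range = 2:4, gain_threshold = 1.0,
                  n_replicates = 2, seed = 1)
  expect_identical(ck2$k_star, 2L)
})

test_that("state labeling follows signed cosine similarity with tie-breaks", {
  parc <- default_parcellation()
  ind <- stateTE:::network_indicators(parc)
  expect_identical(label_states(rbind(ind["DMN", ]), parc), "DMN+")
  expect_identical(label_states(rbind(-ind["DMN", ]), parc), "DMN-")
  expect_identical(label_states(rbind(ind["VIS", ], -ind["FPN", ]), parc),
                   c("VIS+", "FPN-"))
  # exact tie between two networks (equal cosine with both unit
  # indicators): lexicographically first, with warning
  tie <- ind["CER", ] / sqrt(sum(ind["CER", ])) +
    ind["VIS", ] / sqrt(sum(ind["VIS", ]))
  expect_warning(lab <- label_states(rbind(tie), parc), "tie")
  expect_identical(lab, "CER+")
  expect_error(label_states(matrix(0, 1, nrow(parc)), parc), "all-zero")
})

test_that("labeling is equivariant under region permutation", {
  w <- make_planted_data(n_subjects = 3, n_frames = 100)
  p <- run_kmeans(w$data, 4, seed = 2)
  labs <- label_states(p$centroids, w$parc)
  set.seed(21); perm <- sample(ncol(w$data))
  parc_perm <- parcellation(w$parc$network[perm],
                            w$parc$region_name[perm])
  labs_perm <- label_states(p$centroids[, perm, drop = FALSE], parc_perm)
  expect_identical(labs, labs_perm)
})

test_that("frame assignment picks the nearest centroid", {
  w <- make_planted_data(n_subjects = 3, n_frames = 100)
  cent <- w$truth$true_centroids
  # frames equal to centroids map to their own index
  expect_identical(assign_frames(cent, cent), 1:4)
  # a frame equal to -centroid 1 lands on its anticorrelated partner
  expect_identical(assign_frames(rbind(-cent[1, ]), cent[1:2, ]), 2L)
  # zero-variance frame is unassignable
  expect_warning(lab <- assign_frames(rbind(rep(0, ncol(cent)), cent[1, ]),
                                      cent), "unassigned")
  expect_identical(lab, c(NA_integer_, 1L))
})

test_that("subject centroids are frame means with group-centroid imputation", {
  w <- make_planted_data(n_subjects = 2, n_frames = 60)
  g <- w$truth$true_centroids
  series <- g[rep(2L, 10L), ]
  sc <- subject_centroids(series, rep(2L, 10L), g)
  expect_equal(sc$centroids[2, ], g[2, ])
  expect_identical(sc$imputed_states, c(1L, 3L, 4L))
  expect_identical(sum(sc$frames_per_state), 10L)
  # states with frames equal the mean of those frames
  s <- w$subjects[[1]]
  lab <- assign_frames(s$data, g)
  sc2 <- subject_centroids(s$data, lab, g)
  for (j in which(sc2$frames_per_state > 0))
    expect_equal(sc2$centroids[j, ],
                 colMeans(s$data[lab == j, , drop = FALSE]))
  expect_identical(sum(sc2$frames_per_state), nrow(s$data))
})

test_that("extract_brain_states ties the stages together consistently", {
  w <- make_planted_data(n_subjects = 4, n_frames = 100)
  st <- extract_brain_states(w$subjects, w$parc, k = 4,
                             n_replicates = 3, stability_runs = 3,
                             seed = 9)
  expect_identical(st$k, 4L)
  expect_length(st$labels, 4L)
  expect_true(all(grepl("^(VIS|SOM|DAT|VAT|LIM|FPN|DMN|SUB|CER)[+-]$",
                        st$labels)))
  expect_identical(dim(st$ami_matrix), c(3L, 3L))
  # per-subject frame labels are the group partition's restriction
  expect_identical(unname(unlist(st$frame_labels)), st$partition$labels)
  # meta-state structure: recovered states form anticorrelated pairs
  m <- match_centroids(st$group_centroids, w$truth$true_centroids)
  expect_true(all(m$matched_cor >= 0.95))
})
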