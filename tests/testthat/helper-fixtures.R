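# Shared fixture builders. Everything is generated in code at test time.

# Tiny 9-region parcellation: one region per network.
tiny_parcellation <- function() {
  parcellation(NETWORK_NAMES)
}

# Small planted world used across state-extraction tests.
make_planted_data <- function(n_subjects = 6L, n_frames = 120L,
                              noise_sd = 0.3, amplitude = 1,
                              perturbation_sd = 0.05, seed = 1L,
                              k = 4L) {
  parc <- default_parcellation()
  cent <- generate_state_centroids(parc, k = k, amplitude = amplitude,
                                   seed = seed)
  truth <- synthetic_truth(cent, noise_sd = noise_sd, seed = seed)
  subs <- lapply(seq_len(n_subjects), function(i)
    generate_subject_series(truth, n_frames, perturbation_sd,
                            seed = seed * 1000L + i,
                            subject_id = sprintf("sub-%03d", i)))
  list(parc = parc, truth = truth, subjects = subs,
       data = do.call(rbind, lapply(subs, `[[`, "data")),
       labels = unlist(lapply(subs, `[[`, "labels")))
}

# Small test system for control-energy tests.
make_test_system <- function(n = 10L, T_horizon = 1.501, seed = 3L) {
  sc <- generate_connectome(n, 2L, 0.5, seed = seed)
  sys <- stabilized_system(stabilize_system(sc), T_horizon = T_horizon)
  list(sc = sc, system = sys,
       gramian = controllability_gramian(sys))
}

# Independent discrete-time oracle for minimum control energy: the
# least-norm input of the Euler-discretized reachability system. With
# x_{t+1} = (I + A dt) x_t + dt B u_t, the least-squared-norm input
# solving the reachability constraint has continuous-time energy
# delta_d' Wd^{-1} delta_d where Wd = sum_i Ad^i B B' (Ad')^i dt — the
# Gramian form of the pseudoinverse solution (computed without forming
# the n x (n_steps n) reachability matrix).
discrete_energy_oracle <- function(system, x0, xT, n_steps = 20000L) {
  n <- system$n
  dt <- system$T / n_steps
  Ad <- diag(n) + system$A * dt
  BBt <- system$B %*% t(system$B)
  Wd <- matrix(0, n, n)
  P <- diag(n)
  for (i in seq_len(n_steps)) {
    Wd <- Wd + P %*% BBt %*% t(P) * dt
    P <- Ad %*% P
  }
  delta <- xT - P %*% x0
  as.numeric(t(delta) %*% solve(Wd, delta))
}

# Greedy matching of recovered to planted centroids by correlation.
match_centroids <- function(recovered, planted) {
  k <- nrow(planted)
  cors <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    cors[i, j] <- stats::cor(recovered[i, ], planted[j, ])
  perm <- integer(k)
  cc <- cors
  for (step in seq_len(k)) {
    idx <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    perm[idx[1L]] <- idx[2L]
    cc[idx[1L], ] <- NA
    cc[, idx[2L]] <- NA
  }
  list(perm = perm,
       matched_cor = cors[cbind(seq_len(k), perm)])
}
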