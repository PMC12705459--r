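test_that("connectome stabilization matches forced examples", {
  expect_equal(stabilize_system(matrix(0, 3, 3)), -diag(3))
  A <- stabilize_system(matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(A, matrix(c(-1, 0.5, 0.5, -1), 2, 2))
  expect_equal(sort(eigen(A, symmetric = TRUE)$values), c(-1.5, -0.5))
  # random modular connectome: all eigenvalues strictly negative
  sc <- generate_connectome(20, 4, 0.3, seed = 2)
  ev <- eigen(stabilize_system(sc), symmetric = TRUE, only.values = TRUE)
  expect_lt(max(ev$values), 0)
  expect_error(stabilize_system(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(stabilize_system(matrix(c(0, -1, -1, 0), 2, 2)),
               "nonnegative")
})

test_that("Gramian matches the analytic closed form and is symmetric PD", {
  sys <- stabilized_system(-diag(4), T_horizon = 1)
  W <- controllability_gramian(sys)
  expect_equal(W$W, (1 - exp(-2)) / 2 * diag(4), tolerance = 1e-10)
  ts <- make_test_system()
  W2 <- ts$gramian$W
  expect_lt(max(abs(W2 - t(W2))), 1e-10 * max(abs(W2)))
  expect_gt(min(eigen(W2, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("Van Loan and Simpson quadrature Gramians agree", {
  ts <- make_test_system(n = 10)
  Wq <- controllability_gramian(ts$system, method = "quadrature",
                                n_nodes = 2001)
  rel <- max(abs(ts$gramian$W - Wq$W)) / max(abs(ts$gramian$W))
  expect_lt(rel, 1e-6)
})

test_that("Gramian grows monotonically with the horizon", {
  sc <- generate_connectome(12, 3, 0.4, seed = 5)
  A <- stabilize_system(sc)
  Ts <- c(0.5, 1.501, 3, 6)
  Ws <- lapply(Ts, function(T_h)
    controllability_gramian(stabilized_system(A, T_horizon = T_h))$W)
  for (i in seq_len(length(Ts) - 1)) {
    d <- Ws[[i + 1]] - Ws[[i]]
    expect_gte(min(eigen(d, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("minimum-energy control has the quadratic-form structure", {
  ts <- make_test_system()
  n <- ts$system$n
  # the origin is an equilibrium: zero transition costs nothing
  tr0 <- min_control_energy(ts$system, ts$gramian, rep(0, n), rep(0, n))
  expect_equal(tr0$total_energy, 0, tolerance = 1e-12)
  expect_true(all(abs(tr0$u) < 1e-12))
  # doubling the displacement quadruples the energy
  set.seed(3); xT <- rnorm(n)
  e1 <- min_control_energy(ts$system, ts$gramian, rep(0, n), xT)
  e2 <- min_control_energy(ts$system, ts$gramian, rep(0, n), 2 * xT)
  expect_equal(e2$total_energy / e1$total_energy, 4, tolerance = 1e-6)
  # endpoint is reached and the energy decompositions agree
  expect_lt(e1$endpoint_error, 1e-4)
  expect_equal(sum(e1$regional_energy), e1$total_energy,
               tolerance = 1e-12)
  expect_equal(e1$total_energy, e1$total_energy_closed, tolerance = 1e-4)
})

test_that("three independent energy routes agree on small systems", {
  for (n in c(3, 4)) {
    ts <- make_test_system(n = n, seed = n)
    set.seed(n); x0 <- rnorm(n); xT <- rnorm(n)
    tr <- min_control_energy(ts$system, ts$gramian, x0, xT,
                             n_steps = 1000)
    closed <- tr$total_energy_closed
    trapz <- tr$total_energy
    oracle <- discrete_energy_oracle(ts$system, x0, xT, n_steps = 20000)
    expect_lt(abs(trapz - closed) / closed, 0.005)
    expect_lt(abs(oracle - closed) / closed, 0.005)
    expect_lt(abs(oracle - trapz) / trapz, 0.005)
  }
})

test_that("energy is permutation-equivariant in the regions", {
  ts <- make_test_system(n = 8, seed = 2)
  n <- 8
  set.seed(4); x0 <- rnorm(n); xT <- rnorm(n); perm <- sample(n)
  tr <- min_control_energy(ts$system, ts$gramian, x0, xT)
  sc_p <- ts$sc[perm, perm]
  sys_p <- stabilized_system(stabilize_system(sc_p),
                             T_horizon = ts$system$T)
  tr_p <- min_control_energy(sys_p, controllability_gramian(sys_p),
                             x0[perm], xT[perm])
  expect_equal(tr_p$total_energy, tr$total_energy, tolerance = 1e-10)
  expect_equal(tr_p$regional_energy, tr$regional_energy[perm],
               tolerance = 1e-10)
})

test_that("longer horizons never cost more for a fixed transition", {
  sc <- generate_connectome(10, 2, 0.5, seed = 9)
  A <- stabilize_system(sc)
  set.seed(9); x0 <- rnorm(10); xT <- rnorm(10)
  energies <- vapply(c(0.5, 1, 1.501, 3, 6, 10), function(T_h) {
    sys <- stabilized_system(A, T_horizon = T_h)
    stateTE:::te_totals(sys, controllability_gramian(sys),
                        rbind(x0, xT))[1, 2]
  }, numeric(1))
  expect_true(all(diff(energies) <= 1e-8))
})

test_that("pairwise TE tensor is nonnegative and sums to the totals", {
  ts <- make_test_system(n = 12, seed = 6)
  set.seed(6)
  cent <- matrix(rnorm(4 * 12), 4, 12)
  tensor <- pairwise_te(ts$system, ts$gramian, cent, n_steps = 400)
  expect_identical(dim(tensor), c(12L, 4L, 4L))
  expect_true(all(tensor >= 0))
  # summing the tensor over regions reproduces each transition's total
  # energy (closed form) within discretization tolerance
  totals <- apply(tensor, c(2, 3), sum)
  expect_equal(sum(abs(totals - attr(tensor, "total"))) /
                 sum(abs(totals)), 0, tolerance = 1e-4)
  # persistence energies (diagonal) are nonzero: states are not equilibria
  expect_true(all(diag(totals) > 0))
  # the TE matrix is generically asymmetric
  expect_gt(max(abs(totals - t(totals))), 1e-6)
  # zero centroids cost nothing
  z <- pairwise_te(ts$system, ts$gramian, matrix(0, 2, 12), n_steps = 100)
  expect_true(all(z == 0))
})

test_that("horizon selection tracks the energy-probability anticorrelation", {
  # 2-state system where the cheap transition is made frequent by design
  sc <- generate_connectome(10, 2, 0.5, seed = 12)
  A <- stabilize_system(sc)
  set.seed(12)
  cent <- matrix(rnorm(2 * 10), 2, 10)
  sys <- stabilized_system(A, T_horizon = 1.501)
  te <- stateTE:::te_totals(sys, controllability_gramian(sys), cent)
  # dwell probabilities anti-ranked against the pilot TE matrix
  pr <- -rank(te)
  P <- matrix(exp(pr), 2, 2); P <- P / rowSums(P)
  labels <- list()
  set.seed(13)
  lab <- integer(4000); lab[1] <- 1
  for (t in 2:4000) lab[t] <- sample(1:2, 1, prob = P[lab[t - 1], ])
  sel <- select_time_horizon(sc, cent, list(lab),
                             t_grid = c(0.1, 0.5, 1.501, 5))
  expect_true(all(sel$sweep$spearman_rho < 0))
  expect_true(sel$T_star %in% sel$sweep$T)
  # single-point grid returns that T
  sel1 <- select_time_horizon(sc, cent, list(lab), t_grid = 2)
  expect_identical(sel1$T_star, 2)
  # rank correlation is invariant to simultaneous state relabeling
  perm <- c(2L, 1L)
  sel_p <- select_time_horizon(sc, cent[perm, ], list(perm[lab]),
                               t_grid = c(0.1, 0.5, 1.501, 5))
  expect_equal(sel_p$sweep$spearman_rho, sel$sweep$spearman_rho,
               tolerance = 1e-10)
})
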