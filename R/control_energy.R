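#' Stabilize a structural connectome into continuous LTI dynamics
#'
#' Builds the drift matrix of the linear model x'(t) = A x(t) + B u(t) from
#' a structural connectivity matrix: A_norm = sc / (lambda_max(sc) + 1) - I.
#' For a symmetric nonnegative sc all eigenvalues of A_norm are strictly
#' negative, so the uncontrolled system decays to the origin (the mean BOLD
#' signal, since series are demeaned).
#'
#' @param sc N x N symmetric nonnegative matrix with zero diagonal.
#' @return the N x N stabilized matrix A_norm.
#' @export
stabilize_system <- function(sc) {
  sc <- as.matrix(sc)
  if (!isSymmetric(sc, tol = 1e-10))
    stop("structural connectome must be symmetric")
  if (any(sc < 0))
    stop("structural connectome must be nonnegative")
  if (any(abs(diag(sc)) > 1e-12))
    stop("structural connectome must have a zero diagonal")
  lam_max <- max(eigen(sc, symmetric = TRUE, only.values = TRUE)$values)
  sc / (lam_max + 1) - diag(nrow(sc))
}

#' Bundle stabilized dynamics, control set and horizon
#'
#' @param A_norm stabilized drift matrix (see [stabilize_system()]).
#' @param T_horizon control horizon (> 0); default 1.501, the horizon at
#'   which transition energy is most strongly anticorrelated with empirical
#'   transition probability (see [select_time_horizon()]).
#' @param B N x N control matrix; identity = uniform control (every region
#'   receives input).
#' @return a `stabilized_system` list.
#' @export
stabilized_system <- function(A_norm, T_horizon = 1.501, B = NULL) {
  A_norm <- as.matrix(A_norm)
  n <- nrow(A_norm)
  stopifnot(ncol(A_norm) == n, T_horizon > 0)
  if (is.null(B)) B <- diag(n)
  stopifnot(nrow(B) == n, ncol(B) == n)
  structure(list(A = A_norm, B = B, T = T_horizon, n = n),
            class = "stabilized_system")
}

#' Finite-horizon controllability Gramian
#'
#' W(T) = integral over [0, T] of exp(A t) B B' exp(A' t) dt. The default
#' route is the Van Loan block-matrix-exponential construction (a single
#' 2N x 2N matrix exponential, no stiff integration); `method =
#' "quadrature"` computes the same integral by composite Simpson rule and
#' serves as an independent cross-check. W is symmetrized and must be
#' positive definite; a condition number above `cond_ceiling` errors with
#' advice (the Gramian of a stable system loses rank as T -> 0).
#'
#' @param system a [stabilized_system()].
#' @param method "vanloan" (default) or "quadrature".
#' @param n_nodes quadrature nodes (odd; Simpson) when
#'   `method = "quadrature"`.
#' @param cond_ceiling maximum admissible condition number.
#' @return a `gramian` list: `W`, `T`, `condition_number`.
#' @export
controllability_gramian <- function(system, method = c("vanloan",
                                                       "quadrature"),
                                    n_nodes = 2001L, cond_ceiling = 1e12) {
  stopifnot(inherits(system, "stabilized_system"))
  method <- match.arg(method)
  A <- system$A; B <- system$B; T_h <- system$T; n <- system$n
  if (method == "vanloan") {
    # exp([[A, BB'], [0, -A']] T): W(T) = E12 %*% t(E11)
    M <- rbind(cbind(A, B %*% t(B)),
               cbind(matrix(0, n, n), -t(A)))
    E <- as.matrix(Matrix::expm(Matrix::Matrix(M * T_h)))
    E11 <- E[seq_len(n), seq_len(n)]
    E12 <- E[seq_len(n), n + seq_len(n)]
    W <- E12 %*% t(E11)
  } else {
    if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
    ts <- seq(0, T_h, length.out = n_nodes)
    h <- ts[2L] - ts[1L]
    wts <- c(1, rep(c(4, 2), length.out = n_nodes - 2L), 1)
    # advance exp(A t) by repeated multiplication with exp(A h)
    Eh <- as.matrix(Matrix::expm(Matrix::Matrix(A * h)))
    Et <- diag(n)
    BBt <- B %*% t(B)
    W <- matrix(0, n, n)
    for (i in seq_len(n_nodes)) {
      W <- W + wts[i] * (Et %*% BBt %*% t(Et))
      if (i < n_nodes) Et <- Et %*% Eh
    }
    W <- W * h / 3
  }
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("Gramian is not positive definite (min eigenvalue ",
         format(min(ev)), "); the system may be uncontrollable")
  cond <- max(ev) / min(ev)
  if (cond > cond_ceiling)
    stop("Gramian condition number ", format(cond, digits = 3),
         " exceeds ", format(cond_ceiling),
         "; increase the horizon T or regularize")
  structure(list(W = W, T = T_h, condition_number = cond),
            class = "gramian")
}

#' Minimum control energy for one state transition
#'
#' Closed-form minimum-energy control of the LTI system over [0, T]:
#' u*(t) = B' exp(A'(T - t)) W^-1 (xT - exp(A T) x0). The optimal input is
#' evaluated on a uniform grid of `n_steps` intervals; regional energy is
#' the trapezoidal integral of u_i(t)^2 (or |u_i(t)| with `cost = "abs"`,
#' kept for sensitivity analyses), and the state trajectory is propagated
#' by exponential-trapezoid stepping to verify the endpoint. The total
#' energy is cross-checked against the closed form delta' W^-1 delta.
#'
#' @param system a [stabilized_system()].
#' @param gramian the matching [controllability_gramian()].
#' @param x0,xT initial and target N-vectors.
#' @param n_steps grid intervals (default 1000).
#' @param cost "sq" for integral of u^2 (energy), "abs" for integral of
#'   absolute input.
#' @param endpoint_tol relative endpoint tolerance.
#' @return a `control_trajectory` list: `time_grid`, `u`, `x`,
#'   `regional_energy`, `total_energy`, `total_energy_closed`,
#'   `endpoint_error`.
#' @export
min_control_energy <- function(system, gramian, x0, xT, n_steps = 1000L,
                               cost = c("sq", "abs"),
                               endpoint_tol = 1e-4) {
  stopifnot(inherits(system, "stabilized_system"),
            inherits(gramian, "gramian"))
  if (!isTRUE(all.equal(system$T, gramian$T)))
    stop("Gramian horizon (", gramian$T, ") does not match system T (",
         system$T, ")")
  cost <- match.arg(cost)
  n <- system$n
  stopifnot(length(x0) == n, length(xT) == n, all(is.finite(c(x0, xT))))
  traj <- propagate_transitions(system, gramian, matrix(x0, ncol = 1L),
                                matrix(xT, ncol = 1L), n_steps,
                                keep_traj = TRUE, cost = cost)
  endpoint <- traj$endpoint_error[1L]
  scale <- max(sqrt(sum(xT^2)), 1e-12)
  if (endpoint / scale > endpoint_tol && endpoint > endpoint_tol)
    stop("endpoint error ", format(endpoint), " exceeds tolerance ",
         endpoint_tol, " (relative to ||xT|| = ", format(scale), ")")
  structure(list(time_grid = traj$time_grid,
                 u = traj$u[[1L]], x = traj$x[[1L]],
                 regional_energy = traj$regional[, 1L],
                 total_energy = traj$total[1L],
                 total_energy_closed = traj$total_closed[1L],
                 endpoint_error = endpoint),
            class = "control_trajectory")
}

# Core engine: propagate m transitions at once. X0, XT are N x m matrices.
# Returns regional energies (N x m), totals, closed-form totals, endpoint
# errors, and optionally full u/x trajectories (lists of (n_steps+1) x N).
propagate_transitions <- function(system, gramian, X0, XT, n_steps,
                                  keep_traj = FALSE, cost = "sq") {
  A <- system$A; B <- system$B; T_h <- system$T; n <- system$n
  m <- ncol(X0)
  dt <- T_h / n_steps
  EA_T <- as.matrix(Matrix::expm(Matrix::Matrix(A * T_h)))
  Delta <- XT - EA_T %*% X0
  R <- chol(gramian$W)
  Z <- backsolve(R, forwardsolve(t(R), Delta))       # W^-1 Delta, N x m
  total_closed <- colSums(Delta * Z)
  # u(t_i) = B' exp(A'(T - t_i)) Z; step exp(A' dt) backwards from t = T
  P <- as.matrix(Matrix::expm(Matrix::Matrix(t(A) * dt)))
  V <- vector("list", n_steps + 1L)
  V[[n_steps + 1L]] <- Z
  for (i in n_steps:1L) V[[i]] <- P %*% V[[i + 1L]]
  Bt <- t(B)
  # trapezoidal accumulation of the chosen cost, plus state propagation
  Q <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
  X <- X0
  regional <- matrix(0, n, m)
  cost_fun <- if (cost == "sq") function(u) u^2 else function(u) abs(u)
  u_prev <- Bt %*% V[[1L]]
  regional <- regional + cost_fun(u_prev) * (dt / 2)
  u_list <- x_list <- NULL
  if (keep_traj) {
    u_list <- lapply(seq_len(m), function(j)
      matrix(NA_real_, n_steps + 1L, n))
    x_list <- lapply(seq_len(m), function(j)
      matrix(NA_real_, n_steps + 1L, n))
    for (j in seq_len(m)) {
      u_list[[j]][1L, ] <- u_prev[, j]
      x_list[[j]][1L, ] <- X[, j]
    }
  }
  for (i in seq_len(n_steps)) {
    u_next <- Bt %*% V[[i + 1L]]
    # exponential trapezoid: x_{i+1} = Q x_i + dt/2 (Q B u_i + B u_{i+1})
    X <- Q %*% X + (dt / 2) * (Q %*% (B %*% u_prev) + B %*% u_next)
    w <- if (i < n_steps) dt else dt / 2
    regional <- regional + cost_fun(u_next) * w
    if (keep_traj) {
      for (j in seq_len(m)) {
        u_list[[j]][i + 1L, ] <- u_next[, j]
        x_list[[j]][i + 1L, ] <- X[, j]
      }
    }
    u_prev <- u_next
  }
  endpoint <- sqrt(colSums((X - XT)^2))
  list(time_grid = seq(0, T_h, length.out = n_steps + 1L),
       regional = regional, total = colSums(regional),
       total_closed = total_closed, endpoint_error = endpoint,
       u = u_list, x = x_list)
}

#' Pairwise regional transition energies for one subject
#'
#' Computes the minimum-control-energy transition between every ordered
#' pair of the subject's k state centroids (including the diagonal
#' persistence entries, where initial and target states coincide — nonzero
#' because states are not equilibria of the decaying dynamics). Entry
#' [i, s, t] is region i's energy for the transition from state s to state
#' t.
#'
#' @param system a [stabilized_system()].
#' @param gramian the matching [controllability_gramian()].
#' @param centroids k x N matrix of state centroids.
#' @param n_steps trapezoid intervals per transition.
#' @param endpoint_tol relative endpoint tolerance.
#' @param cost "sq" or "abs" (see [min_control_energy()]).
#' @return an N x k x k array of class `regional_te_tensor` with attributes
#'   `total` (k x k closed-form totals).
#' @export
pairwise_te <- function(system, gramian, centroids, n_steps = 1000L,
                        endpoint_tol = 1e-4, cost = "sq") {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids); n <- ncol(centroids)
  stopifnot(n == system$n)
  from <- rep(seq_len(k), times = k)
  to <- rep(seq_len(k), each = k)
  X0 <- t(centroids)[, from, drop = FALSE]
  XT <- t(centroids)[, to, drop = FALSE]
  res <- propagate_transitions(system, gramian, X0, XT, n_steps,
                               keep_traj = FALSE, cost = cost)
  scale <- pmax(sqrt(colSums(XT^2)), 1e-12)
  bad <- res$endpoint_error / scale > endpoint_tol &
    res$endpoint_error > endpoint_tol
  if (any(bad))
    stop("endpoint error exceeded tolerance for transition(s) ",
         paste(paste0(from[bad], "->", to[bad]), collapse = ", "))
  tensor <- array(0, dim = c(n, k, k))
  for (j in seq_along(from)) tensor[, from[j], to[j]] <- res$regional[, j]
  total <- matrix(res$total_closed, k, k)            # [from, to]
  structure(tensor, total = total, class = "regional_te_tensor")
}

#' Select the control horizon by the energy-probability relationship
#'
#' For each candidate horizon T, computes the k x k matrix of pairwise
#' global transition energies between the group state centroids and the
#' Spearman correlation of its k^2 entries with the empirical transition
#' probabilities (row-normalized pooled counts of consecutive within-
#' subject frame-label pairs, persistence included). The selected T* is the
#' grid point with the most negative correlation — easy transitions should
#' be the frequent ones.
#'
#' @param sc N x N structural connectome.
#' @param centroids k x N group state centroids.
#' @param frame_labels list of per-subject label sequences.
#' @param t_grid candidate horizons (> 0); default 50 log-spaced points on
#'   [0.001, 10].
#' @return list with `T_star`, `sweep` (data.frame T, spearman_rho), and
#'   `transition_prob` (the empirical k x k matrix).
#' @export
select_time_horizon <- function(sc, centroids, frame_labels,
                                t_grid = NULL) {
  if (is.null(t_grid))
    t_grid <- exp(seq(log(0.001), log(10), length.out = 50L))
  stopifnot(length(t_grid) >= 1L, all(t_grid > 0))
  k <- nrow(centroids)
  P <- transition_probabilities(frame_labels, k)
  A <- stabilize_system(sc)
  rho <- vapply(t_grid, function(T_h) {
    sys <- stabilized_system(A, T_horizon = T_h)
    W <- controllability_gramian(sys)
    te <- te_totals(sys, W, centroids)
    suppressWarnings(stats::cor(as.vector(te), as.vector(P),
                                method = "spearman"))
  }, numeric(1))
  list(T_star = t_grid[which.min(rho)],
       sweep = data.frame(T = t_grid, spearman_rho = rho),
       transition_prob = P)
}

# Empirical k x k transition probability from pooled consecutive label
# pairs; zero rows fall back to uniform with a warning.
transition_probabilities <- function(frame_labels, k) {
  counts <- matrix(0, k, k)
  for (lab in frame_labels) {
    lab <- lab[!is.na(lab)]
    if (length(lab) < 2L) next
    a <- lab[-length(lab)]; b <- lab[-1L]
    counts <- counts + table(factor(a, levels = seq_len(k)),
                             factor(b, levels = seq_len(k)))
  }
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    warning("state(s) ", paste(which(rs == 0), collapse = ", "),
            " never visited; using uniform row fallback")
    counts[rs == 0, ] <- 1
    rs <- rowSums(counts)
  }
  counts / rs
}

# Closed-form k x k total transition energies (delta' W^-1 delta), fast
# path for horizon sweeps.
te_totals <- function(system, gramian, centroids) {
  k <- nrow(centroids)
  from <- rep(seq_len(k), times = k)
  to <- rep(seq_len(k), each = k)
  EA_T <- as.matrix(Matrix::expm(Matrix::Matrix(system$A * system$T)))
  X0 <- t(centroids)[, from, drop = FALSE]
  XT <- t(centroids)[, to, drop = FALSE]
  Delta <- XT - EA_T %*% X0
  R <- chol(gramian$W)
  Z <- backsolve(R, forwardsolve(t(R), Delta))
  matrix(colSums(Delta * Z), k, k)
}
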