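#' Iterate a population under one or more environments
#'
#' Repeatedly applies environment matrices:
#' `N(t) = A(t) A(t-1) ... A(1) N(0)`. To permit runs far beyond the
#' convergence time without floating-point overflow, the iteration evolves
#' the structure vector together with the log total population; absolute
#' populations are reconstructed as `exp(log_total) * structure`.
#'
#' @param envs a single environment matrix (applied at every step) or a list
#'   of length `T` giving the environment sequence `A(1), ..., A(T)`.
#' @param N0 initial [population_state()] or numeric vector.
#' @param T number of steps (`T >= 1`).
#' @return Object of class `"trajectory"`: `times` (0..T), `structures`
#'   (a `(T+1) x N_c` matrix of simplex rows), `log_total` (log of the total
#'   population at each time).
#' @seealso [trajectory_states()] to recover absolute populations.
#' @export
iterate <- function(envs, N0, T) {
  if (T < 1) stop("T must be at least 1")
  single <- !is.list(envs)
  if (!single && length(envs) != T)
    stop("a sequence of environments must have length T")
  N <- if (inherits(N0, "population_state")) N0$sizes else as.numeric(N0)
  n <- length(N)
  x <- structure_vector(N)
  logNT <- log(sum(N))
  X <- matrix(NA_real_, T + 1, n)
  lt <- numeric(T + 1)
  X[1, ] <- x
  lt[1] <- logNT
  for (t in seq_len(T)) {
    A <- env_matrix(if (single) envs else envs[[t]])
    if (ncol(A) != n) stop("dimension mismatch at step ", t)
    y <- drop(A %*% x)
    g <- sum(y)                      # one-step growth factor of N_T
    if (g <= 0) stop("total population lost at step ", t)
    x <- y / g
    logNT <- logNT + log(g)
    X[t + 1, ] <- x
    lt[t + 1] <- logNT
  }
  structure(list(times = 0:T, structures = X, log_total = lt),
            class = "trajectory")
}

#' Absolute populations along a trajectory
#'
#' @param traj a `"trajectory"`.
#' @return Matrix of absolute populations, rows indexed by time. Infinite
#'   values indicate totals beyond double-precision range (the structure and
#'   `log_total` remain exact in that regime).
#' @export
trajectory_states <- function(traj) {
  exp(traj$log_total) * traj$structures
}

#' Spectral summary of an environment
#'
#' Eigen-decomposition of the environment with eigenvalues sorted by
#' descending real part (ties broken by descending modulus, then ascending
#' imaginary part). For a validated environment the leading eigenvalue
#' \eqn{\lambda_0} is real and positive and its eigenvector is entrywise
#' positive (sign-normalized so its largest-magnitude entry is positive and
#' rescaled to the simplex). The solution of the iteration is
#' \eqn{N(t) = \sum_i \lambda_i^t c_i e_i} with projection coefficients
#' `c = solve(E, N0)`.
#'
#' @param env environment matrix.
#' @param N0 optional initial population (for the projection coefficients).
#' @return List of class `"spectral_summary"`: `values`, `vectors` (columns),
#'   `leading_value`, `leading_vector` (simplex-normalized), `coefficients`
#'   (or NULL), `t_star`, `condition`.
#' @export
spectral_summary <- function(env, N0 = NULL) {
  A <- env_matrix(env)
  eg <- eigen(A)
  ord <- order(-Re(eg$values), -Mod(eg$values), Im(eg$values))
  values <- eg$values[ord]
  vectors <- eg$vectors[, ord, drop = FALSE]
  sv <- svd(vectors, nu = 0, nv = 0)$d
  kappa <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (!is.finite(kappa) || kappa > 1e12)
    warning("eigenvector basis ill-conditioned (condition number ",
            format(kappa, digits = 3), "); reconstruction may be inaccurate")
  e0 <- vectors[, 1]
  e0 <- e0 * sign(Re(e0[which.max(Mod(e0))]))
  e0 <- Re(e0)
  lead <- Re(values[1])
  e0_simplex <- e0 / sum(e0)
  coef <- if (!is.null(N0)) {
    N <- if (inherits(N0, "population_state")) N0$sizes else as.numeric(N0)
    solve(vectors, N)
  }
  sub <- if (length(values) > 1) Mod(values[2]) else 0
  t_star <- if (sub <= 0) 0 else if (sub >= lead) Inf else 1 / log(lead / sub)
  structure(list(values = values, vectors = vectors, leading_value = lead,
                 leading_vector = e0_simplex, coefficients = coef,
                 t_star = t_star, condition = kappa),
            class = "spectral_summary")
}

#' Deterministic convergence time of an environment
#'
#' The longest relaxation time of the relative structure,
#' \eqn{t_* = 1 / \ln(\lambda_0 / |\lambda_1|)}: subdominant modes decay as
#' \eqn{(|\lambda_1|/\lambda_0)^t = e^{-t/t_*}}. Invariant under rescaling of
#' the environment. `Inf` is returned for the periodic/degenerate case
#' \eqn{|\lambda_1| = \lambda_0}.
#'
#' @param env environment matrix.
#' @return Convergence time in steps.
#' @export
convergence_time <- function(env) {
  spectral_summary(env)$t_star
}

#' Stationary population structure of a static environment
#'
#' The leading eigenvector of the environment, normalized to the simplex:
#' the attractor of the relative city-size distribution under any initial
#' condition (strong ergodic behaviour), and the fixed point of one
#' projection step followed by renormalization.
#'
#' @param env environment matrix.
#' @return Structure vector (simplex).
#' @export
stationary_structure <- function(env) {
  spectral_summary(env)$leading_vector
}

#' Iterate the self-consistent nonlinear dynamics
#'
#' Evolves populations by
#' \eqn{N_i(t+1) = [1 + \upsilon_i - \bar\delta_i(t)] N_i(t)} where
#' \eqn{\bar\delta_i = \sum_j \delta_{ij} x_j} depends on the current
#' structure vector: the antisymmetric migration component couples every
#' city's growth to the whole relative distribution (a slow nonlinearity).
#' With `vital = 0` the total population is conserved because
#' \eqn{\sum_i \bar\delta_i x_i = 0} by antisymmetry.
#'
#' @param rates vital rates (vector or [demographic_rates()]).
#' @param delta antisymmetric matrix (or a `"migration_decomposition"`, whose
#'   `delta` field is used).
#' @param N0 initial population.
#' @param T number of steps.
#' @return A `"trajectory"`.
#' @export
iterate_self_consistent <- function(rates, delta, N0, T) {
  if (inherits(delta, "migration_decomposition")) delta <- delta$delta
  delta <- as.matrix(delta)
  if (max(abs(delta + t(delta))) > 1e-12)
    stop("delta must be antisymmetric")
  N <- if (inherits(N0, "population_state")) N0$sizes else as.numeric(N0)
  n <- length(N)
  v <- as_vital(rates, n)
  x <- structure_vector(N)
  logNT <- log(sum(N))
  X <- matrix(NA_real_, T + 1, n)
  lt <- numeric(T + 1)
  X[1, ] <- x; lt[1] <- logNT
  for (t in seq_len(T)) {
    dbar <- drop(delta %*% x)
    g <- 1 + v - dbar
    if (any(g <= 0))
      stop("negative growth factor at step ", t, " (city ",
           which.min(g), ")")
    y <- g * x
    s <- sum(y)                      # equals 1 + weighted mean vital rate
    x <- y / s
    logNT <- logNT + log(s)
    X[t + 1, ] <- x; lt[t + 1] <- logNT
  }
  structure(list(times = 0:T, structures = X, log_total = lt),
            class = "trajectory")
}

#' Solve for the self-consistent stationary structure
#'
#' Finds a simplex vector `x*` with
#' \eqn{\upsilon_i - \bar\upsilon^* = \sum_j \delta_{ij} x_j^*}
#' (\eqn{\bar\upsilon^* = \sum_i \upsilon_i x_i^*}). Although the dynamics
#' is nonlinear, the stationarity condition itself is linear in `x*`:
#' \eqn{(\mathbf{1}\upsilon^T + \delta)\,x^* = \upsilon} together with the
#' simplex normalization, so the solver performs a constrained
#' least-squares solve of this system. If the linear solution leaves the
#' simplex (negative entries: no interior stationary structure exists, and
#' the dynamics drives some cities extinct), a damped iteration of the
#' physical dynamics is run instead and the best point found is returned
#' with its residual -- note that around an interior stationary point the
#' antisymmetric coupling acts as a rotation, so the dynamics can orbit
#' rather than settle; see the methods vignette.
#'
#' @param rates vital rates.
#' @param delta antisymmetric matrix.
#' @param x0 starting structure for the dynamic fallback (default uniform).
#' @param eta damping factor of the fallback iteration.
#' @param tol acceptance tolerance on the support residual.
#' @param max_iter fallback iteration cap.
#' @return Structure vector with attributes `residual` (max stationarity
#'   violation over the support), `support` (logical), `method`
#'   (`"linear"` or `"dynamic"`), and `converged`.
#' @export
solve_self_consistent <- function(rates, delta, x0 = NULL, eta = 0.5,
                                  tol = 1e-8, max_iter = 50000L) {
  if (inherits(delta, "migration_decomposition")) delta <- delta$delta
  delta <- as.matrix(delta)
  if (max(abs(delta + t(delta))) > 1e-12) stop("delta must be antisymmetric")
  n <- nrow(delta)
  v <- as_vital(rates, n)
  resid <- function(x) {
    supp <- x > 1e-12
    r <- v - sum(v * x) - drop(delta %*% x)
    max(abs(r[supp]))
  }
  # stationarity is linear: (1 v^T + delta) x = v, 1^T x = 1. Whenever an
  # interior solution x* exists the system is rank-deficient by one
  # (solutions form the line x* + t delta^-1 1, all on the sum-1 plane), so
  # solve by SVD and then move along the null space to the point that
  # maximizes the minimum share.
  M <- rbind(matrix(v, n, n, byrow = TRUE) + delta, rep(1, n))
  rhs <- c(v, 1)
  sv <- svd(M)
  s_tol <- max(dim(M)) * max(sv$d) * .Machine$double.eps
  rk <- sum(sv$d > s_tol)
  xp <- drop(sv$v[, seq_len(rk), drop = FALSE] %*%
               (crossprod(sv$u[, seq_len(rk), drop = FALSE], rhs) /
                  sv$d[seq_len(rk)]))
  if (max(abs(M %*% xp - rhs)) < 1e-9) {
    if (rk < n) {
      for (j in (rk + 1):n) {        # usually a single null direction
        u <- sv$v[, j]
        tb <- 2 * (max(abs(xp)) + 1) / max(abs(u))
        opt <- stats::optimize(function(t) min(xp + t * u),
                               c(-tb, tb), maximum = TRUE)
        xp <- xp + opt$maximum * u
      }
    }
    if (all(xp >= -1e-10)) {
      x <- pmax(xp, 0)
      x <- x / sum(x)
      r <- resid(x)
      if (r < tol)
        return(structure(x, residual = r, support = x > 1e-12,
                         method = "linear", converged = TRUE))
    }
  }
  # no interior solution: follow the damped physical dynamics
  x <- if (is.null(x0)) rep(1 / n, n) else structure_vector(x0)
  best <- x; best_r <- resid(x)
  for (it in seq_len(max_iter)) {
    g <- 1 + v - sum(v * x) - drop(delta %*% x)
    g[g < 0] <- 0
    y <- g * x
    s <- sum(y)
    if (s <= 0) break
    x <- (1 - eta) * x + eta * y / s
    r <- resid(x)
    if (r < best_r) { best <- x; best_r <- r }
    if (best_r < tol) break
  }
  if (best_r >= tol)
    warning("no simplex solution found to tolerance; best residual = ",
            format(best_r, digits = 4))
  structure(best, residual = best_r, support = best > 1e-12,
            method = "dynamic", converged = best_r < tol)
}
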