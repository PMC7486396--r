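#' Demographic rates for a system of cities
#'
#' Bundles per-capita birth and death rates into a vital-rate vector
#' \eqn{\upsilon_i = b_i - d_i} (per unit time). Net in-migration from outside
#' the system, if any, is conventionally absorbed into the vital rates.
#'
#' @param birth per-capita birth rates, one per city.
#' @param death per-capita death rates, recycled against `birth`.
#' @return An object of class `"demographic_rates"` with fields `birth`,
#'   `death` and `vital`.
#' @examples
#' demographic_rates(birth = c(0.02, 0.015), death = 0.01)
#' @export
demographic_rates <- function(birth, death = 0) {
  n <- max(length(birth), length(death))
  birth <- rep_len(as.numeric(birth), n)
  death <- rep_len(as.numeric(death), n)
  vital <- birth - death
  if (any(!is.finite(vital))) stop("vital rates must be finite")
  structure(list(birth = birth, death = death, vital = vital),
            class = "demographic_rates")
}

#' Demographic rates from vital rates alone
#'
#' Convenience constructor when only the net vital rate
#' \eqn{\upsilon_i = b_i - d_i} is known.
#'
#' @param vital vector of vital rates.
#' @return A `"demographic_rates"` object with `birth = vital`, `death = 0`.
#' @export
vital_rates <- function(vital) demographic_rates(birth = vital, death = 0)

as_vital <- function(rates, n = NULL) {
  v <- if (inherits(rates, "demographic_rates")) rates$vital else as.numeric(rates)
  if (!is.null(n)) {
    if (length(v) == 1L) v <- rep(v, n)
    if (length(v) != n) stop("vital-rate length does not match the number of cities")
  }
  if (any(!is.finite(v))) stop("vital rates must be finite")
  v
}

#' Intercity migration model
#'
#' Holds the matrix of migration probabilities `m[i, j]`: the probability that
#' a resident of city `i` moves to city `j` per unit time. Optionally carries
#' a symmetric positive distance matrix and gravity-law parameters.
#'
#' @param m square matrix of migration probabilities; the diagonal must be
#'   zero and every row must sum to at most 1 (a person migrates out of `i`
#'   with total probability `out_rate[i] <= 1`).
#' @param distance optional symmetric matrix of positive intercity distances.
#' @param G_g,gamma optional gravity-law constant and distance exponent used
#'   to generate `m` (stored for provenance only).
#' @return An object of class `"migration_model"` with fields `m`, `out_rate`
#'   and the optional metadata.
#' @seealso [build_environment()], [decompose_migration()], [gravity_flows()]
#' @export
migration_model <- function(m, distance = NULL, G_g = NULL, gamma = NULL) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("migration matrix must be square")
  if (any(m < 0)) stop("migration probabilities must be non-negative")
  if (any(diag(m) != 0)) stop("self-migration entries m[i,i] must be zero")
  out_rate <- rowSums(m)
  if (any(out_rate > 1 + 1e-12))
    stop("invalid migration: total out-migration probability exceeds 1 for city ",
         paste(which(out_rate > 1 + 1e-12), collapse = ", "))
  if (!is.null(distance)) {
    distance <- as.matrix(distance)
    if (!isTRUE(all.equal(distance, t(distance))))
      stop("distance matrix must be symmetric")
    off <- distance[row(distance) != col(distance)]
    if (any(off <= 0)) stop("off-diagonal distances must be positive")
  }
  structure(list(m = m, out_rate = out_rate, distance = distance,
                 G_g = G_g, gamma = gamma),
            class = "migration_model")
}

#' Population state
#'
#' A vector of absolute city populations at a time step.
#'
#' @param sizes non-negative city populations (persons).
#' @param time integer time index (steps of unit length).
#' @return Object of class `"population_state"` with fields `sizes`, `total`
#'   and `time`.
#' @export
population_state <- function(sizes, time = 0L) {
  sizes <- as.numeric(sizes)
  if (any(sizes < 0)) stop("populations must be non-negative")
  total <- sum(sizes)
  if (total <= 0) stop("total population must be positive")
  structure(list(sizes = sizes, total = total, time = as.integer(time)),
            class = "population_state")
}

#' Population structure vector
#'
#' The shares \eqn{x_i = N_i / N_T}: a probability distribution over cities
#' (the probability of finding a person in city `i`).
#'
#' @param x a `"population_state"`, or a non-negative vector which is
#'   normalized to the simplex.
#' @return Numeric simplex vector.
#' @export
structure_vector <- function(x) {
  if (inherits(x, "population_state")) x <- x$sizes
  x <- as.numeric(x)
  if (any(x < 0)) stop("shares must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("degenerate structure vector")
  x / s
}

#' Build the environment (projection) matrix
#'
#' Constructs the matrix that projects city populations forward one step:
#' `A[i, i] = 1 + vital[i] - out_rate[i]` and `A[i, j] = m[j, i]` for
#' `i != j`. Rows index the destination and columns the origin, so
#' `A %*% N` balances births, deaths, and migration currents. Note that most
#' migration tables ship origin-major: the off-diagonal block is the
#' transpose of the migration-probability matrix.
#'
#' The column sum over destinations for origin `j` is exactly
#' `1 + vital[j]`: people are conserved up to vital rates.
#'
#' @param rates a [demographic_rates()] object, or a vector of vital rates.
#' @param migration a [migration_model()].
#' @param time integer time index attached to the environment.
#' @return A matrix of class `"demog_env"` with attributes `vital` and
#'   `time_index`.
#' @examples
#' mig <- migration_model(rbind(c(0, 0.1), c(0.2, 0)))
#' A <- build_environment(vital_rates(c(0, 0)), mig)
#' colSums(A)  # exactly 1 + vital
#' @export
build_environment <- function(rates, migration, time = 0L) {
  if (!inherits(migration, "migration_model"))
    migration <- migration_model(migration)
  n <- nrow(migration$m)
  v <- as_vital(rates, n)
  A <- t(migration$m)
  diag(A) <- 1 + v - migration$out_rate
  if (any(diag(A) <= 0))
    stop("environment not positive: 1 + vital - out_rate <= 0 for city ",
         paste(which(diag(A) <= 0), collapse = ", "))
  structure(A, vital = v, time_index = as.integer(time),
            class = c("demog_env", "matrix"))
}

env_matrix <- function(env) {
  if (inherits(env, "demog_env") || is.matrix(env)) {
    A <- unclass(env)
    attributes(A) <- list(dim = dim(env))
    return(A)
  }
  stop("not an environment matrix")
}

#' Project a population one step forward
#'
#' Applies the environment to a population state: `N(t) = A N(t-1)`,
#' the matrix form of the per-city birth/death/migration balance.
#'
#' @param env environment matrix from [build_environment()].
#' @param state a [population_state()] (or bare numeric vector).
#' @return The updated `"population_state"` (time advanced by one step).
#' @export
apply_environment <- function(env, state) {
  A <- env_matrix(env)
  bare <- !inherits(state, "population_state")
  N <- if (bare) as.numeric(state) else state$sizes
  if (length(N) != ncol(A)) stop("dimension mismatch between environment and state")
  N1 <- drop(A %*% N)
  population_state(N1, time = if (bare) 1L else state$time + 1L)
}

#' Decompose migration probabilities into symmetric and antisymmetric parts
#'
#' Writes the migration currents as
#' \eqn{J_{ij} = m_{ij} N_i = \frac{s_{ij} + \delta_{ij}}{2} x_j N_i}
#' and solves the two linear relations per pair for
#' `s[i,j] = m[i,j]/x[j] + m[j,i]/x[i]` (symmetric) and
#' `delta[i,j] = m[i,j]/x[j] - m[j,i]/x[i]` (antisymmetric). Only the
#' antisymmetric part moves relative city sizes; the symmetric part cancels.
#'
#' @param migration a [migration_model()].
#' @param x structure vector with strictly positive shares (cities with zero
#'   share must be removed before decomposing).
#' @return Object of class `"migration_decomposition"` with matrices `s` and
#'   `delta`.
#' @export
decompose_migration <- function(migration, x) {
  if (!inherits(migration, "migration_model"))
    migration <- migration_model(migration)
  x <- structure_vector(x)
  if (any(x <= 0)) stop("degenerate city: decomposition requires positive shares")
  m <- migration$m
  if (length(x) != nrow(m)) stop("dimension mismatch")
  r <- sweep(m, 2, x, "/")      # r[i,j] = m[i,j]/x[j]
  s <- r + t(r)
  delta <- r - t(r)
  diag(s) <- 0
  diag(delta) <- 0
  structure(list(s = s, delta = delta), class = "migration_decomposition")
}

#' Recompose migration probabilities from a symmetric/antisymmetric split
#'
#' Inverse of [decompose_migration()]:
#' `m[i,j] = (s[i,j] + delta[i,j]) / 2 * x[j]`.
#'
#' @param dec a `"migration_decomposition"` (or list with `s`, `delta`).
#' @param x structure vector.
#' @return A [migration_model()].
#' @export
compose_migration <- function(dec, x) {
  x <- structure_vector(x)
  m <- sweep((dec$s + dec$delta) / 2, 2, x, "*")
  diag(m) <- 0
  if (any(m < -1e-12))
    stop("inconsistent decomposition: negative migration probability")
  m[m < 0] <- 0
  migration_model(m)
}

#' Gravity-law migration flows
#'
#' Symmetric intercity currents
#' \eqn{J_{ij} = G_g N_i N_j / d_{ij}^{\gamma} = J_{ji}} (persons per step).
#' In the symmetric/antisymmetric decomposition these flows have
#' `delta = 0` and `s[i,j] = G_g * N_T / d[i,j]^gamma`.
#'
#' @param state a [population_state()] or vector of populations.
#' @param distances symmetric matrix of positive intercity distances.
#' @param G_g gravity constant (non-negative).
#' @param gamma distance-decay exponent.
#' @return Symmetric flow matrix `J` with zero diagonal.
#' @examples
#' gravity_flows(c(1000, 2000), rbind(c(0, 10), c(10, 0)), G_g = 0.001, gamma = 1)
#' @export
gravity_flows <- function(state, distances, G_g, gamma) {
  N <- if (inherits(state, "population_state")) state$sizes else as.numeric(state)
  d <- as.matrix(distances)
  if (G_g < 0) stop("gravity constant must be non-negative")
  off <- d[row(d) != col(d)]
  if (any(off <= 0)) stop("off-diagonal distances must be positive")
  J <- G_g * outer(N, N) / ifelse(d > 0, d^gamma, 1)
  diag(J) <- 0
  J
}

# breadth-first search reachability over a boolean adjacency matrix
.bfs_reach <- function(adj, from) {
  n <- nrow(adj)
  seen <- logical(n)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

# period of a strongly connected directed graph: gcd of (level difference + 1)
# over all edges in a BFS tree from node 1
.graph_period <- function(adj) {
  n <- nrow(adj)
  level <- rep(NA_integer_, n)
  level[1] <- 0L
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      vs <- which(adj[u, ] & is.na(level))
      level[vs] <- level[u] + 1L
      nxt <- c(nxt, vs)
    }
    frontier <- nxt
  }
  g <- 0L
  ed <- which(adj, arr.ind = TRUE)
  for (k in seq_len(nrow(ed))) {
    u <- ed[k, 1]; v <- ed[k, 2]
    d <- level[u] + 1L - level[v]
    g <- if (g == 0L) abs(d) else .gcd(g, abs(d))
    if (g == 1L) break
  }
  if (g == 0L) Inf else g
}

.gcd <- function(a, b) {
  while (b != 0L) { t <- b; b <- a %% b; a <- t }
  a
}

#' Validate an environment for ergodic convergence
#'
#' Checks the assumptions under which the leading eigenvector of the
#' environment is guaranteed to exist, be positive, and attract every initial
#' population: non-negative entries, strong connectivity of the migration
#' graph (any city reachable from any other along non-zero flows), and
#' primitivity (aperiodicity, so that some power of the matrix is strictly
#' positive). Entries below `tol` are treated as zero for connectivity.
#'
#' @param env environment matrix.
#' @param tol numerical noise floor below which entries count as zero.
#' @return A list of class `"system_report"` with logical flags
#'   `nonnegative`, `strongly_connected`, `primitive`, `ok`, and a character
#'   vector `failures` describing any offending cities.
#' @export
validate_system <- function(env, tol = 1e-15) {
  A <- env_matrix(env)
  if (nrow(A) != ncol(A)) stop("environment must be square")
  failures <- character(0)
  nonneg <- all(A >= 0)
  if (!nonneg) {
    bad <- unique(which(A < 0, arr.ind = TRUE)[, 1])
    failures <- c(failures, paste0("negative entries in rows: ",
                                   paste(bad, collapse = ", ")))
  }
  adj <- abs(A) > tol
  diag(adj) <- diag(adj) | diag(A) > tol
  fwd <- .bfs_reach(adj, 1L)
  bwd <- .bfs_reach(t(adj), 1L)
  strong <- all(fwd) && all(bwd)
  if (!strong) {
    unreachable <- which(!(fwd & bwd))
    failures <- c(failures, paste0("cities not strongly connected to city 1: ",
                                   paste(unreachable, collapse = ", ")))
  }
  primitive <- FALSE
  if (strong) {
    period <- .graph_period(adj)
    primitive <- is.finite(period) && period == 1L
    if (!primitive)
      failures <- c(failures, paste0("graph is periodic with period ", period))
  }
  structure(list(nonnegative = nonneg, strongly_connected = strong,
                 primitive = primitive, ok = nonneg && strong && primitive,
                 failures = failures),
            class = "system_report")
}

#' @export
print.system_report <- function(x, ...) {
  cat("environment validation:",
      if (x$ok) "PASS" else "FAIL", "\n")
  cat("  non-negative entries :", x$nonnegative, "\n")
  cat("  strongly connected   :", x$strongly_connected, "\n")
  cat("  primitive (aperiodic):", x$primitive, "\n")
  if (length(x$failures)) cat("  failures:\n", paste0("   - ", x$failures, "\n"))
  invisible(x)
}
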