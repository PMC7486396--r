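#' Generate an initial population state
#'
#' Either near-equal city sizes (with optional multiplicative noise) or a
#' Zipfian hierarchy, scaled to a total population.
#'
#' @param kind `"equal"` or `"zipf"`.
#' @param n_cities number of cities.
#' @param total total population `N_T`.
#' @param noise_sd multiplicative lognormal noise (sd of log) applied to the
#'   equal kind.
#' @param seed integer seed.
#' @return A [population_state()].
#' @export
gen_initial_population <- function(kind = c("equal", "zipf"), n_cities,
                                   total, noise_sd = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (total <= 0) stop("total population must be positive")
  if (!is.null(seed)) set.seed(seed)
  N <- switch(kind,
    equal = {
      base <- rep(total / n_cities, n_cities)
      if (noise_sd > 0) base <- base * exp(stats::rnorm(n_cities, 0, noise_sd))
      base * (total / sum(base))
    },
    zipf = zipf_reference(n_cities) * total)
  population_state(N)
}

#' Generate a synthetic demographic environment
#'
#' Three generators covering the simulation protocols:
#' \describe{
#'   \item{`uniform_noise`}{all migration entries equal plus a little
#'     multiplicative noise (`m[i,j] = m0 (1 + noise U(-1,1))`, with
#'     `m0 = mean_out_rate/(n-1)`): an exchangeable environment whose
#'     stationary structure is uniform when `noise = 0`.}
#'   \item{`gravity`}{cities placed uniformly in the unit square; symmetric
#'     flows `J = G_g N_i N_j / d^gamma` around a reference population are
#'     converted to probabilities `m[i,j] = J[i,j]/N_i`. If any out-rate
#'     exceeds 1 the whole matrix is rescaled (with a warning).}
#'   \item{`random_sparse`}{directed edges kept with probability `p`,
#'     lognormal magnitudes scaled to `mean_out_rate`; regenerated (bounded
#'     retries) until the system validates as strongly connected and
#'     primitive.}
#' }
#'
#' @param kind generator name.
#' @param n_cities number of cities.
#' @param vital vital rate(s) (recycled).
#' @param mean_out_rate target mean total out-migration probability.
#' @param noise relative noise amplitude for `uniform_noise`.
#' @param state reference [population_state()] for `gravity` (default:
#'   Zipfian with total `1e6`).
#' @param G_g,gamma gravity parameters; `G_g = NULL` is auto-scaled so the
#'   mean out-rate is `mean_out_rate`.
#' @param p edge probability for `random_sparse`.
#' @param max_retries regeneration cap for `random_sparse`.
#' @param seed integer seed.
#' @return A `"demog_env"` environment matrix passing [validate_system()].
#' @export
gen_environment <- function(kind = c("uniform_noise", "gravity",
                                     "random_sparse"),
                            n_cities, vital = 0, mean_out_rate = 0.1,
                            noise = 0.1, state = NULL, G_g = NULL,
                            gamma = 1, p = 0.1, max_retries = 50L,
                            seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- n_cities
  mig <- switch(kind,
    uniform_noise = {
      m0 <- mean_out_rate / (n - 1)
      m <- matrix(m0 * (1 + noise * stats::runif(n * n, -1, 1)), n, n)
      diag(m) <- 0
      migration_model(m)
    },
    gravity = {
      if (is.null(state)) state <- gen_initial_population("zipf", n, 1e6)
      N <- if (inherits(state, "population_state")) state$sizes else state
      xy <- cbind(stats::runif(n), stats::runif(n))
      d <- as.matrix(stats::dist(xy))
      if (is.null(G_g)) {
        J1 <- gravity_flows(N, d, 1, gamma)
        G_g <- mean_out_rate / mean(rowSums(J1) / N)
      }
      J <- gravity_flows(N, d, G_g, gamma)
      m <- J / N                       # m[i,j] = J[i,j] / N_i (row-wise)
      diag(m) <- 0
      out <- rowSums(m)
      if (any(out > 1)) {
        warning("gravity out-rates exceeded 1; rescaling migration matrix")
        m <- m * (0.95 / max(out))
      }
      migration_model(m, distance = d, G_g = G_g, gamma = gamma)
    },
    random_sparse = {
      for (k in seq_len(max_retries)) {
        keep <- matrix(stats::runif(n * n) < p, n, n)
        diag(keep) <- FALSE
        m <- matrix(0, n, n)
        m[keep] <- stats::rlnorm(sum(keep), 0, 1)
        rs <- rowSums(m)
        if (any(rs == 0)) next           # isolated city: resample
        m <- m * (mean_out_rate / max(rs))
        env_try <- build_environment(vital_rates(rep_len(vital, n)),
                                     migration_model(m))
        if (validate_system(env_try)$ok) return(env_try)
      }
      stop("failed to generate a valid sparse environment in ",
           max_retries, " attempts")
    })
  build_environment(vital_rates(rep_len(vital, n)), mig)
}

#' Generate a reproducible stream of rate-noise matrices
#'
#' Draws `T` matrices with lognormal magnitudes. With
#' `antisymmetric = TRUE` the strict upper triangle gets lognormal
#' magnitudes and symmetric random signs and the lower triangle is the
#' negated mirror, so `delta + t(delta) == 0` holds exactly and the
#' construction mean is zero.
#'
#' @param T number of draws.
#' @param n matrix dimension.
#' @param meanlog,sdlog lognormal parameters of the magnitudes.
#' @param antisymmetric produce antisymmetric matrices?
#' @param seed integer seed.
#' @return `n x n x T` array.
#' @export
gen_noise_process <- function(T, n, meanlog = log(0.036) - 0.5, sdlog = 1,
                              antisymmetric = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- array(0, dim = c(n, n, T))
  ut <- upper.tri(matrix(0, n, n))
  n_ut <- sum(ut)
  for (t in seq_len(T)) {
    mag <- stats::rlnorm(n_ut, meanlog, sdlog)
    sgn <- sample(c(-1, 1), n_ut, replace = TRUE)
    d <- matrix(0, n, n)
    d[ut] <- sgn * mag
    out[, , t] <- if (antisymmetric) d - t(d) else {
      d2 <- matrix(0, n, n)
      d2[ut] <- stats::rlnorm(n_ut, meanlog, sdlog) *
        sample(c(-1, 1), n_ut, replace = TRUE)
      d + t(d2)
    }
  }
  out
}

#' Read an origin-destination flow table
#'
#' Comma-delimited text with header `origin_id,destination_id,count`
#' (the shape migration extracts are commonly reshaped to). Self-flows are
#' dropped with a warning; counts must be non-negative.
#'
#' @param path file path.
#' @return `data.frame` of class `"flow_table"` with character ids.
#' @export
read_flow_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "character",
                                             "numeric"))
  need <- c("origin_id", "destination_id", "count")
  if (!all(need %in% names(df)))
    stop("flow table must have columns: ", paste(need, collapse = ", "))
  df <- df[need]
  if (any(df$count < 0)) stop("malformed rows: negative counts")
  self <- df$origin_id == df$destination_id
  if (any(self)) {
    warning(sum(self), " self-flow rows ignored")
    df <- df[!self, , drop = FALSE]
  }
  class(df) <- c("flow_table", "data.frame")
  df
}

#' Write a flow table
#' @param flows a `"flow_table"` (or compatible data.frame).
#' @param path destination file.
#' @export
write_flow_table <- function(flows, path) {
  utils::write.csv(as.data.frame(flows)[c("origin_id", "destination_id",
                                          "count")],
                   path, row.names = FALSE, quote = FALSE)
}

#' Square flow matrix from a flow table (and back)
#'
#' @param flows a `"flow_table"`.
#' @param units optional character vector fixing the unit order.
#' @return Named square matrix of counts (zero diagonal).
#' @export
flow_matrix <- function(flows, units = NULL) {
  if (is.null(units))
    units <- sort(unique(c(flows$origin_id, flows$destination_id)))
  J <- matrix(0, length(units), length(units),
              dimnames = list(units, units))
  for (k in seq_len(nrow(flows)))
    J[flows$origin_id[k], flows$destination_id[k]] <-
      J[flows$origin_id[k], flows$destination_id[k]] + flows$count[k]
  J
}

#' Aggregate unit-level flows with a crosswalk
#'
#' Sums flows up to aggregates (e.g. counties to metropolitan areas) using a
#' `unit_id -> aggregate_id` crosswalk. Flows within an aggregate are
#' dropped from migration: a move inside an integrated labor market is not a
#' migration event. Out-counts of each aggregate equal the sum of member
#' units' counts to non-member units exactly (integer arithmetic preserved).
#'
#' @param flows a `"flow_table"`.
#' @param crosswalk `data.frame` with columns `unit_id`, `aggregate_id`.
#' @param strict error on units missing from the crosswalk (otherwise their
#'   rows are dropped and the dropped count reported as an attribute).
#' @return Aggregated `"flow_table"`; attribute `dropped` gives rows lost in
#'   non-strict mode, `intra` the intra-aggregate person-count folded out.
#' @export
aggregate_flows <- function(flows, crosswalk, strict = TRUE) {
  if (!all(c("unit_id", "aggregate_id") %in% names(crosswalk)))
    stop("crosswalk must have columns unit_id, aggregate_id")
  map <- stats::setNames(as.character(crosswalk$aggregate_id),
                         as.character(crosswalk$unit_id))
  units <- unique(c(flows$origin_id, flows$destination_id))
  missing <- setdiff(units, names(map))
  dropped <- 0L
  if (length(missing)) {
    if (strict)
      stop("units missing from crosswalk: ", paste(missing, collapse = ", "))
    keep <- !(flows$origin_id %in% missing |
                flows$destination_id %in% missing)
    dropped <- sum(!keep)
    flows <- flows[keep, , drop = FALSE]
  }
  o <- map[flows$origin_id]
  d <- map[flows$destination_id]
  inter <- o != d
  intra <- sum(flows$count[!inter])
  agg <- stats::aggregate(count ~ origin_id + destination_id,
                          data = data.frame(origin_id = o[inter],
                                            destination_id = d[inter],
                                            count = flows$count[inter]),
                          FUN = sum)
  class(agg) <- c("flow_table", "data.frame")
  attr(agg, "dropped") <- dropped
  attr(agg, "intra") <- intra
  agg
}

#' Convert flows to migration probabilities
#'
#' `m[i,j] = count[i -> j] / N_i`: flows as per-capita rates over the origin
#' population. Residual growth not explained by these flows is attributable
#' to the balance of births, deaths, and external migration (recoverable as
#' implied vital rates given populations at two times).
#'
#' @param flows a `"flow_table"`.
#' @param populations named vector (or [population_state()] with names) of
#'   origin populations covering every unit in `flows`.
#' @return A [migration_model()] with units in `names(populations)` order.
#' @export
flows_to_migration <- function(flows, populations) {
  N <- if (inherits(populations, "population_state")) {
    stats::setNames(populations$sizes, names(populations$sizes))
  } else populations
  if (is.null(names(N))) stop("populations must be named by unit id")
  units <- names(N)
  J <- flow_matrix(flows, units = units)
  if (any(N <= 0)) stop("origin populations must be positive")
  if (any(rowSums(J) > N))
    stop("flows exceed origin population for unit ",
         paste(units[rowSums(J) > N], collapse = ", "))
  m <- J / N
  migration_model(m)
}

#' Named simulation scenarios
#'
#' Prepackaged inputs for the standard numerical protocols:
#' \describe{
#'   \item{`fig1a` / `fig1b`}{one static uniform-noise environment with two
#'     initial conditions (near-equal sizes vs Zipf): strong-ergodic
#'     convergence to the leading eigenvector.}
#'   \item{`fig2a`}{self-consistent nonlinear dynamics: static vital-rate
#'     differences plus a static antisymmetric migration component for 100
#'     cities, leading to a fixed non-Zipf hierarchy.}
#'   \item{`fig2b_stochastic`}{symmetry-restored stochastic run for 100
#'     cities whose time-averaged structure approaches Zipf's law.}
#' }
#'
#' @param name scenario name.
#' @param seed integer seed.
#' @param n_cities number of cities (default 100).
#' @return List with the scenario ingredients (`env` or `cfg`, `N0`, and a
#'   `params` record including the seed).
#' @export
gen_scenario <- function(name = c("fig1a", "fig1b", "fig2a",
                                  "fig2b_stochastic"),
                         seed = 1L, n_cities = 100L) {
  name <- match.arg(name)
  n <- n_cities
  if (name %in% c("fig1a", "fig1b")) {
    env <- gen_environment("uniform_noise", n, mean_out_rate = 0.1,
                           noise = 0.1, seed = seed)
    N0 <- gen_initial_population(if (name == "fig1a") "equal" else "zipf",
                                 n, total = 1e6, noise_sd = 0.05,
                                 seed = seed + 1L)
    list(name = name, env = env, N0 = N0,
         params = list(seed = seed, n_cities = n, mean_out_rate = 0.1,
                       noise = 0.1))
  } else if (name == "fig2a") {
    set.seed(seed)
    vital <- stats::rnorm(n, 0, 0.005)
    delta <- gen_noise_process(1, n, meanlog = log(0.02) - 0.5, sdlog = 1,
                               antisymmetric = TRUE)[, , 1]
    N0 <- gen_initial_population("equal", n, total = 1e6, noise_sd = 0.05,
                                 seed = seed + 1L)
    list(name = name, vital = vital, delta = delta, N0 = N0,
         params = list(seed = seed, n_cities = n))
  } else {
    cfg <- stochastic_config(n, sigma = 0.05, T = 1e5, burn_in = 2e4)
    list(name = name, cfg = cfg, x0 = zipf_reference(n),
         params = list(seed = seed, n_cities = n, sigma = 0.05))
  }
}

#' Write a trajectory as delimited text
#'
#' One row per (time, city): columns `t`, `city`, `x` (share), `log_total`.
#'
#' @param traj a `"trajectory"`.
#' @param path destination file.
#' @export
write_trajectory <- function(traj, path) {
  n <- ncol(traj$structures)
  df <- data.frame(
    t = rep(traj$times, each = n),
    city = rep(seq_len(n), length(traj$times)),
    x = as.vector(t(traj$structures)),
    log_total = rep(traj$log_total, each = n))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
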