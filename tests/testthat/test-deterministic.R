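test_that("iteration reproduces matrix powers", {
  expect_equal(iterate(diag(2), c(3, 4), 5)$structures[6, ], c(3, 4) / 7)

  # scalar growth: A = 2 I, three steps
  tr <- iterate(2 * diag(2), c(1, 1), 3)
  expect_equal(trajectory_states(tr)[4, ], c(8, 8))

  set.seed(21)
  env <- random_valid_env(8)
  N0 <- runif(8, 1, 100)
  tr <- iterate(env, N0, 50)
  oracle <- drop(mat_pow(unclass(env), 50) %*% N0)
  expect_equal(trajectory_states(tr)[51, ], oracle, tolerance = 1e-10)

  # environment sequences multiply in order A(T)...A(1)
  envs <- replicate(3, random_valid_env(4), simplify = FALSE)
  N0 <- runif(4, 1, 10)
  tr <- iterate(envs, N0, 3)
  oracle <- drop(unclass(envs[[3]]) %*% unclass(envs[[2]]) %*%
                   unclass(envs[[1]]) %*% N0)
  expect_equal(trajectory_states(tr)[4, ], oracle, tolerance = 1e-12)

  expect_error(iterate(diag(2), c(1, 1), 0), "at least 1")
})

test_that("log-total representation survives far beyond overflow", {
  tr <- iterate(2 * diag(2), c(1, 1), 4000)
  expect_equal(tr$log_total[4001], log(2) * 4000 + log(2), tolerance = 1e-9)
  expect_equal(tr$structures[4001, ], c(0.5, 0.5))
})

test_that("spectral summary sorts, normalizes and reconstructs", {
  ss <- spectral_summary(diag(c(2, 1)))
  expect_equal(Re(ss$values), c(2, 1))
  expect_equal(ss$leading_vector, c(1, 0))

  ss2 <- spectral_summary(two_city_env())
  expect_equal(Re(ss2$values), c(1, 0.7))
  expect_equal(ss2$leading_vector, c(2, 1) / 3)

  # reconstruction against the iteration oracle on a random 20-city system
  set.seed(33)
  env <- random_valid_env(20)
  N0 <- runif(20, 10, 1000)
  ss3 <- spectral_summary(env, N0)
  t <- 10
  rec <- Re(ss3$vectors %*% (ss3$values^t * ss3$coefficients))
  direct <- trajectory_states(iterate(env, N0, t))[t + 1, ]
  expect_lt(max(abs(rec - direct) / direct), 1e-8)
  # coefficients reproduce N(0)
  expect_equal(Re(ss3$vectors %*% ss3$coefficients)[, 1], N0,
               tolerance = 1e-10)
})

test_that("convergence time follows the spectral gap", {
  expect_equal(convergence_time(diag(c(2, 1))), 1 / log(2))
  expect_equal(convergence_time(two_city_env()), 1 / log(1 / 0.7))
  # invariant under overall rescaling
  set.seed(3)
  env <- random_valid_env(6)
  expect_equal(convergence_time(env), convergence_time(3.7 * unclass(env)),
               tolerance = 1e-10)
})

test_that("stationary structure is the simplex-normalized leading eigenvector", {
  # exchangeable environment: uniform structure
  n <- 7
  m <- matrix(0.02, n, n); diag(m) <- 0
  env <- build_environment(vital_rates(rep(0.01, n)), migration_model(m))
  expect_equal(stationary_structure(env), rep(1 / n, n), tolerance = 1e-12)

  expect_equal(stationary_structure(two_city_env()), c(2, 1) / 3)

  # fixed point of one projection step + renormalization
  set.seed(9)
  env <- random_valid_env(10)
  e0 <- stationary_structure(env)
  step <- apply_environment(env, population_state(e0))
  expect_equal(structure_vector(step), e0, tolerance = 1e-10)
})

test_that("different initial conditions converge to a common structure", {
  env <- gen_environment("uniform_noise", 50, mean_out_rate = 0.1,
                         noise = 0.1, seed = 61)
  ts <- convergence_time(env)
  T <- ceiling(20 * ts)
  trA <- iterate(env, gen_initial_population("equal", 50, 1e6, 0.05,
                                             seed = 62), T)
  trB <- iterate(env, gen_initial_population("zipf", 50, 1e6, seed = 63), T)
  xa <- trA$structures[T + 1, ]
  xb <- trB$structures[T + 1, ]
  expect_lt(max(abs(xa - xb)), 1e-8)
  expect_lt(as.numeric(kl_divergence(xa, xb)), 1e-10)
  expect_lt(max(abs(xa - stationary_structure(env))), 1e-8)
})

test_that("endpoint variance across initial conditions collapses to one dof", {
  env <- gen_environment("uniform_noise", 30, seed = 71)
  T <- ceiling(20 * convergence_time(env))
  ends <- sapply(1:10, function(k)
    log(iterate(env, gen_initial_population("equal", 30, 1e5, 0.2,
                                            seed = 700 + k), T)
        $structures[T + 1, ]))
  expect_lt(max(apply(ends, 1, var)), 1e-10)
})

test_that("self-consistent iteration freezes when growth rates equalize", {
  n <- 5
  x0 <- c(10, 20, 30, 15, 25)
  tr <- iterate_self_consistent(rep(0.02, n), matrix(0, n, n), x0, 50)
  expect_equal(tr$structures[51, ], x0 / sum(x0), tolerance = 1e-14)

  # degenerate 2-city family: delta12 = v1 - v2 makes every x stationary
  d <- rbind(c(0, 0.02), c(-0.02, 0))
  tr2 <- iterate_self_consistent(c(0.02, 0), d, c(70, 30), 200)
  expect_equal(tr2$structures[201, ], c(0.7, 0.3), tolerance = 1e-12)
})

test_that("antisymmetric flows conserve the total population when vital = 0", {
  set.seed(15)
  n <- 6
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- rnorm(n * (n - 1) / 2, 0, 0.01)
  d <- d - t(d)
  tr <- iterate_self_consistent(rep(0, n), d, runif(n, 10, 100), 100)
  expect_equal(tr$log_total, rep(tr$log_total[1], 101), tolerance = 1e-12)
})

test_that("self-consistent solver recovers constructed interior solutions", {
  set.seed(3)
  xstar <- c(0.5, 0.3, 0.2)
  d <- matrix(0, 3, 3)
  d[upper.tri(d)] <- c(0.03, -0.02, 0.01)
  d <- d - t(d)
  v <- drop(d %*% xstar)              # by construction vbar* = 0
  xs <- solve_self_consistent(v, d)
  expect_equal(as.numeric(xs), xstar, tolerance = 1e-10)
  expect_lt(attr(xs, "residual"), 1e-8)

  # larger random construction
  n <- 12
  xstar <- rand_simplex(n)
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- rnorm(n * (n - 1) / 2, 0, 0.02)
  d <- d - t(d)
  v <- drop(d %*% xstar) + 0.01       # vbar* shift is unidentified; any works
  xs <- solve_self_consistent(v, d)
  expect_lt(attr(xs, "residual"), 1e-8)
  r <- v - sum(v * xs) - drop(d %*% as.numeric(xs))
  expect_lt(max(abs(r[xs > 1e-12])), 1e-8)
})

test_that("boundary attractors agree between solver and dynamics", {
  # v1 - v2 != delta12: no simplex-interior solution; city 2 wins
  d <- rbind(c(0, 0.04), c(-0.04, 0))
  xs <- suppressWarnings(solve_self_consistent(c(0.02, 0), d))
  tr <- iterate_self_consistent(c(0.02, 0), d, c(50, 50), 5000)
  expect_equal(as.numeric(xs), c(0, 1), tolerance = 1e-6)
  expect_equal(tr$structures[5001, ], c(0, 1), tolerance = 1e-6)
  expect_lt(attr(xs, "residual"), 1e-8)
})

test_that("uniform vital rates select a null direction of delta", {
  # with equal vital rates the condition reduces to delta x* = 0; a 3-city
  # antisymmetric matrix always has a null direction, here (0.03,0.02,0.01)
  d <- rbind(c(0, 0.01, -0.02), c(-0.01, 0, 0.03), c(0.02, -0.03, 0))
  xs <- solve_self_consistent(rep(0.02, 3), d)
  expect_lt(attr(xs, "residual"), 1e-12)
  expect_equal(as.numeric(xs), c(0.03, 0.02, 0.01) / 0.06, tolerance = 1e-8)
})
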