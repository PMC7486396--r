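test_that("environment matrix follows the destination-row convention", {
  # no demography: identity
  n <- 4
  A0 <- build_environment(vital_rates(rep(0, n)),
                          migration_model(matrix(0, n, n)))
  expect_equal(unclass(A0), diag(n), ignore_attr = TRUE)

  env <- two_city_env()
  expect_equal(unclass(env), rbind(c(0.9, 0.2), c(0.1, 0.8)),
               ignore_attr = TRUE)
  expect_equal(colSums(env), c(1, 1))

  # column sums are exactly 1 + vital of the origin
  env2 <- build_environment(vital_rates(c(0.05, 0)),
                            migration_model(rbind(c(0, 0.1), c(0.2, 0))))
  expect_equal(colSums(env2), c(1.05, 1))
})

test_that("environment construction rejects invalid inputs", {
  expect_error(build_environment(vital_rates(c(-1.5, 0)),
                                 migration_model(rbind(c(0, 0.1),
                                                       c(0.2, 0)))),
               "not positive")
  expect_error(migration_model(rbind(c(0, 0.6, 0.6), c(0, 0, 0),
                                     c(0, 0, 0))),
               "exceeds 1")
  expect_error(migration_model(rbind(c(0.1, 0), c(0, 0))), "zero")
  expect_error(migration_model(rbind(c(0, -0.1), c(0, 0))), "non-negative")
})

test_that("column-sum identity holds on random environments", {
  set.seed(101)
  for (k in 1:10) {
    n <- sample(3:20, 1)
    v <- rnorm(n, 0, 0.02)
    mig <- random_migration(n)
    env <- build_environment(vital_rates(v), mig)
    expect_equal(colSums(env), 1 + v, tolerance = 1e-14)
  }
})

test_that("projection equals the explicit birth/death/flow balance", {
  set.seed(42)
  for (k in 1:10) {
    n <- sample(2:15, 1)
    v <- rnorm(n, 0, 0.02)
    mig <- random_migration(n)
    N <- runif(n, 10, 1e4)
    env <- build_environment(vital_rates(v), mig)
    got <- apply_environment(env, population_state(N))$sizes
    # explicit balance: N_i' = N_i + v_i N_i + sum_j (J_ji - J_ij)
    J <- mig$m * N                     # J[i, j] = m_ij N_i
    expected <- N + v * N + colSums(J) - rowSums(J)
    expect_equal(got, expected, tolerance = 1e-12)
  }
  expect_error(apply_environment(two_city_env(), population_state(1:3)),
               "mismatch")
})

test_that("the two-city projection reproduces the hand-computed step", {
  st <- apply_environment(two_city_env(), population_state(c(100, 100)))
  expect_equal(st$sizes, c(110, 90))
  expect_equal(st$time, 1L)
})

test_that("migration decomposition solves the two linear pair relations", {
  mig <- migration_model(rbind(c(0, 0.1), c(0.2, 0)))
  dec <- decompose_migration(mig, c(0.5, 0.5))
  expect_equal(dec$s[1, 2], 0.6)
  expect_equal(dec$delta[1, 2], -0.2)

  set.seed(7)
  for (k in 1:8) {
    n <- sample(2:12, 1)
    mig <- random_migration(n)
    x <- rand_simplex(n)
    dec <- decompose_migration(mig, x)
    expect_equal(dec$s, t(dec$s))
    expect_equal(dec$delta, -t(dec$delta))
    expect_equal(diag(dec$delta), rep(0, n))
    # migration-current conservation
    expect_lt(abs(drop(x %*% dec$delta %*% x)), 1e-12)
    # round-trip is the identity
    back <- compose_migration(dec, x)
    expect_equal(back$m, mig$m, tolerance = 1e-12)
  }
})

test_that("x-reciprocal-symmetric rates have no antisymmetric part", {
  x <- c(0.2, 0.3, 0.5)
  s <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3)
  m <- sweep(s / 2, 2, x, "*")
  diag(m) <- 0
  dec <- decompose_migration(migration_model(m), x)
  expect_equal(max(abs(dec$delta)), 0, tolerance = 1e-14)
})

test_that("composition handles the constant-s uniform case", {
  n <- 5
  s <- matrix(2, n, n); diag(s) <- 0
  dec <- structure(list(s = s, delta = matrix(0, n, n)),
                   class = "migration_decomposition")
  m <- compose_migration(dec, rep(1 / n, n))
  off <- m$m[row(m$m) != col(m$m)]
  expect_equal(off, rep(2 / (2 * n), length(off)))
})

test_that("decomposition requires positive shares", {
  mig <- migration_model(rbind(c(0, 0.1), c(0.2, 0)))
  expect_error(decompose_migration(mig, c(1, 0)), "degenerate")
})

test_that("gravity flows are symmetric and match the direct formula", {
  J <- gravity_flows(c(1000, 2000), rbind(c(0, 10), c(10, 0)),
                     G_g = 0.001, gamma = 1)
  expect_equal(J[1, 2], 200)
  expect_equal(J, t(J))
  expect_equal(gravity_flows(c(10, 20), rbind(c(0, 2), c(2, 0)), 0, 1),
               matrix(0, 2, 2))
  # gamma = 0: distance-free, J ~ N_i N_j
  N <- c(3, 5, 7)
  d <- matrix(1, 3, 3) + diag(3)
  J0 <- gravity_flows(N, 4 * d, 2, 0)
  expect_equal(J0[1, 2] / (N[1] * N[2]), J0[2, 3] / (N[2] * N[3]))
  expect_error(gravity_flows(c(1, 1), matrix(0, 2, 2), 1, 1), "positive")
})

test_that("gravity flows correspond to a purely symmetric decomposition", {
  set.seed(11)
  N <- runif(5, 100, 1000)
  xy <- matrix(runif(10), 5, 2)
  d <- as.matrix(dist(xy))
  J <- gravity_flows(N, d, 1e-5, 1.5)
  m <- J / N
  dec <- decompose_migration(migration_model(m), structure_vector(N))
  expect_lt(max(abs(dec$delta)), 1e-12)
  expect_equal(J, t(J))
})

test_that("system validation detects disconnection and periodicity", {
  set.seed(5)
  expect_true(validate_system(random_valid_env(10))$ok)

  # two disconnected blocks
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- m[3, 4] <- m[4, 3] <- 0.1
  env <- build_environment(vital_rates(rep(0, 4)), migration_model(m))
  rep_ <- validate_system(env)
  expect_false(rep_$strongly_connected)
  expect_false(rep_$ok)

  # pure two-cycle with zero diagonal: strongly connected but period 2
  A <- rbind(c(0, 1), c(1, 0))
  rep2 <- validate_system(A)
  expect_true(rep2$strongly_connected)
  expect_false(rep2$primitive)
})

test_that("purely symmetric flows leave every city unchanged", {
  set.seed(13)
  n <- 6
  x <- rand_simplex(n)
  s <- matrix(runif(n * n), n, n); s <- s + t(s); diag(s) <- 0
  dec <- structure(list(s = s, delta = matrix(0, n, n)),
                   class = "migration_decomposition")
  mig <- compose_migration(dec, x)
  env <- build_environment(vital_rates(rep(0, n)), mig)
  N <- x * 1e5
  expect_equal(apply_environment(env, population_state(N))$sizes, N,
               tolerance = 1e-12)
})
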