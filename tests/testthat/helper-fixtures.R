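# in-code fixtures shared across test files

# random migration matrix with out-rates bounded away from 1
random_migration <- function(n, scale = 0.3) {
  m <- matrix(stats::runif(n * n), n, n)
  diag(m) <- 0
  m <- m * scale / max(rowSums(m))
  migration_model(m)
}

random_valid_env <- function(n, vital_sd = 0.01) {
  build_environment(vital_rates(stats::rnorm(n, 0, vital_sd)),
                    random_migration(n))
}

rand_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# the canonical 2-city example: vital = 0, m12 = 0.1, m21 = 0.2
two_city_env <- function() {
  build_environment(vital_rates(c(0, 0)),
                    migration_model(rbind(c(0, 0.1), c(0.2, 0))))
}

# dense matrix power by repeated squaring (independent oracle for iterate)
mat_pow <- function(A, k) {
  out <- diag(nrow(A))
  B <- A
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% B
    B <- B %*% B
    k <- k %/% 2
  }
  out
}
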