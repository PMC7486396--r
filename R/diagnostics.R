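#' Zipf reference structure vector
#'
#' Shares proportional to `1/rank^z`, normalized (for `z = 1`, by the
#' harmonic number): the neutral rank-size distribution in which the largest
#' city is twice the second and three times the third. Uses compensated
#' (Kahan) summation so the normalizer is accurate up to millions of ranks.
#'
#' @param n number of cities.
#' @param z rank-size exponent (default 1: Zipf's law).
#' @return Simplex vector of length `n`, sorted descending.
#' @export
zipf_reference <- function(n, z = 1) {
  if (n < 1) stop("n must be at least 1")
  w <- 1 / seq_len(n)^z
  s <- 0; c <- 0
  for (v in w) {                       # Kahan summation
    t <- s + v
    c <- c + if (abs(s) >= abs(v)) (s - t) + v else (v - t) + s
    s <- t
  }
  w / (s + c)
}

#' Kullback-Leibler divergence in bits
#'
#' \eqn{D_{KL}(P \| Q) = \sum_i P_i \log_2(P_i / Q_i)}: the information
#' gained when `Q` is replaced by `P`. Terms with `P_i = 0` contribute zero;
#' `Q` is floored at `q_floor` (structure vectors can sit at the boundary
#' floor) and the number of floored entries is attached as an attribute.
#'
#' @param p,q simplex vectors of equal length.
#' @param base logarithm base (2 = bits).
#' @param q_floor floor applied to `q` on the support of `p`.
#' @return Non-negative divergence (0 iff `p == q` on the support of `p`).
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5))  # 1 bit
#' @export
kl_divergence <- function(p, q, base = 2, q_floor = 1e-15) {
  if (length(p) != length(q)) stop("length mismatch")
  supp <- p > 0
  qf <- pmax(q[supp], q_floor)
  n_floored <- sum(q[supp] < q_floor)
  d <- sum(p[supp] * (log(p[supp] / qf) / log(base)))
  structure(max(d, 0), n_floored = n_floored)
}

#' Pointwise surprise relative to a reference distribution
#'
#' \eqn{S_i = \log_2(P_i / Q_i)} in bits; its `P`-average is the KL
#' divergence. Deviations from the Zipf reference carry information about
#' selection (persistent growth preferences between cities).
#'
#' @inheritParams kl_divergence
#' @return Vector of pointwise surprises (NA where `p` is zero).
#' @export
surprise <- function(p, q, base = 2, q_floor = 1e-15) {
  if (length(p) != length(q)) stop("length mismatch")
  out <- rep(NA_real_, length(p))
  supp <- p > 0
  out[supp] <- log(p[supp] / pmax(q[supp], q_floor)) / log(base)
  out
}

#' Fit the rank-size exponent
#'
#' Least-squares regression of `log(size)` on `log(rank)` over a rank
#' window; the rank-size exponent is minus the slope. Sizes are sorted
#' descending internally. The default window `[5, n/2]` avoids the
#' systematic deviations at the extremes of very large and very small
#' cities. Multiplying the sizes by a constant changes the intercept, never
#' the exponent.
#'
#' @param sizes city sizes or shares (any positive scale).
#' @param window integer vector `c(r_lo, r_hi)`; default `c(5, n/2)`
#'   (clipped to at least 3 ranks).
#' @return List of class `"ranksize_fit"`: `z`, `se`, `intercept`
#'   (`log N_0`), `window`, `residuals`, `fit` (the `lm` object).
#' @export
fit_ranksize <- function(sizes, window = NULL) {
  N <- sort(as.numeric(sizes), decreasing = TRUE)
  n <- length(N)
  if (is.null(window)) window <- c(min(5, max(1, n - 2)), max(3, floor(n / 2)))
  r_lo <- max(1L, as.integer(window[1]))
  r_hi <- min(n, as.integer(window[2]))
  if (r_hi - r_lo + 1 < 3) stop("need at least 3 ranks in the fit window")
  r <- r_lo:r_hi
  Nr <- N[r]
  if (any(Nr <= 0)) stop("non-positive sizes inside the fit window")
  fit <- stats::lm(log(Nr) ~ log(r))
  # summary.lm warns on exact power-law input ("essentially perfect fit")
  co <- suppressWarnings(summary(fit)$coefficients)
  structure(list(z = -unname(co[2, 1]), se = unname(co[2, 2]),
                 intercept = unname(co[1, 1]), window = c(r_lo, r_hi),
                 residuals = stats::residuals(fit), fit = fit),
            class = "ranksize_fit")
}

#' @export
print.ranksize_fit <- function(x, ...) {
  cat("rank-size fit over ranks [", x$window[1], ",", x$window[2], "]:\n")
  cat("  z =", format(x$z, digits = 4), "+/-", format(x$se, digits = 3),
      " log N_0 =", format(x$intercept, digits = 4), "\n")
  invisible(x)
}

#' Fit a power-law density exponent from samples
#'
#' Log-binned histogram regression: samples are binned in log-space over
#' `[x_lo, x_hi]`, the per-bin density estimated as count/width, and
#' `log(density)` regressed on `log(midpoint)`. For a density
#' `P(x) ~ x^(-a)` the returned `exponent` estimates `a` (e.g. `2 - alpha`
#' for multiplicative growth whose variance scales as `N^-alpha`).
#'
#' @param samples positive draws from the density.
#' @param x_lo,x_hi fit window (defaults: 5th and 99th percentiles).
#' @param n_bins number of logarithmic bins.
#' @return List of class `"density_fit"`: `exponent`, `se`, `n_bins_used`,
#'   `bin_mids`, `bin_density`.
#' @export
fit_density_exponent <- function(samples, x_lo = NULL, x_hi = NULL,
                                 n_bins = 12L) {
  s <- samples[is.finite(samples) & samples > 0]
  if (is.null(x_lo)) x_lo <- stats::quantile(s, 0.05, names = FALSE)
  if (is.null(x_hi)) x_hi <- stats::quantile(s, 0.99, names = FALSE)
  if (x_lo <= 0 || x_hi <= x_lo) stop("invalid fit window")
  edges <- exp(seq(log(x_lo), log(x_hi), length.out = n_bins + 1))
  h <- graphics::hist(s[s >= x_lo & s <= x_hi], breaks = edges, plot = FALSE)
  keep <- h$counts > 0
  if (sum(keep) < 3) stop("too few occupied bins for a density fit")
  mids <- sqrt(edges[-1] * edges[-(n_bins + 1)])[keep]
  dens <- (h$counts / diff(edges))[keep]
  fit <- stats::lm(log(dens) ~ log(mids))
  co <- summary(fit)$coefficients
  structure(list(exponent = -unname(co[2, 1]), se = unname(co[2, 2]),
                 n_bins_used = sum(keep), bin_mids = mids,
                 bin_density = dens),
            class = "density_fit")
}

#' Cumulative-average structures and their KL trace to Zipf
#'
#' For a sequence of structure snapshots, forms the running (prefix) mean
#' structure and its KL divergence to the Zipf reference: the protocol that
#' reveals Zipf's law as a long-time average even when every individual
#' snapshot deviates from it. Snapshots are rank-aligned by default.
#'
#' @param snapshots matrix of structure vectors (rows = times), or a
#'   `"structure_sim"`.
#' @param ref reference simplex vector (default: Zipf for the column count).
#' @param align `"rank"` (sort each snapshot descending first) or
#'   `"identity"`.
#' @return List: `kl_trace` (KL of each prefix mean to `ref`),
#'   `kl_each` (KL of each individual snapshot), `final_mean`.
#' @export
cumulative_average_kl <- function(snapshots, ref = NULL,
                                  align = c("rank", "identity")) {
  align <- match.arg(align)
  S <- if (inherits(snapshots, "structure_sim")) snapshots$snapshots
       else as.matrix(snapshots)
  if (nrow(S) < 1) stop("need at least one snapshot")
  if (align == "rank") S <- t(apply(S, 1, sort, decreasing = TRUE))
  if (is.null(ref)) ref <- zipf_reference(ncol(S))
  csum <- apply(S, 2, cumsum)
  if (nrow(S) == 1) csum <- matrix(csum, 1)
  kl_trace <- vapply(seq_len(nrow(S)), function(i) {
    p <- csum[i, ] / sum(csum[i, ])
    as.numeric(kl_divergence(p, ref))
  }, numeric(1))
  kl_each <- apply(S, 1, function(p)
    as.numeric(kl_divergence(p / sum(p), ref)))
  final_mean <- csum[nrow(S), ] / sum(csum[nrow(S), ])
  list(kl_trace = kl_trace, kl_each = kl_each, final_mean = final_mean)
}

#' Per-city fitness between consecutive structures
#'
#' The fitness of city `i` over one step is `w_i = x_i(t+1) / x_i(t)`; by
#' normalization the population-mean fitness \eqn{\sum_i w_i x_i(t)} is
#' exactly 1. Neutral dynamics has all `w_i = 1`; departures express
#' selection, and the log-fitness channel is the per-step information gain
#' whose ensemble average is the mutual information between structure and
#' environment.
#'
#' @param x_t,x_t1 consecutive structure vectors on the same support.
#' @return List of class `"fitness_report"`: `w`, `mean_fitness`,
#'   `log_fitness` (bits), `neutral` (logical: all `w == 1` to 1e-12).
#' @export
fitness_report <- function(x_t, x_t1) {
  x_t <- structure_vector(x_t); x_t1 <- structure_vector(x_t1)
  if (length(x_t) != length(x_t1)) stop("length mismatch")
  if (any(x_t == 0 & x_t1 > 0))
    stop("zero share in x_t with nonzero successor: fitness undefined")
  w <- ifelse(x_t > 0, x_t1 / x_t, 1)
  structure(list(w = w, mean_fitness = sum(w * x_t),
                 log_fitness = log2(w),
                 neutral = all(abs(w - 1) < 1e-12)),
            class = "fitness_report")
}

#' Implied number of ghost cities at a given size
#'
#' Zipf's rank-size rule `N(r) = N_0 / r^z` inverted: the rank (and thus the
#' implied count of cities at or above that size, down to unit resolution)
#' at size `N` is `(N_0 / N)^(1/z)`. With a 20-million-person largest city
#' and `z = 1`, current conservation at the lower boundary implies 20
#' million one-person cities, 2 million of size 10, 200,000 of size 100 --
#' the Zipfian ghost distribution below the smallest sampled city.
#'
#' @param N0 size of the largest city.
#' @param size city size(s) at which to evaluate.
#' @param z rank-size exponent.
#' @return Implied count(s) `(N0/size)^(1/z)`.
#' @examples
#' ghost_city_count(2e7, c(1, 10, 100))
#' @export
ghost_city_count <- function(N0, size, z = 1) {
  if (N0 <= 0 || any(size <= 0) || z <= 0) stop("arguments must be positive")
  (N0 / size)^(1 / z)
}
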