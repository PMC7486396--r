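#' Stationary zero-current (Zipf) density
#'
#' The stationary solution of the geometric-growth Fokker-Planck equation
#' with vanishing probability current on `[x_m, x_M]`:
#' \eqn{P(x) = \alpha_1 / x^2} with
#' \eqn{\alpha_1 = x_M x_m / (x_M - x_m)} fixed by normalization. This is
#' the Pareto density with exponent 2, i.e. Zipf's rank-size law with
#' exponent 1.
#'
#' @param x_m,x_M lower and upper share boundaries, `0 < x_m < x_M`.
#' @return List of class `"fp_density"`: `pdf` (vectorized function on
#'   `[x_m, x_M]`), `alpha1`, `x_m`, `x_M`, `current` (0).
#' @examples
#' d <- stationary_zipf_density(0.5, 1)
#' d$alpha1  # 1
#' @export
stationary_zipf_density <- function(x_m, x_M) {
  if (!(0 < x_m && x_m < x_M)) stop("require 0 < x_m < x_M")
  alpha1 <- x_M * x_m / (x_M - x_m)
  pdf <- function(x) ifelse(x >= x_m & x <= x_M, alpha1 / x^2, 0)
  structure(list(pdf = pdf, alpha1 = alpha1, x_m = x_m, x_M = x_M,
                 current = 0), class = "fp_density")
}

#' Stationary constant-current density
#'
#' The second stationary family of the same equation carries a constant
#' probability current across the hierarchy: \eqn{P(x) \propto 1/x},
#' normalized as \eqn{P(x) = c/x} with `c = 1/log(x_M/x_m)`. The associated
#' current (in the convention `J = d/dx[(sigma^2/2) x^2 P]`) is
#' `J = sigma^2 c / 2`.
#'
#' @inheritParams stationary_zipf_density
#' @param sigma volatility (only sets the reported current's scale).
#' @return List of class `"fp_density"`: `pdf`, `coef` (= `c`), `x_m`,
#'   `x_M`, `current`.
#' @export
stationary_constant_current_density <- function(x_m, x_M, sigma = 1) {
  if (!(0 < x_m && x_m < x_M)) stop("require 0 < x_m < x_M")
  coef <- 1 / log(x_M / x_m)
  pdf <- function(x) ifelse(x >= x_m & x <= x_M, coef / x, 0)
  structure(list(pdf = pdf, coef = coef, x_m = x_m, x_M = x_M,
                 current = sigma^2 * coef / 2), class = "fp_density")
}

#' Lognormal transient of free multiplicative growth
#'
#' Without boundary conditions the share density spreads as a lognormal
#' with log-mean \eqn{\ln x_0 - (\sigma^2/2)(t - t_0)} and log-variance
#' \eqn{\sigma^2 (t - t_0)}: the distribution drifts toward ever smaller
#' shares while broadening, which is what the ghost-city boundary current
#' ultimately arrests.
#'
#' @param x evaluation points (positive).
#' @param t time; must exceed `t0`.
#' @param x0 initial share (the density starts as a point mass at `x0`).
#' @param t0 initial time.
#' @param sigma volatility per sqrt(step).
#' @return Density values at `x` (integrates to 1 on (0, Inf)).
#' @export
lognormal_transient <- function(x, t, x0, t0 = 0, sigma) {
  if (t <= t0) stop("t must exceed t0")
  if (x0 <= 0 || sigma <= 0) stop("x0 and sigma must be positive")
  dt <- t - t0
  stats::dlnorm(x, meanlog = log(x0) - sigma^2 / 2 * dt,
                sdlog = sigma * sqrt(dt))
}

#' Logarithmic finite-volume grid for the share axis
#'
#' Cells uniform in `y = log x` on `[x_m, x_M]`; densities live at cell
#' centers (geometric midpoints of the faces).
#'
#' @param x_m,x_M domain boundaries.
#' @param n number of cells.
#' @return List: `centers`, `faces` (length `n+1`), `dx` (cell widths).
#' @export
fp_grid <- function(x_m, x_M, n = 512L) {
  faces <- exp(seq(log(x_m), log(x_M), length.out = n + 1))
  centers <- sqrt(faces[-1] * faces[-(n + 1)])
  list(centers = centers, faces = faces, dx = diff(faces))
}

#' Numerically evolve a share density under geometric diffusion
#'
#' Conservative finite-volume integration of
#' \eqn{dP/dt = d^2/dx^2 [(\sigma^2/2) x^2 P]} on a logarithmic grid, with
#' implicit (backward Euler) time stepping, so no step-size stability limit
#' applies. The flux through each interior face is the difference quotient
#' of \eqn{Q = (\sigma^2/2) x^2 P} between the adjacent cell centers, which
#' makes the discrete zero-current stationary state exactly
#' \eqn{x^2 P = const}.
#'
#' Boundary handling:
#' \describe{
#'   \item{`zero-current`}{no flux through either boundary; total
#'     probability is conserved and the long-time state is the Zipf density
#'     \eqn{\alpha_1/x^2}.}
#'   \item{`absorbing`}{the lower face is held at `Q = 0` (probability
#'     leaks out through the floor); used for extinction-time checks.}
#'   \item{`constant-current`}{a fixed current `J0` enters at the lower and
#'     leaves at the upper face; with the default
#'     `J0 = sigma^2 / (2 log(x_M/x_m))` the unit-mass stationary state is
#'     the pure `1/x` law.}
#' }
#'
#' @param P0 initial density: a function of `x`, or a vector on the
#'   `fp_grid(x_m, x_M, n_cells)` centers. It is renormalized to unit mass.
#' @param sigma volatility per sqrt(step).
#' @param x_m,x_M domain boundaries.
#' @param T total integration time (steps).
#' @param boundary one of `"zero-current"`, `"absorbing"`,
#'   `"constant-current"`.
#' @param n_cells number of finite-volume cells.
#' @param dt time step (default `T/2000`).
#' @param J0 imposed current for `"constant-current"`.
#' @param save_every record the density every `save_every` steps (0 = final
#'   only).
#' @return List of class `"fp_solution"`: `grid`, `P` (final density),
#'   `mass` (final total probability), `mass_trace`, `times`, `P_trace`
#'   (matrix, if `save_every > 0`), `boundary`.
#' @export
evolve_density_numeric <- function(P0, sigma, x_m, x_M, T,
                                   boundary = c("zero-current", "absorbing",
                                                "constant-current"),
                                   n_cells = 512L, dt = NULL, J0 = NULL,
                                   save_every = 0L) {
  boundary <- match.arg(boundary)
  g <- fp_grid(x_m, x_M, n_cells)
  xc <- g$centers; dx <- g$dx; n <- length(xc)
  P <- if (is.function(P0)) P0(xc) else as.numeric(P0)
  if (length(P) != n) stop("P0 vector must match the grid (", n, " cells)")
  if (any(P < 0)) stop("initial density must be non-negative")
  mass0 <- sum(P * dx)
  if (mass0 <= 0) stop("initial density has no mass")
  P <- P / mass0
  if (is.null(dt)) dt <- T / 2000
  n_steps <- max(1L, ceiling(T / dt))
  dt <- T / n_steps

  # dP_i/dt = (J_{i+1/2} - J_{i-1/2}) / dx_i, J at interior face k (between
  # cells k and k+1) = (Q_{k+1} - Q_k) / (xc_{k+1} - xc_k), Q = (s2/2) x^2 P.
  s2 <- sigma^2
  q <- s2 / 2 * xc^2                       # Q_i = q_i * P_i
  dxc <- diff(xc)
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    if (i < n) {                           # face i+1/2
      L[i, i + 1] <- L[i, i + 1] + q[i + 1] / (dxc[i] * dx[i])
      L[i, i]     <- L[i, i]     - q[i]     / (dxc[i] * dx[i])
    }
    if (i > 1) {                           # face i-1/2
      L[i, i - 1] <- L[i, i - 1] + q[i - 1] / (dxc[i - 1] * dx[i])
      L[i, i]     <- L[i, i]     - q[i]     / (dxc[i - 1] * dx[i])
    }
  }
  b <- numeric(n)
  if (boundary == "absorbing") {
    # ghost value Q = 0 just below the lower face
    gap <- xc[1] - g$faces[1]
    L[1, 1] <- L[1, 1] - q[1] / (gap * dx[1])
  } else if (boundary == "constant-current") {
    if (is.null(J0)) J0 <- s2 / (2 * log(x_M / x_m))
    b[1] <- -J0 / dx[1]
    b[n] <- J0 / dx[n]
  }
  M <- diag(n) - dt * L
  Minv <- solve(M)

  keep <- save_every > 0L
  times <- numeric(0); mass_trace <- numeric(0)
  P_trace <- if (keep) matrix(NA_real_, ceiling(n_steps / save_every), n)
  k <- 0L
  for (s in seq_len(n_steps)) {
    P <- drop(Minv %*% (P + dt * b))
    if (keep && s %% save_every == 0L) {
      k <- k + 1L
      P_trace[k, ] <- P
      times <- c(times, s * dt)
      mass_trace <- c(mass_trace, sum(P * dx))
    }
  }
  structure(list(grid = g, P = P, mass = sum(P * dx),
                 mass_trace = mass_trace, times = times,
                 P_trace = if (keep) P_trace[seq_len(k), , drop = FALSE],
                 boundary = boundary, sigma = sigma, dt = dt),
            class = "fp_solution")
}

#' Sine-mode expansion of the boundary-value solution
#'
#' Expands a deviation `g0(y)` from the stationary Zipf profile (in the log
#' coordinate `y`, vanishing at both boundaries) in the sine basis
#' \eqn{\sqrt{2/L} \sin k_n (y - y_m)}, `k_n = 2 pi n / L`,
#' `L = y_M - y_m`, and reconstructs the printed time-dependent form
#' \eqn{g(y,\tau) = \sum_n a_n \sqrt{2/L} \sin k_n[(y-y_m) - 3\tau]
#' e^{-(k_n^2 - 2)\tau}} (with \eqn{\tau = (\sigma^2/2)(t - t_0)}).
#' The coefficients are computed by trapezoidal quadrature of the sine
#' projection. At `tau = 0` the reconstruction reproduces any `g0` in the
#' span of the basis; see the methods vignette for the limitations of this
#' expansion at `tau > 0`.
#'
#' @param g0 initial deviation: function of `y`, or vector on a uniform `y`
#'   grid spanning `[y_m, y_M]`.
#' @param y_m,y_M boundaries in the log coordinate.
#' @param n_modes number of sine modes.
#' @param n_grid quadrature grid size (when `g0` is a function).
#' @return List of class `"fp_modes"`: `a` (coefficients), `k` (wavenumbers),
#'   `y` (grid), `reconstruct(y, tau)` closure.
#' @export
eigenexpansion <- function(g0, y_m, y_M, n_modes = 64L, n_grid = 2048L) {
  if (y_M <= y_m) stop("require y_m < y_M")
  L <- y_M - y_m
  if (is.function(g0)) {
    y <- seq(y_m, y_M, length.out = n_grid)
    gv <- g0(y)
  } else {
    gv <- as.numeric(g0)
    y <- seq(y_m, y_M, length.out = length(gv))
  }
  if (abs(gv[1]) > 1e-8 || abs(gv[length(gv)]) > 1e-8)
    stop("g0 must vanish at both boundaries")
  k <- 2 * pi * seq_len(n_modes) / L
  norm <- sqrt(2 / L)
  trap <- function(f) {
    h <- y[2] - y[1]
    h * (sum(f) - (f[1] + f[length(f)]) / 2)
  }
  a <- vapply(seq_len(n_modes), function(n)
    norm * trap(gv * sin(k[n] * (y - y_m))), numeric(1))
  reconstruct <- function(yy, tau = 0) {
    out <- numeric(length(yy))
    for (n in seq_len(n_modes))
      out <- out + a[n] * norm * sin(k[n] * ((yy - y_m) - 3 * tau)) *
        exp(-(k[n]^2 - 2) * tau)
    out
  }
  structure(list(a = a, k = k, y = y, reconstruct = reconstruct,
                 y_m = y_m, y_M = y_M),
            class = "fp_modes")
}

#' Characteristic demographic time scales of the stochastic regime
#'
#' The growth-rate reversal time \eqn{t_r = 1/(2\sigma^2)} and the
#' logarithmic extinction-time estimate
#' \eqn{\langle \Delta t(r) \rangle = t_r \ln(r_{max}/r)} for a city of
#' initial rank `r`; the deepest (rank-1) city has
#' \eqn{t_r \ln r_{max}}. Doubling `sigma` quarters `t_r`.
#'
#' @param sigma volatility per sqrt(step).
#' @param r_max maximum rank (number of cities in the sample).
#' @param r initial rank(s), `1 <= r <= r_max`.
#' @return List: `t_r`, `mean_extinction` (vector over `r`),
#'   `largest_city_time`.
#' @export
characteristic_times <- function(sigma, r_max, r = 1) {
  if (sigma <= 0) stop("sigma must be positive")
  if (any(r < 1 | r > r_max)) stop("ranks must lie in [1, r_max]")
  t_r <- 1 / (2 * sigma^2)
  list(t_r = t_r, mean_extinction = t_r * log(r_max / r),
       largest_city_time = t_r * log(r_max))
}
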