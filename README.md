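# zipfdyn

Demographic dynamics of city-size distributions in R.

City sizes in many urban systems roughly follow Zipf's rank-size rule
`N(r) = N_0 / r^z` with `z = 1` — the largest city twice the second, three
times the third — yet real data bend away from it at both ends, and the
exponent wanders across systems and eras. `zipfdyn` implements a
demographic account of where such rank-size laws come from and what
deviations from them mean. It is aimed at quantitative geographers,
demographers, and anyone studying multiplicative growth on a simplex
(species abundances and word frequencies share the mathematics).

The framework, bottom to top:

* **Environment matrices.** City populations evolve as
  `N(t) = A(t) N(t-1)`, where the environment `A` collects vital rates
  `υ_i = b_i − d_i` on the diagonal (with retention `1 + υ_i − m_i_out`)
  and migration probabilities `m_ji` off it. In a static, strongly
  connected, aperiodic environment the relative size distribution converges
  to the leading eigenvector `e_0`, at rate set by the spectral gap
  (`t* = 1/ln(λ_0/|λ_1|)`) — and it looks nothing like Zipf in general.
* **Migration decomposition.** Flows split as
  `J_ij = ((s_ij + δ_ij)/2) x_j N_i` into a symmetric part (the gravity law
  `J_ij = G N_i N_j / d_ij^γ` is the fully symmetric case) and an
  antisymmetric part `δ` which alone moves relative sizes:
  `x_i(t+1) = [1 + υ_i − ῡ − Σ_j δ_ij x_j] x_i(t)`.
* **Symmetry restoration.** When vital and migration rates fluctuate with
  vanishing temporal means, every city's share performs driftless
  multiplicative growth (`dx = σ x dW`). With a lower share boundary
  `x_m = N_0/(N_c N_T)` standing in for the "ghost" population of
  cities too small to observe, the stationary density of the associated
  Fokker–Planck equation `dP/dt = d²/dx²[(σ²/2) x² P]` at zero probability
  current is `P = α_1/x²` with `α_1 = x_M x_m/(x_M − x_m)` — Zipf's law —
  while a constant current gives `P ∝ 1/x`. Zipf is the *neutral* state
  (per-city fitness `w_i = x_i(t+1)/x_i(t) ≡ 1`); deviations carry
  information, measured in bits as the KL divergence to the Zipf reference.

The package provides the simulators (deterministic, self-consistent
nonlinear, and stochastic with the ghost-city boundary rule), exact and
finite-volume numerical Fokker–Planck solutions, the extinction-time
estimates, rank-size and information diagnostics, and readers for
origin–destination flow tables with county-to-metro crosswalk aggregation.

## Worked example

```r
library(zipfdyn)

# a two-city environment: 10% move 1 -> 2, 20% move 2 -> 1 per step
mig <- migration_model(rbind(c(0, 0.10), c(0.20, 0)))
env <- build_environment(vital_rates(c(0, 0)), mig)
stationary_structure(env)
#> [1] 0.6666667 0.3333333
convergence_time(env)
#> [1] 2.803673
```

Two-thirds of the population ends up in city 1 (the eigenvector centrality
of the flow graph), regardless of initial sizes, within a few multiples of
`t* ≈ 2.8` steps.

```r
# symmetry-restored stochastic dynamics for 100 cities
cfg <- stochastic_config(n_cities = 100, sigma = 0.05, T = 2e4, burn_in = 5e3)
sim <- simulate_structure(cfg, seed = 42)
sim
#> stochastic structure simulation: 100 cities, 20000 steps (burn-in 5000 )
#>   sigma = 0.05  alpha = 0  migration noise: TRUE
#>   lower boundary x_m = 0.001928 | resets: 49581 | clipped growth factors: 1
#>   time-averaged rank-size exponent z = 0.9078
```

Under zero-temporal-mean noise the time-averaged rank-size exponent sits
near 1 (about 0.90 at these conditions — the small systematic shortfall is
a real property of the boundary rule at 100 cities, dissected in the
vignette). The lower boundary here is the share of the smallest city in a
Zipf hierarchy, `x_m = 0.19/100`; `resets` counts ghost-city boundary
events.

```r
# the stationary laws the simulation is converging around
stationary_zipf_density(1e-4, 1)$alpha1
#> [1] 0.00010001
kl_divergence(sim$mean_sorted, zipf_reference(100))
#> [1] 0.05357025
```

The time-averaged structure is about 0.05 bits away from the exact Zipf
reference.

A thin command-line front end over the same functions is installed at
`inst/cli/zipfdyn` (`simulate-stochastic`, `gen-scenario`, `fp-stationary`,
`diagnose`), writing delimited-text tables plus a JSON run manifest.

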