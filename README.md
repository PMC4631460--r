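# cntrack

Recursive Bayesian estimation of a time-varying local concentration of
signal molecules (NO, H₂O₂) from the stochastic single-molecule
adsorption/desorption counts reported by carbon-nanotube sensor arrays —
for researchers designing or analyzing nIR-fluorescent SWNT sensing
experiments, and for anyone who wants a compact, fully tested testbed for
nonlinear/non-Gaussian filtering on chemical-master-equation data.

## The model

A sensor exposes `N_T ≈ 10` binding sites. Free molecules at local
concentration `C(t)` bind to an empty site with effective rate `k_A C`
and unbind with rate `k_D`; every `Δt` seconds the integer occupancy
`y_k ∈ {0..N_T}` is read out. Because the sites are independent, the
chemical master equation solves in closed form: conditional on the
previous count,

    y_k | y_{k-1}, C  ~  Bin(y_{k-1}, λ_F) * Bin(N_T − y_{k-1}, λ_E)

with `λ_E = k_A C (1 − e^{−aΔt})/a`, `λ_F = λ_E + e^{−aΔt}`,
`a = k_A C + k_D` — a convolution of two binomials that is strongly
non-Gaussian at these occupancies.

The concentration itself follows a random walk
`x_k = x_{k-1} + w_k`, `w_k ~ N(0, q)`; in the two-state (tumor-like)
setting a hidden Markov regime `r_k` with transition matrix
`Π = [[0.99, 0.01], [0.01, 0.99]]` switches the walk variance between a
quiescent `q_1 = 1e-16 M²` and a drifting `q_2 = 5e-14 M²`.

Four estimators recover `C(t)` (and the regime) from one or several
count trajectories:

| method | observation model | regime-aware |
|---|---|---|
| `kf` | moment-matched Gaussian, analytic linearization | no |
| `pf` | exact convolved-binomial likelihood, 200 particles | no |
| `kf-gpb2` | Gaussian, branched over recent regime pairs (GPB2) | yes |
| `pf-mcmc` | exact, particle populations branched over regime pairs | yes |

A kinetic Monte Carlo (Gillespie) simulator generates ground truth with
exactly the statistical structure the estimators assume, and a benchmark
harness reports averaged scaled RMSEs (concentration × 1e5, so 1.0 means
a 10 µM error) over replicated experiments.

## Worked example

```r
library(cntrack)

p <- sensor_params(kA = 100, kD = 0.001, NT = 10, dt = 1)
d <- generate_dataset(process_model("random_walk", q = 1e-16, x0 = 1e-5),
                      p, Ns = 5, n_steps = 2000, seed = 42)
d
#> Sensor-array dataset: 2000 instants x 5 sensor(s), dt = 1 s
#>   true concentration: 9.47e-06 .. 1.01e-05 M
#>   counts: 0 .. 9 of NT = 10 sites

cnt_filter(d, "pf", seed = 1)
#> Concentration estimate: bootstrap particle filter
#>   2000 instants, 5 sensor(s)
#>   final estimate: 1.115e-05 M (truth 9.689e-06 M)
#>   scaled RMSE (x1e5 M): 0.3513

cnt_filter(d, "kf")
#> Concentration estimate: Kalman filter
#>   2000 instants, 5 sensor(s)
#>   final estimate: 1.01e-05 M (truth 9.689e-06 M)
#>   scaled RMSE (x1e5 M): 0.3146
```

Both filters start from a deliberately wrong initial guess (2e-5 M,
twice the truth) and converge onto the ~10 µM truth; the scaled RMSE of
~0.3 says the average estimation error over the whole run was ~3 µM,
most of it accrued while the wrong guess was being corrected. A small
replicated benchmark:

```r
run_benchmark("normal", sensor_counts = c(1, 5), n_runs = 20, seed = 1)
#> Averaged scaled RMSE (x1e5 M) over 20 runs
#>  estimator n_sensors n_runs   rmse mc_se seconds
#>         pf         1     20 0.5337 0.037 0.09200
#>         kf         1     20 0.6041 0.052 0.00055
#>         pf         5     20 0.2379 0.016 0.12000
#>         kf         5     20 0.2391 0.017 0.00160
```

With a single sensor the exact-likelihood particle filter beats the
Gaussian-approximation Kalman filter; with five sensors the extra
information closes the gap — the qualitative behavior the method was
designed to expose. `summary()`, `fitted()`, `residuals()` and `plot()`
work on every fit, `write_estimates_csv()` / `write_dataset_csv()`
serialize results, and `inst/cli/cntrack.R` wraps simulate / estimate /
benchmark for shell use.

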