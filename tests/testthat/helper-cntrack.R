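# Shared fixtures and independent oracles for the test suite.

test_params <- function(kA = 100, kD = 0.001, NT = 10, dt = 1) {
  sensor_params(kA = kA, kD = kD, NT = NT, dt = dt)
}

# Total variation distance between two pmfs on the same support.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# Exact mean/variance of a pmf on {0..n}.
pmf_mean <- function(p) sum((seq_along(p) - 1) * p)
pmf_var <- function(p) sum((seq_along(p) - 1)^2 * p) - pmf_mean(p)^2

# Independent exact Bayes filter on a dense concentration grid.  The
# state transition is the reflected-at-zero Gaussian random walk the
# particle filter samples from; the likelihood is the R-level
# convolved-binomial pmf (itself cross-checked against the CME matrix
# exponential), so this path shares no code with the compiled particle
# filter being tested.
# Vectorized convolved-binomial likelihood over a concentration grid,
# built from stats::dbinom (independent of the compiled kernel).
lik_grid <- function(params, y, y_prev, Cvec) {
  lam <- occupancy_fractions(params, Cvec)
  out <- rep(1, length(Cvec))
  for (j in seq_along(y)) {
    yp <- y_prev[j]; yy <- y[j]
    l <- 0
    for (m in max(0, yy - (params$NT - yp)):min(yy, yp))
      l <- l + stats::dbinom(m, yp, lam$lamF) *
        stats::dbinom(yy - m, params$NT - yp, lam$lamE)
    out <- out * l
  }
  out
}

grid_filter <- function(dataset, q, init_mean, init_var,
                        Cmax = 1e-4, n_grid = 4000) {
  p <- dataset$params
  dx <- Cmax / n_grid
  cgrid <- (seq_len(n_grid) - 0.5) * dx # cell midpoints: O(dx^2) rule
  post <- stats::dnorm(cgrid, init_mean, sqrt(init_var))
  post <- post / sum(post)
  sdq <- sqrt(q)
  # reflected random-walk kernel: K(x'|x) = phi(x'-x) + phi(x'+x)
  Tm <- outer(cgrid, cgrid,
              function(xp, x) stats::dnorm(xp - x, 0, sdq) +
                stats::dnorm(xp + x, 0, sdq)) * dx
  K <- nrow(dataset$counts)
  means <- numeric(K)
  y_prev <- dataset$y0
  for (k in seq_len(K)) {
    post <- as.vector(Tm %*% post)
    post <- post * lik_grid(p, dataset$counts[k, ], y_prev, cgrid)
    post <- post / sum(post)
    means[k] <- sum(post * cgrid)
    y_prev <- dataset$counts[k, ]
  }
  means
}

# One-step posterior mean by dense quadrature from a Gaussian prior over
# the concentration (truncated at 0), for a single observation vector.
grid_one_step <- function(params, prior_mean, prior_sd, q, y, y_prev,
                          Cmax = 1e-4, n_grid = 4000) {
  dx <- Cmax / n_grid
  cgrid <- (seq_len(n_grid) - 0.5) * dx
  prior <- stats::dnorm(cgrid, prior_mean, prior_sd)
  sdq <- sqrt(q)
  if (sdq > 0) { # propagate through the reflected random walk
    Tm <- outer(cgrid, cgrid,
                function(xp, x) stats::dnorm(xp - x, 0, sdq) +
                  stats::dnorm(xp + x, 0, sdq)) * dx
    prior <- as.vector(Tm %*% (prior / sum(prior)))
  }
  post <- prior * lik_grid(params, y, y_prev, cgrid)
  post <- post / sum(post)
  sum(post * cgrid)
}

make_rw_dataset <- function(n_steps = 200, Ns = 1, seed = 1, q = 1e-16,
                            x0 = 1e-5, params = test_params()) {
  generate_dataset(process_model("random_walk", q = q, x0 = x0), params,
                   Ns = Ns, n_steps = n_steps, seed = seed)
}

make_switch_dataset <- function(n_steps = 4000, Ns = 1, seed = 1,
                                switch_time = 2000,
                                qs = c(1e-16, 5e-14),
                                params = test_params()) {
  reg <- regime_model(qs = qs, switch_time = switch_time)
  generate_dataset(process_model("regime_switching", regime = reg,
                                 x0 = 1e-5),
                   params, Ns = Ns, n_steps = n_steps,
                   y0_policy = "random", seed = seed)
}
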