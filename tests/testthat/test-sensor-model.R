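# Exact observation model: site probabilities, continuum mean, convolved
# binomial kernel, CME oracle, Gaussian moment matching.

test_that("occupancy fractions match hand-derived values and limits", {
  # no desorption: occupied sites never empty
  p0 <- test_params(kD = 0)
  lam <- occupancy_fractions(p0, 1e-5)
  expect_equal(lam$lamF, 1)
  expect_equal(lam$lamE, -expm1(-1e-3))

  # vanishing interval: identity kernel
  pdt <- test_params(dt = 1e-12)
  lam <- occupancy_fractions(pdt, 1e-5)
  expect_equal(lam$lamF, 1, tolerance = 1e-9)
  expect_equal(lam$lamE, 0, tolerance = 1e-9)

  # direct evaluation at a = kA*C + kD = 2e-3
  p <- test_params()
  lam <- occupancy_fractions(p, 1e-5)
  expect_equal(lam$lamE, 0.5 * (1 - exp(-2e-3)), tolerance = 1e-12)
  expect_equal(lam$lamF, lam$lamE + exp(-2e-3), tolerance = 1e-12)
  expect_equal(round(lam$lamF, 7), 0.9990010)
  expect_equal(round(lam$lamE, 7), 0.0009990)

  # pure-desorption limit at C = 0
  lam <- occupancy_fractions(p, 0)
  expect_equal(lam$lamE, 0)
  expect_equal(lam$lamF, exp(-p$kD * p$dt))

  expect_error(occupancy_fractions(p, -1e-6), "nonnegative")
})

test_that("lamF - lamE identity and monotonicity hold on a grid", {
  for (kD in c(0, 1e-3, 0.1)) {
    p <- test_params(kD = kD)
    C <- c(0, 1e-8, 1e-6, 1e-5, 1e-4, 1e-2)
    lam <- occupancy_fractions(p, C)
    expect_equal(lam$lamF - lam$lamE, exp(-(p$kA * C + p$kD) * p$dt),
                 tolerance = 1e-14)
    expect_true(all(lam$lamE >= 0 & lam$lamF <= 1))
    expect_true(all(lam$lamE <= lam$lamF))
    expect_true(all(diff(lam$lamE) > 0)) # lamE strictly increasing in C
  }
})

test_that("continuum update matches its ODE, fixed point, and identity", {
  p <- test_params()
  # from empty: one step equals NT * lamE
  expect_equal(continuum_update(p, 0, 1e-5),
               10 * occupancy_fractions(p, 1e-5)$lamE, tolerance = 1e-14)
  expect_equal(round(continuum_update(p, 0, 1e-5), 6), 0.009990)

  # steady state is a fixed point
  for (C in c(1e-6, 1e-5, 1e-4)) {
    Nss <- p$NT * p$kA * C / (p$kA * C + p$kD)
    expect_equal(continuum_update(p, Nss, C), Nss, tolerance = 1e-10)
  }

  # C = 0 limit: pure exponential desorption
  expect_equal(continuum_update(p, 4, 0), 4 * exp(-p$kD * p$dt))

  # algebraic identity N*lamF + (NT-N)*lamE over a grid
  for (C in c(0, 1e-6, 1e-5, 1e-3)) {
    lam <- occupancy_fractions(p, C)
    for (N in c(0, 0.5, 3, 9.2, 10))
      expect_equal(continuum_update(p, N, C),
                   N * lam$lamF + (p$NT - N) * lam$lamE, tolerance = 1e-13)
  }

  # one-interval numerical integration of the mean-field ODE
  skip_if_not_installed("deSolve")
  ode_step <- function(N0, C) {
    f <- function(t, y, parms)
      list(p$kA * C * (p$NT - y) - p$kD * y)
    deSolve::ode(N0, c(0, p$dt), f, NULL, method = "ode45")[2, 2]
  }
  for (C in c(1e-6, 1e-5, 1e-4))
    for (N0 in c(0, 2, 7))
      expect_equal(continuum_update(p, N0, C), unname(ode_step(N0, C)),
                   tolerance = 1e-8)

  expect_error(continuum_update(p, -0.1, 1e-5), "N_prev")
  expect_error(continuum_update(p, 10.5, 1e-5), "N_prev")
})

test_that("transition pmf is normalized and reduces to a single binomial", {
  p <- test_params()
  for (C in c(0, 1e-6, 1e-5, 1e-4))
    for (yp in 0:10)
      expect_lt(abs(sum(transition_pmf(p, yp, C)) - 1), 1e-12)

  # y_prev = 0: single binomial with lam = continuum_update(0, C) / NT
  for (C in c(1e-6, 1e-5, 1e-4)) {
    lam <- continuum_update(p, 0, C) / p$NT
    expect_equal(transition_pmf(p, 0, C), dbinom(0:10, 10, lam),
                 tolerance = 1e-12)
  }
  # empty start, one step: no molecule adsorbs with prob (1 - lamE)^10
  lamE <- occupancy_fractions(p, 1e-5)$lamE
  expect_equal(transition_pmf(p, 0, 1e-5)[1], (1 - lamE)^10,
               tolerance = 1e-12)
  expect_equal(transition_pmf(p, 0, 1e-5)[1], 0.990055, tolerance = 1e-6)

  # vanishing interval: point mass at the previous count
  pdt <- test_params(dt = 1e-9)
  for (yp in c(0, 4, 10)) {
    pmf <- transition_pmf(pdt, yp, 1e-5)
    expect_equal(pmf[yp + 1L], 1, tolerance = 1e-6)
  }

  expect_error(transition_pmf(p, 11, 1e-5), "y_prev")
  expect_error(transition_pmf(p, 2.5, 1e-5), "y_prev")
})

test_that("transition pmf agrees with CME matrix-exponential propagation", {
  p <- test_params()
  for (C in c(0, 1e-6, 1e-5, 1e-4)) {
    for (yp in 0:10) {
      init <- replace(numeric(11), yp + 1L, 1)
      expect_lt(tv_dist(transition_pmf(p, yp, C),
                        cme_propagate(p, init, C, p$dt)), 1e-8)
    }
  }
})

test_that("CME propagation respects identity, stationarity, and the ODE", {
  p <- test_params()
  init <- replace(numeric(11), 3, 1)
  expect_identical(cme_propagate(p, init, 1e-5, 0), init)

  # long-horizon law is Binomial(NT, kA C / (kA C + kD)) = Binomial(10, .5)
  station <- cme_propagate(p, init, 1e-5, 5e4)
  expect_lt(tv_dist(station, dbinom(0:10, 10, 0.5)), 1e-8)
  expect_equal(pmf_mean(station), 5, tolerance = 1e-7)

  # eigen-analysis: the stationary law spans the generator's null space
  G <- cme_generator(p, 1e-5)
  expect_equal(as.vector(dbinom(0:10, 10, 0.5) %*% G), numeric(11),
               tolerance = 1e-12)

  expect_error(cme_propagate(p, rep(0.5, 11), 1e-5, 1), "probability")

  skip_if_not_installed("deSolve")
  f <- function(t, y, parms) list(as.vector(y %*% G))
  num <- deSolve::ode(init, c(0, 1), f, NULL, method = "ode45")[2, -1]
  expect_lt(tv_dist(unname(num), cme_propagate(p, init, 1e-5, 1)), 1e-7)
})

test_that("Gaussian moments equal the exact pmf moments", {
  p <- test_params()
  for (C in c(0, 1e-6, 1e-5, 1e-4)) {
    for (yp in c(0, 3, 7, 10)) {
      mom <- gaussian_obs_moments(p, yp, C)
      pmf <- transition_pmf(p, yp, C)
      expect_equal(mom$mean, continuum_update(p, yp, C), tolerance = 1e-12)
      expect_equal(mom$mean, pmf_mean(pmf), tolerance = 1e-10)
      expect_equal(mom$var, pmf_var(pmf), tolerance = 1e-10)
      expect_gte(mom$var, 0)
      expect_true(mom$mean >= 0 && mom$mean <= p$NT)
    }
  }
  mom <- gaussian_obs_moments(p, 0, 0)
  expect_equal(mom$mean, 0)
  expect_equal(mom$var, 0)
})

test_that("count log-likelihood is consistent in both modes", {
  p <- test_params()
  # exact mode normalizes
  for (yp in c(0, 5, 10)) {
    ll <- vapply(0:10, function(y) count_loglik(p, y, yp, 1e-5), 0)
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-12)
  }
  # identity kernel at dt -> 0
  pdt <- test_params(dt = 1e-9)
  expect_equal(count_loglik(pdt, 5, 5, 1e-5), 0, tolerance = 1e-6)

  # gaussian mode differs from exact by a bounded, nonzero amount
  exact <- transition_pmf(p, 5, 1e-5)
  gauss <- vapply(0:10, function(y)
    exp(count_loglik(p, y, 5, 1e-5, mode = "gaussian")), 0)
  tv <- tv_dist(exact, gauss / sum(gauss))
  expect_gt(tv, 1e-4) # genuinely different distributions
  expect_lt(tv, 0.2)  # but a close approximation

  # degenerate gaussian mode: var = 0 at C = 0, kD = 0
  p0 <- test_params(kD = 0)
  expect_equal(count_loglik(p0, 3, 3, 0, mode = "gaussian"), 700)
  expect_identical(count_loglik(p0, 2, 3, 0, mode = "gaussian"), -Inf)
})
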