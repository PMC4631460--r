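# Bootstrap particle filter with the exact likelihood, and its
# jump-Markov (branched) extension.

test_that("initialization produces uniform weights and honest spread", {
  ps <- pf_init(2e-5, 0, M = 50, seed = 1)
  expect_equal(ps$values, rep(2e-5, 50))
  expect_equal(ps$weights, rep(1 / 50, 50))

  means <- vapply(1:30, function(s)
    mean(pf_init(2e-5, 1e-10, M = 400, seed = s)$values), 0)
  # redrawing negatives samples the normal truncated at 0, whose mean is
  # mu + sigma * phi(-mu/sigma) / (1 - Phi(-mu/sigma))
  trunc_mean <- 2e-5 + 1e-5 * dnorm(-2) / (1 - pnorm(-2))
  expect_lt(abs(mean(means) - trunc_mean),
            4 * sd(means) / sqrt(length(means)))
  expect_true(all(pf_init(1e-6, 1e-10, M = 500, seed = 2)$values >= 0))
})

test_that("systematic resampling is unbiased and preserves the mean", {
  set.seed(4)
  x <- runif(50); w <- runif(50); w <- w / sum(w)
  target <- sum(w * x)
  reps <- vapply(1:1000, function(i)
    mean(resample_systematic(x, w)), 0)
  expect_lt(abs(mean(reps) - target), 4 * sd(reps) / sqrt(1000))
  # stratification: per-draw spread is below multinomial spread
  mult <- vapply(1:1000, function(i)
    mean(sample(x, 50, TRUE, prob = w)), 0)
  expect_lt(sd(reps), sd(mult))
})

test_that("degenerate steps behave as identities", {
  p <- test_params()
  ps <- pf_init(1e-5, 1e-12, M = 100, seed = 2)
  # no sensors: flat likelihood leaves weights untouched
  stp <- pf_step(ps, integer(), integer(), p, q = 0)
  expect_equal(stp$ps$weights, ps$weights)
  expect_equal(stp$ps$values, ps$values)
  # a single particle always carries weight one
  one <- pf_init(1e-5, 1e-12, M = 1, seed = 3)
  stp <- pf_step(one, 5L, 3L, p, q = 1e-16)
  expect_equal(stp$ps$weights, 1)
})

test_that("one-step posterior matches dense-grid Bayes quadrature", {
  p <- test_params()
  M <- 1e4
  y_prev <- 3L; y <- 5L
  oracle <- grid_one_step(p, 1.5e-5, 5e-6, 1e-12, y, y_prev)
  ests <- vapply(1:12, function(s) {
    set.seed(700 + s)
    ps <- pf_init(1.5e-5, 2.5e-11, M)
    pf_step(ps, y, y_prev, p, q = 1e-12)$est
  }, 0)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - oracle), 3 * se + 1e-9)
})

test_that("full PF tracks the grid-filter posterior and tightens with M", {
  d <- make_rw_dataset(n_steps = 50, Ns = 1, seed = 31, q = 1e-12)
  oracle <- grid_filter(d, q = 1e-12, init_mean = 2e-5, init_var = 1e-10)
  err_for <- function(M, seeds) {
    vapply(seeds, function(s)
      sqrt(mean((pf_run(d, M = M, q = 1e-12, seed = s)$est - oracle)^2)),
      0)
  }
  e_small <- err_for(150, 1:6)
  e_large <- err_for(4800, 1:6)
  expect_lt(mean(e_large), mean(e_small)) # ~1/sqrt(M) convergence
  expect_lt(mean(e_large) / mean(e_small), 0.6)
})

test_that("PF engines agree draw-for-draw and estimates stay physical", {
  d <- make_rw_dataset(n_steps = 300, Ns = 2, seed = 6)
  a <- pf_run(d, M = 120, seed = 9, engine = "cpp")
  b <- pf_run(d, M = 120, seed = 9, engine = "r")
  expect_equal(a$est, b$est, tolerance = 1e-12)
  expect_identical(as.logical(a$resampled), b$resampled)
  expect_true(all(a$est >= 0))
  # snapshots expose normalized particle sets
  snp <- pf_run(d, M = 60, seed = 9, snapshots = c(10, 200))$snapshots
  expect_length(snp, 2)
  expect_equal(sum(snp[[1]]$weights), 1, tolerance = 1e-10)
})

test_that("jump PF reduces to the bootstrap PF when regimes cannot mix", {
  d <- make_rw_dataset(n_steps = 400, Ns = 1, seed = 41)
  regI <- regime_model(Pi = diag(2), qs = c(1e-16, 5e-14))
  pf <- pf_run(d, M = 200, q = 1e-16, seed = 13)
  jm <- pfmcmc_run(d, M = 200, regime = regI, regime_init = c(1, 0),
                   seed = 13)
  expect_true(all(jm$regime_probs[, 1] == 1))
  # identical RNG stream: particle populations coincide, so estimates are
  # exactly equal except on resampling steps, where the plain PF reports
  # the post-resample unweighted mean while the jump filter reports the
  # pre-collapse branch-weighted mean
  same <- !pf$resampled
  expect_identical(as.logical(pf$resampled), as.logical(jm$resampled))
  expect_equal(jm$est[same], pf$est[same], tolerance = 1e-12)
  expect_lt(max(abs(jm$est - pf$est)), 5e-7) # O(sd/sqrt(M)) on the rest
})

test_that("jump PF with equal regime variances matches the bootstrap PF", {
  d <- make_rw_dataset(n_steps = 600, Ns = 1, seed = 55)
  regE <- regime_model(qs = c(1e-16, 1e-16))
  pf <- pf_run(d, M = 400, q = 1e-16, seed = 21)
  jm <- pfmcmc_run(d, M = 400, regime = regE, regime_init = c(1, 0),
                   seed = 22)
  gap <- sqrt(mean((jm$est - pf$est)^2)) / sqrt(mean((pf$est - d$C_true)^2))
  expect_lt(gap, 0.5) # indistinguishable regimes, Monte Carlo error apart
})

test_that("jump PF normalizes branch masses and detects a true switch", {
  d <- make_switch_dataset(n_steps = 1200, seed = 61, switch_time = 600)
  jm <- pfmcmc_run(d, M = 200, regime = regime_model(), seed = 62)
  expect_equal(rowSums(jm$regime_probs), rep(1, 1200), tolerance = 1e-10)
  p2 <- jm$regime_probs[, 2]
  expect_gt(mean(p2[601:1200]), mean(p2[1:600]))
  expect_true(all(jm$est >= 0))

  # per-step branch bookkeeping sums to one as well
  jps <- pfmcmc_init(2e-5, 1e-10, M = 100, regime_init = c(1, 0), seed = 3)
  stp <- pfmcmc_step(jps, 5L, 4L, test_params(), regime_model())
  expect_equal(sum(stp$branch_probs), 1, tolerance = 1e-12)
  expect_equal(sum(stp$regime_probs), 1, tolerance = 1e-12)

  # engines agree draw-for-draw on the jump filter too
  a <- pfmcmc_run(d, M = 80, regime = regime_model(), seed = 5,
                  engine = "cpp")
  b <- pfmcmc_run(d, M = 80, regime = regime_model(), seed = 5,
                  engine = "r")
  expect_equal(a$est, b$est, tolerance = 1e-12)
  expect_equal(a$regime_probs, b$regime_probs, tolerance = 1e-12)
})

test_that("with the truth pinned to regime 1 the jump PF matches plain PF", {
  # single-seed gaps are dominated by independent resampling noise, so
  # the comparison aggregates squared errors over paired seeds
  reg <- regime_model()
  sq <- vapply(1:8, function(s) {
    d <- make_rw_dataset(n_steps = 1000, Ns = 1, seed = 800 + s)
    pf <- pf_run(d, M = 200, q = 1e-16, seed = 900 + s)
    jm <- pfmcmc_run(d, M = 200, regime = reg, seed = 900 + s)
    c(scaled_rmse(d$C_true, pf$est, root = FALSE),
      scaled_rmse(d$C_true, jm$est, root = FALSE))
  }, c(pf = 0, jm = 0))
  gap <- (sqrt(mean(sq["jm", ])) - sqrt(mean(sq["pf", ]))) /
    sqrt(mean(sq["pf", ]))
  expect_lt(abs(gap), 0.10)
})
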