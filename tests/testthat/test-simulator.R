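# Synthetic-data generator: truth trajectories, kinetic Monte Carlo counts,
# dataset assembly and serialization.

test_that("concentration trajectories follow the process model", {
  m0 <- process_model("random_walk", q = 0, x0 = 1e-5)
  sim <- simulate_concentration(m0, 100, seed = 1)
  expect_equal(sim$C, rep(1e-5, 100))
  expect_null(sim$regimes)

  # increment SD matches the nominal process noise (pooled over 100 runs)
  m <- process_model("random_walk", q = 1e-16, x0 = 1e-5)
  incs <- unlist(lapply(1:100, function(s) {
    diff(c(1e-5, simulate_concentration(m, 2000, seed = s)$C))
  }))
  expect_equal(sd(incs), 1e-8, tolerance = 0.05)

  # frozen regime chain: identity transition matrix never leaves state 1
  regI <- regime_model(Pi = diag(2), qs = c(0, 5e-14))
  mi <- process_model("regime_switching", regime = regI, x0 = 1e-5)
  sim <- simulate_concentration(mi, 500, seed = 3)
  expect_true(all(sim$regimes == 1L))
  expect_equal(sim$C, rep(1e-5, 500))

  # forced switch places regime 2 from t >= switch_time onwards
  regF <- regime_model(switch_time = 200)
  mf <- process_model("regime_switching", regime = regF, x0 = 1e-5)
  sim <- simulate_concentration(mf, 400, dt = 1, seed = 4)
  expect_equal(sim$regimes, c(rep(1L, 199), rep(2L, 201)))

  expect_error(process_model("regime_switching", regime = NULL),
               "regime_model")
  expect_error(regime_model(Pi = matrix(c(.5, .2, .5, .9), 2), qs = c(0, 0)),
               "sum to 1")
})

test_that("SSA counts: degenerate input, reproducibility", {
  p <- test_params()
  expect_equal(simulate_counts_ssa(p, rep(0, 50), y0 = 0, seed = 1),
               rep(0L, 50))
  y1 <- simulate_counts_ssa(p, rep(1e-5, 200), y0 = 0, seed = 7)
  y2 <- simulate_counts_ssa(p, rep(1e-5, 200), y0 = 0, seed = 7)
  expect_identical(y1, y2)
  expect_true(all(y1 >= 0 & y1 <= 10))
})

test_that("SSA one-step transition frequencies match the exact kernel", {
  p <- test_params()
  n <- 1e5
  for (yp in c(0, 5)) {
    set.seed(42 + yp)
    draws <- vapply(seq_len(n), function(i)
      cntrack:::cpp_ssa_counts(1e-5, yp, p$kA, p$kD, p$NT, p$dt)[1], 0L)
    pmf <- transition_pmf(p, yp, 1e-5)
    obs <- tabulate(draws + 1L, nbins = 11)
    keep <- pmf * n >= 5 # pool sparse tail cells
    chi <- sum((obs[keep] - n * pmf[keep])^2 / (n * pmf[keep])) +
      (sum(obs[!keep]) - n * sum(pmf[!keep]))^2 /
        max(n * sum(pmf[!keep]), 1e-12)
    df <- sum(keep) # pooled cell adds one, minus one for the total
    expect_lt(chi, qchisq(0.99, df))
  }
})

test_that("SSA and analytic one-step samplers are distributionally equal", {
  p <- test_params()
  n <- 1e4
  set.seed(11)
  a <- vapply(seq_len(n), function(i)
    cntrack:::cpp_ssa_counts(1e-5, 3, p$kA, p$kD, p$NT, p$dt)[1], 0L)
  b <- vapply(seq_len(n), function(i)
    simulate_counts_exact(p, 1e-5, y0 = 3)[1], 0L)
  tab <- rbind(tabulate(a + 1L, 11), tabulate(b + 1L, 11))
  keep <- colSums(tab) >= 10
  suppressWarnings(ct <- chisq.test(tab[, keep]))
  expect_gt(ct$p.value, 0.01)
})

test_that("analytic sampler mean from empty start matches the continuum", {
  p <- test_params()
  set.seed(3)
  lam <- occupancy_fractions(p, 1e-5)
  draws <- rbinom(1e5, 10, lam$lamE) # y0 = 0: pure empty-subset binomial
  expect_equal(mean(draws), continuum_update(p, 0, 1e-5),
               tolerance = 0.05)
  # frozen trajectory under a vanishing interval
  pdt <- test_params(dt = 1e-9)
  expect_equal(simulate_counts_exact(pdt, rep(1e-5, 100), y0 = 4, seed = 1),
               rep(4L, 100))
})

test_that("long SSA runs reach the binomial stationary law", {
  p <- test_params()
  y <- simulate_counts_ssa(p, rep(1e-5, 2e5), y0 = 0, seed = 9)
  # relaxation time is 1/(kA C + kD) = 500 s; thin to near-independence
  thin <- y[seq(5000, 2e5, by = 2500)]
  expect_equal(mean(thin), 5, tolerance = 0.15) # 4 sd of the thinned mean
  expect_equal(mean(y), 5, tolerance = 0.1)
  expect_equal(var(y), 2.5, tolerance = 0.25)
})

test_that("datasets share one truth, have independent sensors, and
           serialize deterministically", {
  m <- process_model("random_walk", q = 1e-16, x0 = 1e-5)
  d <- generate_dataset(m, test_params(), Ns = 5, n_steps = 2000, seed = 12)
  expect_s3_class(d, "cnt_dataset")
  expect_equal(dim(d$counts), c(2000L, 5L))
  expect_equal(length(unique(apply(d$counts, 2, paste, collapse = ""))), 5L)
  expect_equal(d$y0, rep(0L, 5))

  # conditional on the shared truth, count increments are uncorrelated
  inc <- apply(rbind(d$y0, d$counts), 2, diff)
  cors <- cor(inc)[upper.tri(diag(5))]
  expect_lt(max(abs(cors)), 3 / sqrt(2000))

  # random initial-count policy draws integers below NT, reproducibly
  d2 <- generate_dataset(m, test_params(), Ns = 20, n_steps = 5,
                         y0_policy = "random", seed = 5)
  d3 <- generate_dataset(m, test_params(), Ns = 20, n_steps = 5,
                         y0_policy = "random", seed = 5)
  expect_identical(d2$y0, d3$y0)
  expect_true(all(d2$y0 >= 0 & d2$y0 <= 9))

  # identical seed => identical CSV bytes; round trip is lossless
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset_csv(d, f1)
  write_dataset_csv(generate_dataset(m, test_params(), Ns = 5,
                                     n_steps = 2000, seed = 12), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  rt <- read_dataset_csv(f1, test_params())
  expect_equal(rt$C_true, d$C_true)
  expect_identical(unname(rt$counts), unname(d$counts))
  expect_identical(rt$y0, d$y0)
  unlink(c(f1, f2))
})
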