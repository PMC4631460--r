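#' Weighted particle representation of the concentration posterior
#'
#' @param values Nonnegative concentration samples in M.
#' @param weights Nonnegative weights summing to 1 (default uniform).
#' @return An object of class `"particle_set"`.
#' @export
particle_set <- function(values, weights = NULL) {
  stopifnot(is.numeric(values), length(values) >= 1L, all(values >= 0))
  M <- length(values)
  if (is.null(weights)) weights <- rep(1 / M, M)
  stopifnot(length(weights) == M, all(weights >= 0),
            abs(sum(weights) - 1) < 1e-10)
  structure(list(values = as.numeric(values),
                 weights = as.numeric(weights), M = M),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("Particle set: M = %d, weighted mean %.4g M, ESS %.1f\n",
              x$M, sum(x$weights * x$values), 1 / sum(x$weights^2)))
  invisible(x)
}

#' Initialize a particle set from the initial Gaussian guess
#'
#' Draws `M` samples from `N(mean, var)`; negative draws are replaced by
#' fresh draws until all particles are nonnegative (truncation at 0 by
#' resampling).  Weights start uniform at `1/M`.
#'
#' @param mean Initial guess mean in M.
#' @param var Initial guess variance in M^2.
#' @param M Number of particles.
#' @param seed Optional integer seed.
#' @return A [particle_set()].
#' @export
pf_init <- function(mean = 2e-5, var = 1e-10, M = 200, seed = NULL) {
  stopifnot(M >= 1, var >= 0)
  with_seed(seed, {
    x <- stats::rnorm(M, mean, sqrt(var))
    while (any(neg <- x < 0))
      x[neg] <- stats::rnorm(sum(neg), mean, sqrt(var))
    particle_set(x)
  })
}

#' Systematic resampling of a weighted sample
#'
#' Draws `M` values using a single uniform offset and a stratified
#' comb over the cumulative weights; unbiased (the expected number of
#' copies of particle `i` is `M * w_i`) and lower-variance than
#' multinomial resampling.  Consumes exactly one uniform RNG draw.
#'
#' @param values Sample values.
#' @param weights Normalized weights (same length).
#' @param M Number of values to draw (default `length(values)`).
#' @return Numeric vector of `M` resampled values.
#' @export
resample_systematic <- function(values, weights, M = length(values)) {
  stopifnot(length(values) == length(weights), M >= 1)
  u <- stats::runif(1) / M
  pos <- u + (seq_len(M) - 1) / M
  idx <- findInterval(pos, cumsum(weights), left.open = TRUE) + 1L
  values[pmin(idx, length(values))]
}

#' One bootstrap particle-filter step with the exact count likelihood
#'
#' Propagates every particle through the state-transition prior
#' `x + N(0, q)` (reflected at 0), multiplies its weight by the product
#' over sensors of the exact convolved-binomial likelihood
#' `p(y_j | x, y_prev_j)` (computed in log space), renormalizes, and
#' resamples systematically when the effective sample size drops below
#' `ess_frac * M` (default `M/2`).  If all weights underflow to zero the
#' weights are reset to uniform with a warning.
#'
#' The reported point estimate is the weighted particle mean; on steps
#' where resampling occurred it is the unweighted mean of the resampled
#' particles (identical in expectation).
#'
#' @param ps A [particle_set()].
#' @param y_vec,y_prev_vec Current and previous counts per sensor (may be
#'   empty, in which case the likelihood is flat and weights are
#'   unchanged).
#' @param params A [sensor_params()].
#' @param q Process-noise variance in M^2.
#' @param ess_frac Resampling threshold as a fraction of `M`.
#' @return A list with `ps` (updated [particle_set()]), `est` (point
#'   estimate), and `resampled` (logical).
#' @export
pf_step <- function(ps, y_vec, y_prev_vec, params, q, ess_frac = 0.5) {
  stopifnot(inherits(ps, "particle_set"))
  assert_params(params)
  stopifnot(length(y_vec) == length(y_prev_vec))
  M <- ps$M
  x <- abs(ps$values + stats::rnorm(M, 0, sqrt(q)))
  y_vec <- assert_count(y_vec, params$NT, "y_vec")
  y_prev_vec <- assert_count(y_prev_vec, params$NT, "y_prev_vec")
  ll <- cpp_loglik_exact(x, y_vec, y_prev_vec,
                         params$kA, params$kD, params$NT, params$dt)
  lw <- log(ps$weights) + ll
  mx <- max(lw)
  if (!is.finite(mx)) {
    warning("all particle weights underflowed; resetting to uniform")
    w <- rep(1 / M, M)
  } else {
    w <- exp(lw - mx)
    w <- w / sum(w)
  }
  if (1 / sum(w^2) < ess_frac * M) {
    x <- resample_systematic(x, w)
    w <- rep(1 / M, M)
    list(ps = particle_set(x, w), est = sum(x) / M, resampled = TRUE)
  } else {
    list(ps = particle_set(x, w), est = sum(w * x), resampled = FALSE)
  }
}

#' Run the bootstrap particle filter over a dataset
#'
#' Sequential importance sampling with the state-transition prior as
#' proposal, the exact convolved-binomial observation likelihood, and
#' systematic resampling when the effective sample size falls below
#' `M/2`.  Point estimates are weighted particle means and are therefore
#' always nonnegative.
#'
#' @inheritParams kf_run
#' @param init Initial guess as `c(mean, var)` (M, M^2); particles are
#'   drawn from this Gaussian truncated at 0.
#' @param M Number of particles (200 by default).
#' @param seed Optional integer seed.
#' @param snapshots Optional integer vector of sampling instants (step
#'   indices) at which the full particle set is recorded, for posterior
#'   density reconstruction.
#' @param engine `"cpp"` (compiled loop) or `"r"` (loops [pf_step()]);
#'   both consume the RNG stream identically, so matched seeds give
#'   matched trajectories.
#' @return A list with `est` (point estimates), `resampled` (logical per
#'   step), and `snapshots` (list of `step`/`values`/`weights` records).
#' @export
pf_run <- function(dataset, init = c(mean = 2e-5, var = 1e-10), M = 200,
                   q = 1e-16, seed = NULL, snapshots = integer(),
                   engine = c("cpp", "r"), ess_frac = 0.5) {
  engine <- match.arg(engine)
  dataset <- as_dataset(dataset)
  p <- dataset$params
  with_seed(seed, {
    if (engine == "cpp")
      return(cpp_pf_run(dataset$counts, dataset$y0, p$kA, p$kD, p$NT, p$dt,
                        q, as.integer(M), init[[1]], init[[2]], ess_frac,
                        as.integer(snapshots)))
    ps <- pf_init(init[[1]], init[[2]], M)
    K <- nrow(dataset$counts)
    est <- numeric(K)
    resampled <- logical(K)
    snaps <- list()
    y_prev <- dataset$y0
    for (k in seq_len(K)) {
      y <- dataset$counts[k, ]
      stp <- pf_step(ps, y, y_prev, p, q, ess_frac)
      ps <- stp$ps
      est[k] <- stp$est
      resampled[k] <- stp$resampled
      if (k %in% snapshots)
        snaps[[length(snaps) + 1L]] <-
          list(step = k, values = ps$values, weights = ps$weights)
      y_prev <- y
    }
    list(est = est, resampled = resampled, n_flat = NA_integer_,
         snapshots = snaps)
  })
}

#' Jump-Markov particle populations
#'
#' Carries one collapsed particle population per current hidden regime
#' together with the posterior regime probabilities; the branched
#' `(previous regime, current regime)` particle sets and their joint
#' probabilities appear in the return value of [pfmcmc_step()].
#'
#' @param populations List of [particle_set()] objects, one per regime.
#' @param regime_probs Posterior regime probabilities (sum to 1).
#' @return An object of class `"jump_particle_set"`.
#' @export
jump_particle_set <- function(populations, regime_probs) {
  stopifnot(is.list(populations),
            all(vapply(populations, inherits, TRUE, "particle_set")),
            length(regime_probs) == length(populations),
            all(regime_probs >= 0),
            abs(sum(regime_probs) - 1) < 1e-10)
  structure(list(populations = populations,
                 regime_probs = as.numeric(regime_probs)),
            class = "jump_particle_set")
}

#' Initialize the jump-Markov particle filter
#'
#' @inheritParams pf_init
#' @param regime_init Initial regime probabilities.
#' @return A [jump_particle_set()].  Only regimes with positive initial
#'   probability consume RNG draws.
#' @export
pfmcmc_init <- function(mean = 2e-5, var = 1e-10, M = 200,
                        regime_init = c(1, 0), seed = NULL) {
  with_seed(seed, {
    pops <- lapply(seq_along(regime_init), function(h) {
      if (regime_init[h] > 0) pf_init(mean, var, M)
      else particle_set(rep(mean, M))
    })
    jump_particle_set(pops, regime_init)
  })
}

#' One step of the branched (jump-Markov) particle filter
#'
#' For every pair `(g, h)` of previous and current regimes with positive
#' probability mass, propagates the collapsed population of regime `g`
#' with the process-noise variance of regime `h`, computes per-particle
#' exact likelihoods, and weighs the branch by
#' `p(g | past) * Pi[g, h] * (marginal branch likelihood)`.  The point
#' estimate is the branch-probability-weighted mean over all branches'
#' weighted particle means.  Branches are then collapsed to one
#' population per current regime: a regime fed by a single branch keeps
#' its weighted particles (resampling only when the effective sample size
#' drops below `ess_frac * M`, so the no-switching limit reduces exactly
#' to the bootstrap filter), while a regime fed by several branches is
#' rebuilt by systematic resampling from their mixture.
#'
#' @param jps A [jump_particle_set()].
#' @inheritParams pf_step
#' @param regime A [regime_model()].
#' @return A list with `jps` (collapsed [jump_particle_set()]), `est`
#'   (point estimate), `regime_probs` (posterior `p(r_k | data)`),
#'   `branch_probs` (H x H joint `p(r_{k-1}, r_k | data)`), `branches`
#'   (H x H list of branch [particle_set()]s, `NULL` where inactive) and
#'   `resampled` (logical).
#' @export
pfmcmc_step <- function(jps, y_vec, y_prev_vec, params, regime,
                        ess_frac = 0.5) {
  stopifnot(inherits(jps, "jump_particle_set"),
            inherits(regime, "regime_model"))
  assert_params(params)
  H <- regime$H
  Pi <- regime$Pi; qs <- regime$qs; p <- jps$regime_probs
  M <- jps$populations[[1L]]$M
  y_vec <- assert_count(y_vec, params$NT, "y_vec")
  y_prev_vec <- assert_count(y_prev_vec, params$NT, "y_prev_vec")
  bx <- bv <- vector("list", H * H)
  logm <- matrix(-Inf, H, H)
  active <- matrix(FALSE, H, H)
  for (g in seq_len(H)) {
    for (h in seq_len(H)) {
      if (p[g] <= 0 || Pi[g, h] <= 0) next
      active[g, h] <- TRUE
      b <- (g - 1L) * H + h
      x <- abs(jps$populations[[g]]$values + stats::rnorm(M, 0, sqrt(qs[h])))
      lw <- log(jps$populations[[g]]$weights) +
        cpp_loglik_exact(x, y_vec, y_prev_vec, params$kA, params$kD,
                         params$NT, params$dt)
      mx <- max(lw)
      bx[[b]] <- x
      if (is.finite(mx)) {
        w <- exp(lw - mx)
        mass <- sum(w)
        bv[[b]] <- w / mass
        logm[g, h] <- log(p[g]) + log(Pi[g, h]) + mx + log(mass)
      } else {
        bv[[b]] <- jps$populations[[g]]$weights
      }
    }
  }
  L <- max(logm)
  if (is.finite(L)) {
    A <- ifelse(is.finite(logm), exp(logm - L), 0)
  } else {
    warning("all jump-PF branch masses vanished; using transition prior")
    A <- ifelse(active, p * Pi, 0)
  }
  A <- A / sum(A)
  est <- 0
  for (g in seq_len(H)) for (h in seq_len(H)) {
    b <- (g - 1L) * H + h
    if (active[g, h] && A[g, h] > 0)
      est <- est + A[g, h] * sum(bv[[b]] * bx[[b]])
  }
  pn <- colSums(A)
  pops <- jps$populations
  resampled <- FALSE
  for (h in seq_len(H)) {
    if (pn[h] <= 0) next
    f <- A[, h] / pn[h]
    ncontrib <- sum(f > 0)
    gdom <- which.max(f)
    if (ncontrib == 1L || f[gdom] > 1 - 1e-12) {
      b <- (gdom - 1L) * H + h
      nx <- bx[[b]]; nv <- bv[[b]]
      if (1 / sum(nv^2) < ess_frac * M) {
        nx <- resample_systematic(nx, nv)
        nv <- rep(1 / M, M)
        resampled <- TRUE
      }
      pops[[h]] <- particle_set(nx, nv)
    } else {
      cx <- cw <- numeric(0)
      for (g in seq_len(H)) {
        b <- (g - 1L) * H + h
        if (f[g] <= 0) next
        cx <- c(cx, bx[[b]])
        cw <- c(cw, f[g] * bv[[b]])
      }
      pops[[h]] <- particle_set(resample_systematic(cx, cw, M))
      resampled <- TRUE
    }
  }
  branches <- lapply(seq_len(H * H), function(b)
    if (is.null(bx[[b]])) NULL else particle_set(bx[[b]], bv[[b]]))
  dim(branches) <- c(H, H)
  list(jps = jump_particle_set(pops, pn), est = est, regime_probs = pn,
       branch_probs = A, branches = branches, resampled = resampled)
}

#' Run the branched jump-Markov particle filter over a dataset
#'
#' Full recursion of [pfmcmc_step()], returning per-step point estimates
#' and posterior regime probabilities.
#'
#' @inheritParams pf_run
#' @param regime A [regime_model()].
#' @param regime_init Initial regime probabilities (default: surely in
#'   regime 1).
#' @return A list with `est`, `regime_probs` (`n_steps x H` matrix) and
#'   `resampled`.
#' @export
pfmcmc_run <- function(dataset, init = c(mean = 2e-5, var = 1e-10), M = 200,
                       regime = regime_model(), regime_init = NULL,
                       seed = NULL, engine = c("cpp", "r"),
                       ess_frac = 0.5) {
  engine <- match.arg(engine)
  dataset <- as_dataset(dataset)
  stopifnot(inherits(regime, "regime_model"))
  H <- regime$H
  if (is.null(regime_init)) regime_init <- c(1, rep(0, H - 1L))
  p <- dataset$params
  with_seed(seed, {
    if (engine == "cpp")
      return(cpp_pfmcmc_run(dataset$counts, dataset$y0, p$kA, p$kD, p$NT,
                            p$dt, regime$Pi, regime$qs, as.integer(M),
                            init[[1]], init[[2]], as.numeric(regime_init),
                            ess_frac))
    jps <- pfmcmc_init(init[[1]], init[[2]], M, regime_init)
    K <- nrow(dataset$counts)
    est <- numeric(K)
    resampled <- logical(K)
    rp <- matrix(0, K, H)
    y_prev <- dataset$y0
    for (k in seq_len(K)) {
      y <- dataset$counts[k, ]
      stp <- pfmcmc_step(jps, y, y_prev, p, regime, ess_frac)
      jps <- stp$jps
      est[k] <- stp$est
      rp[k, ] <- stp$regime_probs
      resampled[k] <- stp$resampled
      y_prev <- y
    }
    list(est = est, regime_probs = rp, resampled = resampled,
         n_fallback = NA_integer_)
  })
}
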