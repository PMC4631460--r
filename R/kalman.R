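#' Gaussian belief over the concentration state
#'
#' Mean and variance of a (scalar) Gaussian estimate of the local
#' concentration, the quantity the Kalman-type filters propagate.
#'
#' @param mean Concentration estimate in M.
#' @param cov Estimate variance in M^2 (nonnegative).
#' @return An object of class `"gaussian_belief"`.
#' @export
gaussian_belief <- function(mean = 2e-5, cov = 1e-10) {
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean))
  stopifnot(is.numeric(cov), length(cov) == 1L, is.finite(cov), cov >= 0)
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat(sprintf("Gaussian belief: mean %.4g M, sd %.4g M\n",
              x$mean, sqrt(x$cov)))
  invisible(x)
}

#' Kalman prediction step for the random-walk state
#'
#' The state transition is the identity (`f(x) = x`, so its linearization
#' is exactly 1): the mean is unchanged and the process-noise variance `q`
#' is added to the covariance.
#'
#' @param belief A [gaussian_belief()].
#' @param q Process-noise variance in M^2.
#' @return The predicted [gaussian_belief()].
#' @export
kf_predict <- function(belief, q) {
  stopifnot(inherits(belief, "gaussian_belief"), is.numeric(q), q >= 0)
  gaussian_belief(belief$mean, belief$cov + q)
}

# Floor for modeled per-sensor measurement variances, in squared molecule
# counts (see kf_gain_update); mirrors the compiled kernel.
OBS_VAR_FLOOR <- 1e-3

# d lamE / dC, analytic (mirrors the compiled kernel; see linearize_obs).
dlamE_dC_r <- function(params, C) {
  kA <- params$kA; kD <- params$kD; dt <- params$dt
  out <- numeric(length(C))
  pos <- C > 0
  a <- kA * C[pos] + kD
  g <- -expm1(-a * dt)
  out[pos] <- kA * (g * kD / a^2 + kA * C[pos] * dt * exp(-a * dt) / a)
  out[!pos] <- if (kD <= 0) kA * dt else kA * (-expm1(-kD * dt)) / kD
  out
}

#' Linearized Gaussian observation model at a working concentration
#'
#' For each sensor `j` with previous count `y_prev_vec[j]`, returns the
#' moment-matched observation mean
#' `h_j = NT * lamE + y_prev_j * exp(-a*dt)`, its analytic derivative with
#' respect to the concentration (`Cbar_j`, the observation Jacobian used
#' in the Kalman gain), and the measurement-noise variance
#' `r_j = y_prev_j * lamF * (1 - lamF) + (NT - y_prev_j) * lamE * (1 - lamE)`
#' forming the diagonal measurement-noise matrix.
#'
#' A negative working concentration (possible transiently, since the
#' internal Kalman recursion is not clipped) is evaluated at 0 with a
#' warning.
#'
#' @inheritParams occupancy_fractions
#' @param y_prev_vec Integer vector of previous counts, one per sensor.
#' @return A list with numeric vectors `h`, `Cbar`, `R` (one entry per
#'   sensor).
#' @export
linearize_obs <- function(params, C, y_prev_vec) {
  assert_params(params)
  stopifnot(is.numeric(C), length(C) == 1L, is.finite(C))
  if (C < 0) {
    warning("negative working concentration clipped to 0 for linearization")
    C <- 0
  }
  y_prev_vec <- assert_count(y_prev_vec, params$NT, "y_prev_vec")
  lam <- occupancy_fractions(params, C)
  decay <- lam$lamF - lam$lamE # exp(-a dt)
  dE <- dlamE_dC_r(params, C)
  list(h = params$NT * lam$lamE + y_prev_vec * decay,
       Cbar = params$NT * dE - y_prev_vec * params$kA * params$dt * decay,
       R = y_prev_vec * lam$lamF * (1 - lam$lamF) +
         (params$NT - y_prev_vec) * lam$lamE * (1 - lam$lamE))
}

#' Low-level Kalman measurement update with explicit observation terms
#'
#' Applies the innovation update `x + L (y - h)`,
#' `L = P Cbar' (R + Cbar P Cbar')^{-1}`, `P - L Cbar P`, for a scalar
#' state observed through `Ns` sensors with diagonal noise `R_diag`,
#' evaluated in the algebraically equivalent information form.
#'
#' Modeled measurement variances are floored at `1e-3` squared molecule
#' counts: the moment-matched Gaussian observation variance vanishes at
#' the `C = 0` boundary while the observation Jacobian does not, which
#' would otherwise make the gain unbounded there.  The floor equals the
#' exact-model variance of an empty sensor about 1 uM from the boundary
#' and sits an order of magnitude below the variance at typical operating
#' occupancies, so it only binds very close to the boundary.
#'
#' @param prior A [gaussian_belief()].
#' @param y_vec Observed counts.
#' @param h_vec Predicted observation means.
#' @param Cbar_vec Observation Jacobian entries.
#' @param R_diag Measurement-noise variances.
#' @return The posterior [gaussian_belief()], with attributes `"loglik"`
#'   (Gaussian innovation log-likelihood `log N(y - h; 0, Cbar P Cbar' + R)`)
#'   and `"updated"`.
#' @export
kf_gain_update <- function(prior, y_vec, h_vec, Cbar_vec, R_diag) {
  stopifnot(inherits(prior, "gaussian_belief"))
  Ns <- length(y_vec)
  stopifnot(length(h_vec) == Ns, length(Cbar_vec) == Ns,
            length(R_diag) == Ns, all(R_diag >= 0))
  if (Ns == 0L) {
    out <- prior
    attr(out, "loglik") <- 0
    attr(out, "updated") <- FALSE
    return(out)
  }
  r <- pmax(R_diag, OBS_VAR_FLOOR)
  nu <- y_vec - h_vec
  Ic <- sum(Cbar_vec^2 / r)
  Iy <- sum(Cbar_vec * nu / r)
  d <- 1 + prior$cov * Ic
  Pk <- prior$cov / d
  out <- gaussian_belief(prior$mean + Pk * Iy, Pk)
  attr(out, "loglik") <-
    -0.5 * (Ns * log(2 * pi) + sum(log(r)) + log(d) +
              (sum(nu^2 / r) - prior$cov * Iy^2 / d))
  attr(out, "updated") <- TRUE
  out
}

#' Kalman measurement update against the sensor observation model
#'
#' Linearizes the Gaussian-approximated observation model at the prior
#' mean ([linearize_obs()]) and applies [kf_gain_update()].
#'
#' @inheritParams kf_gain_update
#' @param y_vec Observed counts (one per sensor).
#' @param y_prev_vec Previous counts (one per sensor).
#' @param params A [sensor_params()].
#' @return The posterior [gaussian_belief()] (attributes as in
#'   [kf_gain_update()]).
#' @export
kf_update <- function(prior, y_vec, y_prev_vec, params) {
  assert_params(params)
  y_vec <- assert_count(y_vec, params$NT, "y_vec")
  lin <- linearize_obs(params, max(prior$mean, 0), y_prev_vec)
  kf_gain_update(prior, y_vec, lin$h, lin$Cbar, lin$R)
}

as_dataset <- function(dataset) {
  if (!inherits(dataset, "cnt_dataset"))
    stop("`dataset` must be a cnt_dataset (see generate_dataset())",
         call. = FALSE)
  dataset
}

#' Run the linearized Kalman filter over a dataset
#'
#' Full predict/update recursion over all sampling instants.  The
#' observation model conditions on each sensor's previous count; for the
#' first instant this is the dataset's recorded initial count `y0`.
#' Reported point estimates are floored at 0 (a concentration is
#' physical); the internal recursion is left unclipped.
#'
#' @param dataset A `"cnt_dataset"` (see [generate_dataset()]).
#' @param init Initial [gaussian_belief()] (the deliberately wrong default
#'   guess is mean `2e-5` M with variance `1e-10` M^2, i.e. a standard
#'   deviation of the state scale).
#' @param q Filter process-noise variance in M^2.
#' @param engine `"cpp"` (compiled recursion, default) or `"r"` (reference
#'   implementation looping [kf_predict()] / [kf_update()]); both produce
#'   the same trajectories to floating-point accuracy.
#' @return A list with per-instant numeric vectors `mean` (raw posterior
#'   mean), `var` (posterior variance) and `est` (`pmax(mean, 0)`).
#' @export
kf_run <- function(dataset, init = gaussian_belief(), q = 1e-16,
                   engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  dataset <- as_dataset(dataset)
  p <- dataset$params
  if (engine == "cpp")
    return(cpp_kf_run(dataset$counts, dataset$y0, p$kA, p$kD, p$NT, p$dt,
                      q, init$mean, init$cov))
  K <- nrow(dataset$counts)
  mean <- var <- numeric(K)
  bel <- init
  y_prev <- dataset$y0
  for (k in seq_len(K)) {
    bel <- kf_predict(bel, q)
    y <- dataset$counts[k, ]
    bel <- kf_update(bel, y, y_prev, p)
    mean[k] <- bel$mean
    var[k] <- bel$cov
    y_prev <- y
  }
  list(mean = mean, var = var, est = pmax(mean, 0))
}

#' Per-regime Gaussian belief for the jump-Markov filter
#'
#' One [gaussian_belief()] per hidden regime together with the posterior
#' regime probabilities.
#'
#' @param beliefs List of [gaussian_belief()] objects, one per regime.
#' @param regime_probs Nonnegative weights summing to 1.
#' @return An object of class `"jump_belief"`.
#' @export
jump_belief <- function(beliefs, regime_probs) {
  stopifnot(is.list(beliefs),
            all(vapply(beliefs, inherits, TRUE, "gaussian_belief")),
            length(regime_probs) == length(beliefs),
            all(regime_probs >= 0),
            abs(sum(regime_probs) - 1) < 1e-12)
  structure(list(beliefs = beliefs, regime_probs = as.numeric(regime_probs)),
            class = "jump_belief")
}

#' @export
print.jump_belief <- function(x, ...) {
  cat("Jump-Markov Gaussian belief\n")
  for (h in seq_along(x$beliefs))
    cat(sprintf("  regime %d (p = %.3f): mean %.4g M, sd %.4g M\n",
                h, x$regime_probs[h], x$beliefs[[h]]$mean,
                sqrt(x$beliefs[[h]]$cov)))
  invisible(x)
}

#' One step of the second-order generalized pseudo-Bayesian (GPB2) filter
#'
#' Branches over every pair of previous and current regimes: each branch
#' runs a Kalman predict (with the current regime's process-noise
#' variance) and update, and is weighted by the prior regime probability,
#' the Markov transition probability and the Gaussian innovation
#' likelihood of the branch.  The branches are then merged by moment
#' matching to one Gaussian per current regime, with the spread of the
#' branch means inflating the merged covariance; the overall point
#' estimate mixes the merged regimes by their posterior probabilities.
#' If every branch likelihood underflows, the transition prior is used as
#' the branch weight (with a warning).
#'
#' @param belief A [jump_belief()].
#' @param y_vec,y_prev_vec Current and previous counts per sensor.
#' @param params A [sensor_params()].
#' @param regime A [regime_model()].
#' @return A list with `belief` (the merged [jump_belief()]), `est`
#'   (point estimate, floored at 0), `mean` (raw mixture mean) and `var`
#'   (mixture variance).
#' @export
gpb2_step <- function(belief, y_vec, y_prev_vec, params, regime) {
  stopifnot(inherits(belief, "jump_belief"), inherits(regime, "regime_model"))
  assert_params(params)
  H <- regime$H
  stopifnot(length(belief$beliefs) == H)
  Pi <- regime$Pi; qs <- regime$qs; p <- belief$regime_probs
  bm <- bP <- lw <- matrix(-Inf, H, H)
  for (g in seq_len(H)) {
    for (h in seq_len(H)) {
      pred <- kf_predict(belief$beliefs[[g]], qs[h])
      if (p[g] <= 0 || Pi[g, h] <= 0) {
        bm[g, h] <- pred$mean; bP[g, h] <- pred$cov
        next
      }
      post <- kf_update(pred, y_vec, y_prev_vec, params)
      bm[g, h] <- post$mean; bP[g, h] <- post$cov
      lw[g, h] <- log(p[g]) + log(Pi[g, h]) + attr(post, "loglik")
    }
  }
  L <- max(lw)
  if (is.finite(L)) {
    a <- ifelse(is.finite(lw), exp(lw - L), 0)
  } else {
    warning("all GPB2 branch likelihoods vanished; using transition prior")
    a <- p * Pi # recycles p down columns = p[g] * Pi[g, h]
  }
  a <- a / sum(a)
  pn <- colSums(a)
  mh <- Ph <- numeric(H)
  for (h in seq_len(H)) {
    if (pn[h] > 0) {
      wgt <- a[, h] / pn[h]
      mh[h] <- sum(wgt * bm[, h])
      Ph[h] <- sum(wgt * (bP[, h] + (bm[, h] - mh[h])^2))
    } else { # unreachable regime: carry the predicted prior mixture
      mh[h] <- sum(p * vapply(belief$beliefs, `[[`, 0, "mean"))
      pv <- vapply(belief$beliefs, `[[`, 0, "cov") + qs[h]
      Ph[h] <- sum(p * (pv + (vapply(belief$beliefs, `[[`, 0, "mean") - mh[h])^2))
    }
  }
  xk <- sum(pn * mh)
  Pk <- sum(pn * (Ph + (mh - xk)^2))
  list(belief = jump_belief(lapply(seq_len(H),
                                   function(h) gaussian_belief(mh[h], Ph[h])),
                            pn),
       est = max(xk, 0), mean = xk, var = Pk)
}

#' Run the GPB2 jump-Markov Kalman filter over a dataset
#'
#' Full recursion of [gpb2_step()], tracking both the concentration and
#' the posterior probability of each hidden regime.
#'
#' @inheritParams kf_run
#' @param regime A [regime_model()] (the filter's model of the hidden
#'   switch; defaults to the benchmark two-regime model).
#' @param regime_init Initial regime probabilities (default `c(1, 0, ...)`:
#'   the cell is known to start in the quiescent regime).
#' @return A list with `mean`, `var`, `est` as in [kf_run()] plus
#'   `regime_probs`, a `n_steps x H` matrix of posterior regime
#'   probabilities.
#' @export
gpb2_run <- function(dataset, init = gaussian_belief(),
                     regime = regime_model(), regime_init = NULL,
                     engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  dataset <- as_dataset(dataset)
  stopifnot(inherits(regime, "regime_model"))
  H <- regime$H
  if (is.null(regime_init)) regime_init <- c(1, rep(0, H - 1L))
  stopifnot(length(regime_init) == H, all(regime_init >= 0),
            abs(sum(regime_init) - 1) < 1e-10)
  p <- dataset$params
  if (engine == "cpp")
    return(cpp_gpb2_run(dataset$counts, dataset$y0, p$kA, p$kD, p$NT, p$dt,
                        regime$Pi, regime$qs, init$mean, init$cov,
                        as.numeric(regime_init)))
  K <- nrow(dataset$counts)
  bel <- jump_belief(rep(list(init), H), regime_init)
  mean <- var <- numeric(K)
  rp <- matrix(0, K, H)
  y_prev <- dataset$y0
  for (k in seq_len(K)) {
    y <- dataset$counts[k, ]
    stp <- gpb2_step(bel, y, y_prev, p, regime)
    bel <- stp$belief
    mean[k] <- stp$mean
    var[k] <- stp$var
    rp[k, ] <- bel$regime_probs
    y_prev <- y
  }
  list(mean = mean, var = var, est = pmax(mean, 0), regime_probs = rp)
}
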