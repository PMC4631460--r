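#' One-interval survival and fill probabilities of a sensor site
#'
#' Over one sampling interval at constant concentration `C`, each occupied
#' site stays occupied with probability `lamF` and each empty site becomes
#' occupied with probability `lamE`.  These are the parameters of the two
#' binomials whose convolution is the exact one-step count distribution
#' (see [transition_pmf()]).  With `a = kA * C + kD`,
#' `lamE = kA * C * (1 - exp(-a * dt)) / a` and `lamF = lamE + exp(-a * dt)`.
#'
#' At `C = 0` the printed expressions are 0/0; the analytic limits
#' `lamF = exp(-kD * dt)`, `lamE = 0` (pure desorption) are returned.
#' `lamE` is evaluated through `expm1()` so the formula stays accurate for
#' arbitrarily small positive `C`, and `lamF` through the identity
#' `lamF - lamE = exp(-a * dt)`, which avoids cancellation.
#'
#' @param params A [sensor_params()] object.
#' @param C Local concentration in M (scalar or vector, nonnegative).
#' @return A list with numeric components `lamF` and `lamE`, each the same
#'   length as `C`, both in `[0, 1]` with `lamE <= lamF`.
#' @examples
#' p <- sensor_params(100, 0.001, 10, 1)
#' occupancy_fractions(p, 1e-5)
#' @export
occupancy_fractions <- function(params, C) {
  assert_params(params)
  assert_conc(C)
  a <- params$kA * C + params$kD
  decay <- exp(-a * params$dt)
  lamE <- ifelse(C > 0, params$kA * C / a * (-expm1(-a * params$dt)), 0)
  list(lamF = lamE + decay, lamE = lamE)
}

#' Deterministic (continuum) one-step update of the mean occupancy
#'
#' Integrates the mean-field kinetics
#' `dN/dt = kA * C * (NT - N) - kD * N` over one sampling interval with `C`
#' held constant, starting from `N_prev`.  Algebraically this equals
#' `N_prev * lamF + (NT - N_prev) * lamE`, which is the form evaluated here
#' (it is also the exact mean of [transition_pmf()]).
#'
#' @inheritParams occupancy_fractions
#' @param N_prev Previous (real-valued) occupancy in `[0, NT]`.
#' @return Occupancy after one interval, in `[0, NT]`.
#' @export
continuum_update <- function(params, N_prev, C) {
  assert_params(params)
  assert_conc(C)
  if (!is.numeric(N_prev) || anyNA(N_prev) ||
      any(N_prev < 0) || any(N_prev > params$NT))
    stop("`N_prev` must lie in [0, NT]", call. = FALSE)
  lam <- occupancy_fractions(params, C)
  N_prev * lam$lamF + (params$NT - N_prev) * lam$lamE
}

#' Exact one-step count distribution (convolution of two binomials)
#'
#' Conditional on the previously observed count `y_prev`, the next count is
#' the sum of the survivors of the `y_prev` occupied sites
#' (`Binomial(y_prev, lamF)`) and the newly filled ones among the
#' `NT - y_prev` empty sites (`Binomial(NT - y_prev, lamE)`).  This is the
#' exact solution of the chemical master equation for this monomolecular
#' system and is used directly as the particle-filter likelihood.
#'
#' @inheritParams occupancy_fractions
#' @param y_prev Previously observed integer count in `{0..NT}`.
#' @return Numeric vector of length `NT + 1`; element `i + 1` is
#'   `Pr(count = i)`.  Sums to 1.
#' @examples
#' p <- sensor_params(100, 0.001, 10, 1)
#' transition_pmf(p, y_prev = 0, C = 1e-5)
#' @export
transition_pmf <- function(params, y_prev, C) {
  assert_params(params)
  assert_conc(C)
  stopifnot(length(C) == 1L)
  y_prev <- assert_count(y_prev, params$NT, "y_prev")
  stopifnot(length(y_prev) == 1L)
  NT <- params$NT
  lam <- occupancy_fractions(params, C)
  pF <- stats::dbinom(0:y_prev, y_prev, lam$lamF)
  pE <- stats::dbinom(0:(NT - y_prev), NT - y_prev, lam$lamE)
  out <- numeric(NT + 1L)
  for (m in 0:y_prev)
    out[(m + 0:(NT - y_prev)) + 1L] <-
      out[(m + 0:(NT - y_prev)) + 1L] + pF[m + 1L] * pE
  out
}

#' Generator matrix of the chemical master equation
#'
#' The occupancy count performs a birth-death process on `{0..NT}` with
#' birth (adsorption) rate `kA * C * (NT - i)` and death (desorption) rate
#' `kD * i` from state `i`.  Returns the `(NT+1) x (NT+1)` rate matrix `G`
#' with `G[i, j]` the rate from state `i - 1` to `j - 1` and rows summing
#' to zero, so that a row-vector distribution evolves as `p(t) = p0 expm(G t)`.
#'
#' @inheritParams occupancy_fractions
#' @return A dense numeric matrix.
#' @export
cme_generator <- function(params, C) {
  assert_params(params)
  assert_conc(C)
  stopifnot(length(C) == 1L)
  NT <- params$NT
  i <- 0:NT
  up <- params$kA * C * (NT - i)   # last entry 0
  down <- params$kD * i            # first entry 0
  G <- matrix(0, NT + 1L, NT + 1L)
  G[cbind(1:NT, 2:(NT + 1L))] <- up[1:NT]
  G[cbind(2:(NT + 1L), 1:NT)] <- down[2:(NT + 1L)]
  diag(G) <- -(up + down)
  G
}

#' Propagate a count distribution through the chemical master equation
#'
#' Integrates the `(NT+1)`-state master equation at constant concentration
#' `C` over `duration` seconds, via the matrix exponential of the generator
#' (exact at these dimensions).  Serves as the independent oracle for
#' [transition_pmf()].
#'
#' @inheritParams occupancy_fractions
#' @param init Numeric probability vector of length `NT + 1` (sums to 1).
#' @param duration Nonnegative time in seconds.
#' @return Probability vector of length `NT + 1`.
#' @export
cme_propagate <- function(params, init, C, duration) {
  assert_params(params)
  assert_conc(C)
  stopifnot(length(C) == 1L)
  stopifnot(is.numeric(duration), length(duration) == 1L, duration >= 0)
  NT <- params$NT
  if (!is.numeric(init) || length(init) != NT + 1L || any(init < 0) ||
      abs(sum(init) - 1) > 1e-8)
    stop("`init` must be a probability vector of length NT + 1",
         call. = FALSE)
  if (duration == 0) return(init)
  G <- cme_generator(params, C)
  P <- as.matrix(Matrix::expm(Matrix::Matrix(G * duration)))
  drop(init %*% P)
}

#' Moment-matched Gaussian approximation of the one-step count model
#'
#' Replaces each of the two binomials in [transition_pmf()] by a normal
#' with the same mean and variance; their convolution is again normal.
#' Because moment matching is exact for binomials, `mean` and `var` equal
#' the exact mean and variance of the convolved-binomial distribution.
#' These moments define the observation function and measurement-noise
#' variance used by the Kalman filters.
#'
#' @inheritParams transition_pmf
#' @return A list with components `muF`, `varF` (occupied-subset binomial),
#'   `muE`, `varE` (empty-subset binomial), and their sums `mean`, `var`.
#' @export
gaussian_obs_moments <- function(params, y_prev, C) {
  assert_params(params)
  assert_conc(C)
  y_prev <- assert_count(y_prev, params$NT, "y_prev")
  lam <- occupancy_fractions(params, C)
  muF <- y_prev * lam$lamF
  varF <- y_prev * lam$lamF * (1 - lam$lamF)
  muE <- (params$NT - y_prev) * lam$lamE
  varE <- (params$NT - y_prev) * lam$lamE * (1 - lam$lamE)
  list(muF = muF, varF = varF, muE = muE, varE = varE,
       mean = muF + muE, var = varF + varE)
}

# Documented finite cap substituting the +Inf log-density that arises in
# gaussian mode when var = 0 and the observation sits exactly at the mean.
LOGLIK_CAP <- 700

#' Log-likelihood of an observed count given the previous count
#'
#' `mode = "exact"` evaluates the log of [transition_pmf()] at `y`;
#' `mode = "gaussian"` evaluates the continuous normal log-density with the
#' moment-matched mean and variance of [gaussian_obs_moments()] (no
#' continuity correction).  In gaussian mode with `var = 0` the density is
#' degenerate: the function returns `-Inf` when `y != mean` and a finite
#' cap of `700` (on the log scale) when `y == mean`.
#'
#' @inheritParams transition_pmf
#' @param y Observed integer count in `{0..NT}`.
#' @param mode `"exact"` or `"gaussian"`.
#' @return A log-probability (exact) or log-density (gaussian).
#' @export
count_loglik <- function(params, y, y_prev, C, mode = c("exact", "gaussian")) {
  mode <- match.arg(mode)
  assert_params(params)
  y <- assert_count(y, params$NT, "y")
  if (mode == "exact") {
    pmf <- transition_pmf(params, y_prev, C)
    return(log(pmf[y + 1L]))
  }
  mom <- gaussian_obs_moments(params, y_prev, C)
  if (mom$var == 0) {
    return(if (isTRUE(all.equal(as.numeric(y), mom$mean))) LOGLIK_CAP
           else -Inf)
  }
  stats::dnorm(y, mom$mean, sqrt(mom$var), log = TRUE)
}
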