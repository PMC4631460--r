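#' Process model for the true concentration dynamics
#'
#' Two forms of concentration dynamics are supported.
#' `kind = "random_walk"` is an integrated white-noise process
#' `x_k = x_{k-1} + w_k`, `w_k ~ N(0, q)`, describing the slowly varying
#' release of signal molecules from a quiescent cell.
#' `kind = "regime_switching"` couples the same random walk to a hidden
#' finite-state Markov chain (see [regime_model()]): the process-noise
#' variance at step `k` is that of the current regime, so a low-noise
#' "normal" regime alternates with a high-noise "drifting" regime
#' (intermittent drift).
#'
#' Truth trajectories are clipped at 0 step-by-step, since a concentration
#' is physical; at the default noise scales the clip never triggers.
#'
#' @param kind `"random_walk"` or `"regime_switching"`.
#' @param q Process-noise variance in M^2 (random-walk kind).
#' @param regime A [regime_model()] (regime-switching kind).
#' @param x0 Initial true concentration in M.
#' @return An object of class `"process_model"`.
#' @examples
#' process_model("random_walk", q = 1e-16, x0 = 1e-5)
#' @export
process_model <- function(kind = c("random_walk", "regime_switching"),
                          q = 1e-16, regime = NULL, x0 = 1e-5) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(x0), length(x0) == 1L, x0 >= 0)
  if (kind == "random_walk") {
    stopifnot(is.numeric(q), length(q) == 1L, q >= 0)
    regime <- NULL
  } else {
    if (!inherits(regime, "regime_model"))
      stop("regime_switching kind needs a regime_model()", call. = FALSE)
    q <- NA_real_
  }
  structure(list(kind = kind, q = q, regime = regime, x0 = x0),
            class = "process_model")
}

#' Hidden-Markov regime model for intermittent concentration drift
#'
#' A hidden regime `r_k` follows a finite-state Markov chain with
#' row-stochastic transition matrix `Pi`; regime `h` drives the
#' concentration random walk with process-noise variance `qs[h]`.  The
#' two-regime case with `qs[1] ~ 0 << qs[2]` models a cell switching
#' between a quiescent (normal) state and a state whose signal-molecule
#' output drifts rapidly (tumor-like activity).
#'
#' `switch_time` selects a deterministic alternative to Markov sampling:
#' the regime is forced to state 1 before that time and state 2 from it
#' onwards (useful for figure-style demonstrations and detection tests).
#'
#' @param Pi H x H row-stochastic transition matrix.
#' @param qs Per-regime process-noise variances in M^2, length H.
#' @param switch_time Optional forced switch time in seconds (2-regime
#'   models only); `NULL` (default) samples the chain from `Pi`.
#' @return An object of class `"regime_model"`.
#' @examples
#' regime_model(Pi = matrix(c(.99, .01, .01, .99), 2, byrow = TRUE),
#'              qs = c(1e-16, 5e-14))
#' @export
regime_model <- function(Pi = matrix(c(0.99, 0.01, 0.01, 0.99), 2,
                                     byrow = TRUE),
                         qs = c(1e-16, 5e-14), switch_time = NULL) {
  Pi <- as.matrix(Pi)
  H <- nrow(Pi)
  stopifnot(ncol(Pi) == H, H >= 1, all(Pi >= 0), all(Pi <= 1))
  if (any(abs(rowSums(Pi) - 1) > 1e-10))
    stop("rows of Pi must sum to 1", call. = FALSE)
  stopifnot(is.numeric(qs), length(qs) == H, all(qs >= 0))
  if (!is.null(switch_time)) {
    stopifnot(H == 2L, is.numeric(switch_time), switch_time >= 0)
  }
  structure(list(Pi = Pi, qs = as.numeric(qs), H = H,
                 switch_time = switch_time),
            class = "regime_model")
}

#' @export
print.process_model <- function(x, ...) {
  cat(sprintf("Concentration process model (%s)\n", x$kind))
  cat(sprintf("  x0: %g M\n", x$x0))
  if (x$kind == "random_walk") cat(sprintf("  q:  %g M^2\n", x$q))
  else {
    cat(sprintf("  regimes: %d, variances %s M^2\n", x$regime$H,
                paste(signif(x$regime$qs, 3), collapse = ", ")))
  }
  invisible(x)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed))
  expr
}

#' Simulate a ground-truth concentration trajectory
#'
#' Draws `x_k = x_{k-1} + w_k` for `k = 1..n_steps` starting from the
#' model's `x0`, with `w_k ~ N(0, q)` (random walk) or
#' `w_k ~ N(0, qs[r_k])` where the hidden regime `r_k` starts in state 1
#' and follows the regime model's Markov chain (or its forced switch).
#' Negative excursions are clipped at 0.
#'
#' @param model A [process_model()].
#' @param n_steps Number of sampling instants (>= 1).
#' @param dt Sampling interval in seconds (used only to place a forced
#'   regime switch on the time grid).
#' @param seed Optional integer seed (`set.seed()` is called when given);
#'   with `seed = NULL` the current RNG stream is used.
#' @return A list with `C` (length `n_steps`, concentrations at
#'   `t = dt, ..., n_steps * dt`) and `regimes` (integer vector, or `NULL`
#'   for the random walk).
#' @export
simulate_concentration <- function(model, n_steps, dt = 1, seed = NULL) {
  if (!inherits(model, "process_model"))
    stop("`model` must be a process_model()", call. = FALSE)
  stopifnot(is.numeric(n_steps), length(n_steps) == 1L, n_steps >= 1)
  n_steps <- as.integer(n_steps)
  with_seed(seed, {
    if (model$kind == "random_walk") {
      regimes <- NULL
      sds <- rep(sqrt(model$q), n_steps)
    } else {
      rm_ <- model$regime
      if (!is.null(rm_$switch_time)) {
        regimes <- ifelse(seq_len(n_steps) * dt < rm_$switch_time, 1L, 2L)
      } else {
        regimes <- integer(n_steps)
        r <- 1L
        for (k in seq_len(n_steps)) {
          r <- sample.int(rm_$H, 1L, prob = rm_$Pi[r, ])
          regimes[k] <- r
        }
      }
      sds <- sqrt(rm_$qs[regimes])
    }
    w <- stats::rnorm(n_steps, 0, sds)
    C <- numeric(n_steps)
    x <- model$x0
    for (k in seq_len(n_steps)) {
      x <- max(x + w[k], 0)
      C[k] <- x
    }
    list(C = C, regimes = regimes)
  })
}

#' Simulate sensor counts by exact kinetic Monte Carlo (SSA)
#'
#' Runs the stochastic simulation algorithm for the adsorption/desorption
#' birth-death process within each sampling interval, with propensities
#' `kA * C_k * (NT - y)` (adsorption) and `kD * y` (desorption) and the
#' concentration held constant over the interval, recording the occupancy
#' at each sampling instant.  Each trajectory is one exact realization of
#' the chemical master equation.
#'
#' @inheritParams occupancy_fractions
#' @param C_true Concentration trajectory, one value per sampling interval.
#' @param y0 Initial occupancy count in `{0..NT}`.
#' @param seed Optional integer seed.
#' @return Integer vector of counts, same length as `C_true`.
#' @export
simulate_counts_ssa <- function(params, C_true, y0 = 0, seed = NULL) {
  assert_params(params)
  assert_conc(C_true)
  y0 <- assert_count(y0, params$NT, "y0")
  with_seed(seed,
    cpp_ssa_counts(as.numeric(C_true), y0, params$kA, params$kD,
                   params$NT, params$dt))
}

#' Simulate sensor counts by sampling the analytic one-step kernel
#'
#' Draws `y_k ~ Binomial(y_{k-1}, lamF) + Binomial(NT - y_{k-1}, lamE)`
#' directly from the exact convolved-binomial transition law.  At the
#' sampling instants this is distributionally identical to
#' [simulate_counts_ssa()] (a tested equivalence), at a fraction of the
#' cost.
#'
#' @inheritParams simulate_counts_ssa
#' @return Integer vector of counts, same length as `C_true`.
#' @export
simulate_counts_exact <- function(params, C_true, y0 = 0, seed = NULL) {
  assert_params(params)
  assert_conc(C_true)
  y0 <- assert_count(y0, params$NT, "y0")
  with_seed(seed, {
    lam <- occupancy_fractions(params, C_true)
    n <- length(C_true)
    y <- integer(n)
    yp <- y0
    for (k in seq_len(n)) {
      yp <- stats::rbinom(1L, yp, lam$lamF[k]) +
        stats::rbinom(1L, params$NT - yp, lam$lamE[k])
      y[k] <- yp
    }
    y
  })
}

#' Generate a complete synthetic sensor-array dataset
#'
#' Draws one shared ground-truth concentration trajectory and `Ns`
#' conditionally independent sensor count trajectories (kinetic Monte
#' Carlo by default).  Initial counts follow `y0_policy`: `"zero"` starts
#' every sensor empty; `"random"` draws each sensor's initial count
#' uniformly from `{0 .. NT-1}` (partly occupied).
#'
#' @param model A [process_model()].
#' @param params A [sensor_params()].
#' @param Ns Number of sensors sharing the local concentration.
#' @param n_steps Number of sampling instants.
#' @param y0_policy `"zero"` or `"random"`.
#' @param seed Optional integer seed; fixed seeds reproduce the dataset
#'   bit-for-bit (including its CSV serialization).
#' @param sampler Count sampler: `"ssa"` (exact kinetic Monte Carlo) or
#'   `"exact"` (analytic one-step kernel).
#' @return An object of class `"cnt_dataset"`: a list with `times`
#'   (`k * dt`), `C_true`, `regimes` (or `NULL`), `counts`
#'   (`n_steps x Ns` integer matrix), `params`, `Ns`, plus the initial
#'   conditions `x0`, `y0` (length `Ns`) at `t = 0`.
#' @examples
#' d <- generate_dataset(process_model(q = 1e-16), sensor_params(),
#'                       Ns = 2, n_steps = 50, seed = 1)
#' d
#' @export
generate_dataset <- function(model, params, Ns = 1, n_steps = 2000,
                             y0_policy = c("zero", "random"), seed = NULL,
                             sampler = c("ssa", "exact")) {
  y0_policy <- match.arg(y0_policy)
  sampler <- match.arg(sampler)
  assert_params(params)
  stopifnot(is.numeric(Ns), length(Ns) == 1L, Ns >= 1)
  Ns <- as.integer(Ns)
  with_seed(seed, {
    sim <- simulate_concentration(model, n_steps, dt = params$dt)
    y0 <- if (y0_policy == "zero") rep(0L, Ns)
          else sample.int(params$NT, Ns, replace = TRUE) - 1L
    draw <- if (sampler == "ssa") simulate_counts_ssa else simulate_counts_exact
    counts <- vapply(seq_len(Ns),
                     function(j) draw(params, sim$C, y0[j]),
                     integer(n_steps))
    structure(list(times = seq_len(n_steps) * params$dt,
                   C_true = sim$C, regimes = sim$regimes,
                   counts = matrix(counts, nrow = n_steps, ncol = Ns,
                                   dimnames = list(NULL, paste0("y_", seq_len(Ns)))),
                   params = params, Ns = Ns,
                   x0 = model$x0, y0 = y0, regime0 = 1L),
              class = "cnt_dataset")
  })
}

#' @export
print.cnt_dataset <- function(x, ...) {
  cat(sprintf("Sensor-array dataset: %d instants x %d sensor(s), dt = %g s\n",
              length(x$times), x$Ns, x$params$dt))
  cat(sprintf("  true concentration: %.3g .. %.3g M%s\n",
              min(x$C_true), max(x$C_true),
              if (is.null(x$regimes)) "" else
                sprintf(" (%d regime switches)", sum(diff(x$regimes) != 0))))
  cat(sprintf("  counts: %d .. %d of NT = %d sites\n",
              min(x$counts), max(x$counts), x$params$NT))
  invisible(x)
}

#' @rdname generate_dataset
#' @param dataset A `"cnt_dataset"` object.
#' @param path File path for the CSV.
#' @details The CSV serialization has the header
#'   `t,C_true,regime,y_1,...,y_Ns` and one leading `t = 0` row carrying
#'   the initial conditions (`x0`, starting regime, `y0`), followed by one
#'   row per sampling instant, so a dataset round-trips losslessly through
#'   [write_dataset_csv()] / [read_dataset_csv()].  The `regime` column is
#'   empty for random-walk datasets.
#' @export
write_dataset_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cnt_dataset"))
  reg <- if (is.null(dataset$regimes)) rep(NA_integer_, length(dataset$times))
         else dataset$regimes
  df <- data.frame(t = c(0, dataset$times),
                   C_true = c(dataset$x0, dataset$C_true),
                   regime = c(if (is.null(dataset$regimes)) NA_integer_
                              else dataset$regime0, reg))
  cnts <- rbind(dataset$y0, dataset$counts)
  colnames(cnts) <- colnames(dataset$counts)
  df <- cbind(df, as.data.frame(cnts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname generate_dataset
#' @param params_csv Sensor parameters to attach to the re-read dataset
#'   (the CSV stores data only).
#' @export
read_dataset_csv <- function(path, params_csv = sensor_params()) {
  df <- utils::read.csv(path)
  stopifnot(nrow(df) >= 2L, df$t[1] == 0)
  ycols <- grep("^y_", names(df))
  counts <- as.matrix(df[-1L, ycols, drop = FALSE])
  storage.mode(counts) <- "integer"
  regimes <- if (all(is.na(df$regime))) NULL else as.integer(df$regime[-1L])
  structure(list(times = df$t[-1L], C_true = df$C_true[-1L],
                 regimes = regimes, counts = counts,
                 params = params_csv, Ns = length(ycols),
                 x0 = df$C_true[1L],
                 y0 = as.integer(df[1L, ycols]),
                 regime0 = if (is.null(regimes)) 1L else as.integer(df$regime[1L])),
            class = "cnt_dataset")
}
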