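#' Scaled root-mean-square estimation error
#'
#' Concentrations are multiplied by `1e5` before squaring, so an RMSE of
#' 1.0 corresponds to a 10 uM error.  For a single run this is
#' `sqrt(mean((C_true*1e5 - C_hat*1e5)^2))`; multi-run aggregation (see
#' [run_benchmark()]) takes the square root of the grand mean of squared
#' scaled errors over all runs and samples.
#'
#' @param C_true,C_hat True and estimated concentration trajectories in M
#'   (equal lengths).
#' @param scale Concentration scale factor (default `1e5`).
#' @param root Take the square root (default); `root = FALSE` returns the
#'   mean squared scaled error.
#' @return A nonnegative scalar.
#' @examples
#' scaled_rmse(rep(1e-5, 4), rep(2e-5, 4)) # constant 1e-5 M offset -> 1
#' @export
scaled_rmse <- function(C_true, C_hat, scale = 1e5, root = TRUE) {
  if (length(C_true) != length(C_hat))
    stop("trajectory lengths differ", call. = FALSE)
  mse <- mean(((C_true - C_hat) * scale)^2)
  if (root) sqrt(mse) else mse
}

subset_sensors <- function(dataset, js) {
  out <- dataset
  out$counts <- dataset$counts[, js, drop = FALSE]
  out$y0 <- dataset$y0[js]
  out$Ns <- length(js)
  out
}

#' Replicated benchmark of the recursive estimators
#'
#' Runs the full synthetic experiment: for each of `n_runs` replicates a
#' fresh ground-truth concentration trajectory and fresh kinetic Monte
#' Carlo sensor counts are drawn, every requested estimator is run from
#' the (wrong) initial guess on the same data, and squared scaled errors
#' are aggregated into the averaged scaled RMSE with a Monte Carlo
#' standard error (delta method on the per-run mean squared errors).
#'
#' Two scenarios are built in.  `"normal"`: quiescent-cell random-walk
#' concentration (variance `q`), 2000 instants, sensors starting empty,
#' estimators KF and PF.  `"two_state"`: hidden two-regime switching
#' concentration, 4000 instants, sensors starting at a random count below
#' `NT`, estimators KF-GPB2 and PF-MCMC (which are given the true regime
#' model).  Per-sensor-count results reuse the same per-run dataset
#' (estimators at `n` sensors see the first `n` columns).
#'
#' @param scenario `"normal"` or `"two_state"`.
#' @param estimators Subset of `c("kf", "pf", "kf-gpb2", "pf-mcmc")`;
#'   defaults depend on the scenario.
#' @param sensor_counts Sensor-array sizes to evaluate.
#' @param n_runs Number of independent replicates.
#' @param n_steps Instants per run (scenario default: 2000 or 4000).
#' @param seed Base seed; the full benchmark is deterministic given it.
#' @param params Sensor kinetics ([sensor_params()]).
#' @param x0 True initial concentration in M.
#' @param q Random-walk process-noise variance (normal scenario; also the
#'   filters' process model).
#' @param regime True and assumed [regime_model()] (two-state scenario).
#' @param M Particle count.
#' @param init_mean,init_var Filter initial guess.
#' @param verbose Print one line per run.
#' @return A data frame of class `"cnt_benchmark"` with columns
#'   `estimator`, `n_sensors`, `n_runs`, `rmse`, `mc_se`, `seconds`; the
#'   per-run mean squared scaled errors are attached as attribute
#'   `"per_run_mse"` (an `n_runs x cells` matrix).
#' @examples
#' run_benchmark("normal", sensor_counts = 1, n_runs = 2, n_steps = 100,
#'               seed = 1)
#' @export
run_benchmark <- function(scenario = c("normal", "two_state"),
                          estimators = NULL,
                          sensor_counts = c(1, 5, 10, 20),
                          n_runs = 100, n_steps = NULL, seed = 1,
                          params = sensor_params(), x0 = 1e-5,
                          q = 1e-16, regime = regime_model(), M = 200,
                          init_mean = 2e-5, init_var = 1e-10,
                          verbose = FALSE) {
  scenario <- match.arg(scenario)
  if (is.null(estimators))
    estimators <- if (scenario == "normal") c("pf", "kf")
                  else c("pf-mcmc", "kf-gpb2")
  stopifnot(all(estimators %in% c("kf", "pf", "kf-gpb2", "pf-mcmc")),
            n_runs >= 1, all(sensor_counts >= 1))
  if (is.null(n_steps))
    n_steps <- if (scenario == "normal") 2000L else 4000L
  if (scenario == "normal") {
    model <- process_model("random_walk", q = q, x0 = x0)
    y0_policy <- "zero"
  } else {
    model <- process_model("regime_switching", regime = regime, x0 = x0)
    y0_policy <- "random"
  }
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max - 1L, n_runs * 2L),
                  n_runs, 2L)
  cells <- expand.grid(estimator = estimators, n_sensors = sensor_counts,
                       stringsAsFactors = FALSE)
  sq <- matrix(NA_real_, n_runs, nrow(cells))
  secs <- numeric(nrow(cells))
  maxNs <- max(sensor_counts)
  for (i in seq_len(n_runs)) {
    d <- generate_dataset(model, params, Ns = maxNs, n_steps = n_steps,
                          y0_policy = y0_policy, seed = seeds[i, 1L])
    for (cell in seq_len(nrow(cells))) {
      dsub <- subset_sensors(d, seq_len(cells$n_sensors[cell]))
      est <- cells$estimator[cell]
      t0 <- proc.time()[["elapsed"]]
      fit <- switch(est,
        "kf" = kf_run(dsub, gaussian_belief(init_mean, init_var), q),
        "pf" = pf_run(dsub, c(init_mean, init_var), M = M, q = q,
                      seed = seeds[i, 2L]),
        "kf-gpb2" = gpb2_run(dsub, gaussian_belief(init_mean, init_var),
                             regime = regime),
        "pf-mcmc" = pfmcmc_run(dsub, c(init_mean, init_var), M = M,
                               regime = regime, seed = seeds[i, 2L]))
      secs[cell] <- secs[cell] + proc.time()[["elapsed"]] - t0
      sq[i, cell] <- scaled_rmse(d$C_true, fit$est, root = FALSE)
    }
    if (verbose)
      message(sprintf("run %d/%d done (seed %d)", i, n_runs, seeds[i, 1L]))
  }
  rmse <- sqrt(colMeans(sq))
  mc_se <- if (n_runs > 1)
    apply(sq, 2, stats::sd) / sqrt(n_runs) / (2 * rmse)
  else rep(NA_real_, nrow(cells))
  out <- data.frame(estimator = cells$estimator,
                    n_sensors = cells$n_sensors,
                    n_runs = n_runs, rmse = rmse, mc_se = mc_se,
                    seconds = secs / n_runs)
  attr(out, "per_run_mse") <- sq
  class(out) <- c("cnt_benchmark", "data.frame")
  out
}

#' @export
print.cnt_benchmark <- function(x, digits = 4, ...) {
  cat("Averaged scaled RMSE (x1e5 M) over", x$n_runs[1], "runs\n")
  y <- as.data.frame(x)
  y$rmse <- signif(y$rmse, digits)
  y$mc_se <- signif(y$mc_se, 2)
  y$seconds <- signif(y$seconds, 2)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' @rdname run_benchmark
#' @param benchmark A `"cnt_benchmark"` object.
#' @param path Output CSV path (columns
#'   `estimator,n_sensors,n_runs,rmse,mc_se,seconds`).
#' @export
write_benchmark_csv <- function(benchmark, path) {
  stopifnot(inherits(benchmark, "cnt_benchmark"))
  utils::write.csv(as.data.frame(benchmark), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
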