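#' Fit a recursive concentration estimator to sensor count data
#'
#' The package's modelling front-end: runs one of the four recursive
#' Bayesian estimators over a sensor-array dataset and returns a classed
#' fit with the usual accessor methods.
#'
#' * `"kf"` — linearized Kalman filter against the moment-matched
#'   Gaussian observation model.
#' * `"pf"` — bootstrap particle filter with the exact convolved-binomial
#'   likelihood.
#' * `"kf-gpb2"` — second-order generalized pseudo-Bayesian Kalman filter
#'   for the hidden two-regime (jump-Markov) concentration model.
#' * `"pf-mcmc"` — particle filter branched over the recent regime pair
#'   for the same jump-Markov model.
#'
#' @param dataset A `"cnt_dataset"` from [generate_dataset()] or
#'   [read_dataset_csv()].
#' @param method Estimator, see above.
#' @param init_mean,init_var Initial concentration guess (mean in M,
#'   variance in M^2).  The defaults deliberately start from a wrong mean
#'   of `2e-5` M with a standard deviation of the state scale.
#' @param q Process-noise variance used by the non-switching filters, M^2.
#' @param regime A [regime_model()] for the switching filters.
#' @param regime_init Initial regime probabilities (switching filters).
#' @param M Particle count for the particle filters.
#' @param seed Optional integer seed (particle filters).
#' @param engine `"cpp"` or `"r"` computation engine.
#' @param snapshots Sampling instants at which `"pf"` records its full
#'   particle set.
#' @return An object of class `"cnt_filter"` with methods [print()],
#'   [summary()], [fitted()] (point estimates), [residuals()]
#'   (estimate minus ground truth), and [plot()].
#' @examples
#' d <- generate_dataset(process_model(q = 1e-16), sensor_params(),
#'                       Ns = 1, n_steps = 200, seed = 42)
#' fit <- cnt_filter(d, "pf", seed = 7)
#' fit
#' head(fitted(fit))
#' @export
cnt_filter <- function(dataset,
                       method = c("kf", "pf", "kf-gpb2", "pf-mcmc"),
                       init_mean = 2e-5, init_var = 1e-10, q = 1e-16,
                       regime = regime_model(), regime_init = NULL,
                       M = 200, seed = NULL, engine = c("cpp", "r"),
                       snapshots = integer()) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  dataset <- as_dataset(dataset)
  res <- switch(method,
    "kf" = kf_run(dataset, gaussian_belief(init_mean, init_var), q,
                  engine = engine),
    "pf" = pf_run(dataset, c(init_mean, init_var), M = M, q = q,
                  seed = seed, snapshots = snapshots, engine = engine),
    "kf-gpb2" = gpb2_run(dataset, gaussian_belief(init_mean, init_var),
                         regime = regime, regime_init = regime_init,
                         engine = engine),
    "pf-mcmc" = pfmcmc_run(dataset, c(init_mean, init_var), M = M,
                           regime = regime, regime_init = regime_init,
                           seed = seed, engine = engine))
  structure(list(method = method, est = res$est, var = res$var,
                 regime_probs = res$regime_probs,
                 resampled = res$resampled, snapshots = res$snapshots,
                 dataset = dataset, call = match.call(),
                 settings = list(init_mean = init_mean,
                                 init_var = init_var, q = q, M = M,
                                 regime = if (method %in% c("kf-gpb2", "pf-mcmc"))
                                   regime else NULL)),
            class = "cnt_filter")
}

#' @export
print.cnt_filter <- function(x, ...) {
  lab <- c("kf" = "Kalman filter",
           "pf" = "bootstrap particle filter",
           "kf-gpb2" = "GPB2 jump-Markov Kalman filter",
           "pf-mcmc" = "branched jump-Markov particle filter")[x$method]
  cat(sprintf("Concentration estimate: %s\n", lab))
  cat(sprintf("  %d instants, %d sensor(s)\n",
              length(x$est), x$dataset$Ns))
  cat(sprintf("  final estimate: %.4g M (truth %.4g M)\n",
              x$est[length(x$est)],
              x$dataset$C_true[length(x$dataset$C_true)]))
  cat(sprintf("  scaled RMSE (x1e5 M): %.4f\n",
              scaled_rmse(x$dataset$C_true, x$est)))
  invisible(x)
}

#' @export
summary.cnt_filter <- function(object, ...) {
  out <- list(method = object$method,
              n_steps = length(object$est),
              Ns = object$dataset$Ns,
              rmse = scaled_rmse(object$dataset$C_true, object$est),
              final_est = object$est[length(object$est)],
              final_truth = object$dataset$C_true[length(object$est)])
  if (!is.null(object$regime_probs)) {
    out$mean_p2 <- mean(object$regime_probs[, 2])
    if (!is.null(object$dataset$regimes))
      out$regime_accuracy <-
        mean((object$regime_probs[, 2] > 0.5) + 1L == object$dataset$regimes)
  }
  if (!is.null(object$resampled) && !anyNA(object$resampled))
    out$resample_rate <- mean(object$resampled)
  structure(out, class = "summary.cnt_filter")
}

#' @export
print.summary.cnt_filter <- function(x, ...) {
  cat(sprintf("%s fit over %d instants (%d sensors)\n",
              x$method, x$n_steps, x$Ns))
  cat(sprintf("  scaled RMSE (x1e5 M): %.4f\n", x$rmse))
  cat(sprintf("  final estimate %.4g M vs truth %.4g M\n",
              x$final_est, x$final_truth))
  if (!is.null(x$mean_p2))
    cat(sprintf("  mean posterior P(drifting regime): %.3f\n", x$mean_p2))
  if (!is.null(x$regime_accuracy))
    cat(sprintf("  regime classification accuracy: %.3f\n",
                x$regime_accuracy))
  if (!is.null(x$resample_rate))
    cat(sprintf("  resampling rate: %.3f\n", x$resample_rate))
  invisible(x)
}

#' @export
fitted.cnt_filter <- function(object, ...) object$est

#' @export
residuals.cnt_filter <- function(object, ...) {
  object$est - object$dataset$C_true
}

#' @param x A `"cnt_filter"` object.
#' @param show_regimes Shade the instants whose true regime is 2.
#' @param ... Passed to [graphics::plot()].
#' @rdname cnt_filter
#' @export
plot.cnt_filter <- function(x, show_regimes = TRUE, ...) {
  d <- x$dataset
  ylim <- range(d$C_true, x$est)
  graphics::plot(d$times, d$C_true, type = "l", col = "black",
                 xlab = "time [s]", ylab = "concentration [M]",
                 ylim = ylim, ...)
  if (show_regimes && !is.null(d$regimes) && any(d$regimes == 2L)) {
    idx <- which(d$regimes == 2L)
    graphics::rug(d$times[idx], col = grDevices::adjustcolor("red", 0.3))
  }
  graphics::lines(d$times, x$est, col = "blue")
  graphics::legend("topright", c("truth", x$method),
                   col = c("black", "blue"), lty = 1, bty = "n")
  invisible(x)
}

#' Write per-instant estimates to CSV
#'
#' Serializes a fit as `t,estimate,variance[,p_regime_1,...,p_regime_H]`
#' (variance only for the Kalman-type methods).
#'
#' @param fit A `"cnt_filter"` object.
#' @param path Output file path.
#' @export
write_estimates_csv <- function(fit, path) {
  stopifnot(inherits(fit, "cnt_filter"))
  df <- data.frame(t = fit$dataset$times, estimate = fit$est)
  if (!is.null(fit$var)) df$variance <- fit$var
  if (!is.null(fit$regime_probs)) {
    rp <- as.data.frame(fit$regime_probs)
    names(rp) <- paste0("p_regime_", seq_len(ncol(rp)))
    df <- cbind(df, rp)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
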