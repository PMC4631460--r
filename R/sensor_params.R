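#' Kinetic parameters of a single-molecule adsorption sensor
#'
#' Bundles the constants that define the reversible monomolecular
#' adsorption/desorption dynamics of one nanotube sensor: free analyte
#' molecules bind to any of `NT` identical surface sites with an effective
#' first-order rate constant `kA * C` (proportional to the local bulk
#' concentration `C`) and unbind with rate constant `kD`.  Counts are read
#' out every `dt` seconds.
#'
#' @param kA Adsorption rate prefactor in M^-1 s^-1; the effective
#'   adsorption rate constant at concentration `C` is `kA * C`.
#' @param kD Desorption rate constant in s^-1 (may be 0: irreversible
#'   binding).
#' @param NT Total number of adsorption sites (positive integer; about 10
#'   for nanotube sensors).
#' @param dt Sampling interval in seconds.
#'
#' @return An object of class `"sensor_params"`.
#' @examples
#' sensor_params(kA = 100, kD = 0.001, NT = 10, dt = 1)
#' @export
sensor_params <- function(kA = 100, kD = 0.001, NT = 10, dt = 1) {
  stopifnot(is.numeric(kA), length(kA) == 1L, is.finite(kA), kA > 0)
  stopifnot(is.numeric(kD), length(kD) == 1L, is.finite(kD), kD >= 0)
  stopifnot(is.numeric(NT), length(NT) == 1L, is.finite(NT), NT >= 1,
            NT == round(NT), NT <= 1000)
  stopifnot(is.numeric(dt), length(dt) == 1L, is.finite(dt), dt > 0)
  structure(list(kA = kA, kD = kD, NT = as.integer(NT), dt = dt),
            class = "sensor_params")
}

#' @export
print.sensor_params <- function(x, ...) {
  cat("Single-molecule sensor kinetics\n")
  cat(sprintf("  adsorption prefactor kA: %g M^-1 s^-1\n", x$kA))
  cat(sprintf("  desorption constant  kD: %g s^-1\n", x$kD))
  cat(sprintf("  adsorption sites     NT: %d\n", x$NT))
  cat(sprintf("  sampling interval    dt: %g s\n", x$dt))
  invisible(x)
}

assert_params <- function(params) {
  if (!inherits(params, "sensor_params"))
    stop("`params` must be created by sensor_params()", call. = FALSE)
  params
}

assert_conc <- function(C) {
  if (!is.numeric(C) || anyNA(C) || any(C < 0))
    stop("concentration must be nonnegative", call. = FALSE)
  C
}

assert_count <- function(y, NT, name = "y") {
  if (!is.numeric(y) || anyNA(y) || any(y != round(y)) ||
      any(y < 0) || any(y > NT))
    stop(sprintf("`%s` must be an integer count in {0..%d}", name, NT),
         call. = FALSE)
  as.integer(y)
}
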