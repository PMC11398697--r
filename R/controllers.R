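new_controller <- function(kind, kind_code, pars, theta0 = 0) {
  structure(list(kind = kind, kind_code = kind_code,
                 pars = pars, theta0 = theta0),
            class = "pend_controller")
}

#' @export
print.pend_controller <- function(x, ...) {
  cat("pendulum controller:", x$kind, "\n")
  invisible(x)
}

#' Constant motor-link command
#' @param value held angle (rad).
#' @export
controller_hold <- function(value = 0) {
  new_controller("hold", 0L, c(value = value))
}

#' Sinusoidal motor-link command
#'
#' `theta(t) = offset + A sin(w t + phase)`.
#'
#' @param A amplitude (rad).
#' @param freq frequency (Hz); `w = 2 pi freq`.
#' @param offset,phase offset (rad) and phase (rad).
#' @export
controller_sine <- function(A, freq, offset = 0, phase = 0) {
  new_controller(sprintf("sine %.3g rad @ %.3g Hz", A, freq), 1L,
                 c(A = A, w = 2 * pi * freq, offset = offset, phase = phase))
}

# wrap a plain R function f(t, state, theta_prev); runs on the slow R path
controller_rfun <- function(f) {
  ctrl <- new_controller("custom R function", NULL, NULL)
  ctrl$kind_code <- NULL
  ctrl$fun <- f
  ctrl
}

#' Baseline strategy BL1: resonant sine
#'
#' Commands `theta(t) = A sin(2 pi f_res t)` with `f_res` the mode-1
#' eigenfrequency `1/T(E)` of the conservative system, read off the
#' continued mode family at energy `E`. The amplitude default 0.12 rad is
#' the empirically tuned value that reaches both targets.
#'
#' @param family a [continue_mode()] mode family.
#' @param E energy level (J) at which the eigenfrequency is taken.
#' @param A amplitude (rad).
#' @export
make_bl1 <- function(family, E = 2.5, A = 0.12) {
  f <- eigenfrequency(family, E)
  ctrl <- controller_sine(A = A, freq = f)
  ctrl$kind <- sprintf("BL1 resonant sine (%.3g Hz, A = %.3g rad)", f, A)
  ctrl$freq <- f
  ctrl
}

#' Baseline strategy BL2: slow position-control sine
#'
#' Same sine as BL1 but at half the resonant frequency with amplitude 1.0
#' rad, so the motor link sweeps with the pendulum and spring deflections
#' stay small: a (rigid) position-control strategy.
#'
#' @inheritParams make_bl1
#' @export
make_bl2 <- function(family, E = 2.5, A = 1.0) {
  f <- eigenfrequency(family, E) / 2
  ctrl <- controller_sine(A = A, freq = f)
  ctrl$kind <- sprintf("BL2 slow sine (%.3g Hz, A = %.3g rad)", f, A)
  ctrl$freq <- f
  ctrl
}

#' Baseline strategy BL3: bang-bang with deadzone
#'
#' Each control sample evaluates the first-spring torque
#' `tau = k1 (theta_prev - q1)` from the previous command (zero-order hold)
#' and jumps the motor link to `+theta_hat` if `tau > eps_tau`, to
#' `-theta_hat` if `tau < -eps_tau`, and to 0 otherwise. From rest the
#' deadzone is absorbing, so the very first command is forced to
#' `kick * theta_hat` to start the oscillation; steady-state behavior does
#' not depend on the kick sign.
#'
#' @param params a [pendulum_params()] object (supplies `k1`).
#' @param eps_tau torque threshold (N m).
#' @param theta_hat commanded jump position (rad).
#' @param kick sign of the kick-start command (+1 or -1).
#' @export
make_bl3 <- function(params, eps_tau = 1.0, theta_hat = 0.5, kick = 1) {
  stopifnot(kick %in% c(-1, 1))
  ctrl <- new_controller(
    sprintf("BL3 bang-bang (eps_tau = %g N m, theta_hat = %g rad)",
            eps_tau, theta_hat),
    2L, c(eps_tau = eps_tau, theta_hat = theta_hat, kick = kick))
  ctrl
}

#' Randomly re-seeded sine command
#'
#' Amplitude and frequency are redrawn every `reseed_dt` seconds,
#' `A ~ U(1, 10)` rad and `w ~ U(0, 10)` rad/s, and the command is
#' `A sin(w t)`. Used to outline the pendulum's reachable space. Draws come
#' from R's RNG, so results are reproducible under `set.seed()`.
#'
#' @param reseed_dt resampling interval (s).
#' @param A_range,w_range uniform supports for amplitude (rad) and angular
#'   frequency (rad/s).
#' @export
controller_random <- function(reseed_dt = 0.1, A_range = c(1, 10),
                              w_range = c(0, 10)) {
  new_controller("random excitation", 3L,
                 c(reseed_dt = reseed_dt, A_lo = A_range[1], A_hi = A_range[2],
                   w_lo = w_range[1], w_hi = w_range[2]))
}
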