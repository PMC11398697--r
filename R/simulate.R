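#' Closed-loop simulation of the driven pendulum
#'
#' Runs the pendulum under a controller at a fixed control rate `fs`
#' (default 1 kHz, matching the experimental loop). At each control sample
#' the controller is queried once with `(t, state, previous command)`; the
#' resulting motor-link angle is held constant (zero-order hold) while the
#' continuous dynamics are advanced to the next sample with `n_sub`
#' classical Runge-Kutta substeps.
#'
#' @param params a [pendulum_params()] object.
#' @param controller a controller object (see [controller_hold()],
#'   [make_bl1()], ...) or a plain R function `f(t, state, theta_prev)`
#'   returning the commanded angle.
#' @param duration trial length (s).
#' @param fs control/sampling rate (Hz, >= 100).
#' @param initial initial [pend_state()]; defaults to rest at `q_eq`.
#' @param n_sub integrator substeps per control sample.
#' @return a `trial_log`: a data frame with columns
#'   `t, theta, q1, q2, qd1, qd2, tau` (with `tau = k1 (theta - q1)`
#'   exactly), carrying the parameters and sample rate as attributes.
#' @export
simulate <- function(params, controller, duration, fs = 1000,
                     initial = pend_state(params$q_eq), n_sub = 4) {
  stopifnot(duration > 0, fs >= 100)
  if (is.function(controller)) controller <- controller_rfun(controller)
  stopifnot(inherits(controller, "pend_controller"))
  if (is.null(controller$kind_code)) {
    out <- simulate_r(params, controller, duration, fs, initial, n_sub)
  } else {
    out <- simulate_core(param_vec(params), controller, duration, fs,
                         as.integer(n_sub), initial$q, initial$qdot)
  }
  log <- data.frame(t = out$t, theta = out$theta, q1 = out$q1, q2 = out$q2,
                    qd1 = out$qd1, qd2 = out$qd2, tau = out$tau)
  attr(log, "fs") <- fs
  attr(log, "params") <- params
  class(log) <- c("trial_log", "data.frame")
  log
}

# Pure-R reference loop for controllers given as R functions. Semantics are
# identical to the compiled path; kept for extensibility and cross-checking.
simulate_r <- function(params, controller, duration, fs, initial, n_sub) {
  n <- round(duration * fs) + 1
  dt <- 1 / fs
  h <- dt / n_sub
  pv <- param_vec(params)
  t <- theta <- q1 <- q2 <- qd1 <- qd2 <- numeric(n)
  st <- initial
  th_prev <- 0
  f <- controller$fun
  for (i in seq_len(n)) {
    ti <- (i - 1) * dt
    th <- f(ti, st, th_prev)
    if (!is.finite(th)) stop("controller returned a non-finite command at t = ", ti)
    t[i] <- ti; theta[i] <- th
    q1[i] <- st$q[1]; q2[i] <- st$q[2]
    qd1[i] <- st$qdot[1]; qd2[i] <- st$qdot[2]
    th_prev <- th
    if (i < n) {
      hold <- controller_hold(th)
      seg <- simulate_core(pv, hold, dt, n_sub / dt, 1L, st$q, st$qdot)
      m <- length(seg$t)
      st <- pend_state(c(seg$q1[m], seg$q2[m]), c(seg$qd1[m], seg$qd2[m]))
    }
  }
  list(t = t, theta = theta, q1 = q1, q2 = q2, qd1 = qd1, qd2 = qd2,
       tau = params$k1 * (theta - q1))
}

#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf("trial log: %d samples at %g Hz (%.3g s)\n",
              nrow(x), attr(x, "fs"), x$t[nrow(x)]))
  ev <- attr(x, "events")
  if (!is.null(ev))
    cat(sprintf("  scored: %d hits, %d overshoots, %d undershoots\n",
                sum(ev$kind == "hit"), sum(ev$kind == "overshoot"),
                sum(ev$kind == "undershoot")))
  invisible(x)
}

#' Write / read a trial log as CSV
#'
#' Samples go to `path` with header `t,theta,q1,q2,qd1,qd2,tau`; scored
#' events (if present) go to a sibling file `<path>_events.csv` with header
#' `t,kind,side`. Full double precision.
#'
#' @param log a `trial_log`.
#' @param path CSV file path.
#' @export
write_trial_log <- function(log, path) {
  df <- as.data.frame(log)[, c("t", "theta", "q1", "q2", "qd1", "qd2", "tau")]
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  ev <- attr(log, "events")
  if (!is.null(ev) && nrow(ev) > 0) {
    utils::write.csv(ev[, c("t", "kind", "side")],
                     sub("\\.csv$", "_events.csv", path), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_trial_log
#' @param fs sample rate of the stored log (Hz).
#' @param params the parameter set the log was produced with.
#' @export
read_trial_log <- function(path, fs = 1000, params = NULL) {
  log <- utils::read.csv(path)
  attr(log, "fs") <- fs
  attr(log, "params") <- params
  ev_path <- sub("\\.csv$", "_events.csv", path)
  if (file.exists(ev_path)) attr(log, "events") <- utils::read.csv(ev_path)
  class(log) <- c("trial_log", "data.frame")
  log
}

log_fs <- function(log) {
  fs <- attr(log, "fs")
  if (is.null(fs)) fs <- 1 / diff(log$t[1:2])
  fs
}
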