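# Data preparation and the four comparison metrics: hit score, oscillation
# frequency, the DTW-based mode metric against the ideal brake orbit, and
# the handle-motion descriptors (deflection ratio, phase lag, path-length
# ratio).

#' Cut a scored trial to whole swings
#'
#' Trims a scored trial so it starts at its first armed turning point and
#' ends at the last turning point on the opposite side, the same cut
#' applied to every kept trial before concatenation in
#' [prepare_subject()].
#'
#' @param log a scored `trial_log`.
#' @return the trimmed `trial_log` with re-indexed events.
#' @export
cut_trial <- function(log) {
  ev <- attr(log, "events")
  if (is.null(ev)) stop("trial must be scored before preparation")
  if (nrow(ev) < 2) return(log)
  i0 <- ev$idx[1]
  opp <- ev$idx[ev$side != ev$side[1]]
  i1 <- opp[length(opp)]
  keep <- seq(i0, i1)
  out <- log[keep, , drop = FALSE]
  ev2 <- ev[ev$idx >= i0 & ev$idx <= i1, , drop = FALSE]
  ev2$idx <- ev2$idx - i0 + 1L
  ev2$t <- out$t[ev2$idx]
  for (a in c("fs", "params")) attr(out, a) <- attr(log, a)
  attr(out, "events") <- ev2
  attr(out, "totals") <- attr(log, "totals")
  class(out) <- class(log)
  out
}

#' Combine a participant's trials for analysis
#'
#' Of the four scored trials per configuration, the one with the lowest hit
#' score is excluded (earliest on ties) to avoid bias from initial learning
#' or lapses. Each remaining trial is cut to start on one target side and
#' end on the opposite, then the three are concatenated into one log with a
#' rebuilt uniform time axis.
#'
#' @param trials list of exactly four scored `trial_log`s.
#' @return a combined scored `trial_log`; its `totals` attribute is the sum
#'   over the three kept (uncut) trials.
#' @export
prepare_subject <- function(trials) {
  if (length(trials) != 4) stop("expected exactly 4 scored trials")
  hits <- vapply(trials, function(x) unname(attr(x, "totals")["hits"]), 0)
  worst <- which.min(hits) # which.min takes the earliest on ties
  kept <- trials[-worst]
  cut <- lapply(kept, cut_trial)
  fs <- log_fs(cut[[1]])
  offs <- cumsum(c(0L, vapply(cut, nrow, 0L)))
  ev <- do.call(rbind, lapply(seq_along(cut), function(i) {
    e <- attr(cut[[i]], "events")
    e$idx <- e$idx + offs[i]
    e
  }))
  out <- do.call(rbind, lapply(cut, as.data.frame))
  out$t <- (seq_len(nrow(out)) - 1) / fs
  ev$t <- out$t[ev$idx]
  attr(out, "fs") <- fs
  attr(out, "params") <- attr(trials[[1]], "params")
  attr(out, "events") <- ev
  tot <- Reduce(`+`, lapply(kept, attr, "totals"))
  attr(out, "totals") <- tot
  class(out) <- c("trial_log", "data.frame")
  out
}

#' Oscillation frequency from turning points
#'
#' `f = 1 / (2 * mean interval between successive turning points)`.
#'
#' @param log a `trial_log`.
#' @param params parameter set (defaults to the log's).
#' @return frequency (Hz).
#' @export
oscillation_frequency <- function(log, params = attr(log, "params")) {
  tp <- find_turnings(log, params)
  if (nrow(tp) < 4) stop("too few turning points to estimate a frequency")
  1 / (2 * mean(diff(tp$t)))
}

# linear resampling of a multi-column segment onto n points
resample_mat <- function(mat, n) {
  x <- seq(0, 1, length.out = nrow(mat))
  xo <- seq(0, 1, length.out = n)
  apply(mat, 2, function(col) stats::approx(x, col, xout = xo)$y)
}

#' Average excited cycle of a trial
#'
#' Splits the log into periods (same-side turning point to same-side
#' return), keeps only periods whose two turning points were both scored as
#' hits (so the required energy level was maintained), resamples each onto
#' `N` samples and averages pointwise.
#'
#' @param log a scored `trial_log`.
#' @param N resampling length.
#' @param start_side which target side the cycle starts on.
#' @param require_hits if `TRUE` (default) keep only periods whose two
#'   turning points are both hits; set `FALSE` to average all periods
#'   (used for deterministic baselines whose steady cycle misses the disks,
#'   where the energy-maintenance filter would exclude everything).
#' @return an `N x 4` matrix with columns `q1, q2, qd1, qd2`, or `NULL`
#'   when no period qualifies.
#' @export
average_period <- function(log, N = 1000, start_side = "left",
                           require_hits = TRUE) {
  ev <- attr(log, "events")
  if (is.null(ev)) stop("log must be scored")
  cycles <- list()
  k <- 1
  while (k + 2 <= nrow(ev)) {
    if (ev$side[k] == start_side &&
        (!require_hits ||
           (ev$kind[k] == "hit" && ev$kind[k + 1] == "hit"))) {
      seg <- as.matrix(log[ev$idx[k]:ev$idx[k + 2],
                           c("q1", "q2", "qd1", "qd2")])
      cycles[[length(cycles) + 1]] <- resample_mat(seg, N)
    }
    k <- k + 1
  }
  if (length(cycles) == 0) return(NULL)
  Reduce(`+`, cycles) / length(cycles)
}

# resample a brake-orbit path to N samples, optionally starting at the
# opposite turning point (time shift of T/2 along the periodic orbit)
orbit_cycle <- function(orbit, N, from_B = FALSE) {
  p <- orbit$path
  tt <- seq(0, orbit$T, length.out = N)
  if (from_B) tt <- (tt + orbit$T / 2) %% orbit$T
  cols <- c("q1", "q2", "qd1", "qd2")
  sapply(cols, function(cl) stats::approx(p$t, p[[cl]], xout = tt)$y)
}

#' Mode metric: DTW distance to the ideal brake orbit
#'
#' Dynamic time warping between the averaged excited cycle and the
#' conservative brake orbit, both resampled to length `N` and aligned to
#' start at the turning point on the same target side. The cost per aligned
#' pair is the squared difference summed over the four dimensions
#' `(q1, q2, qd1, qd2)` (no square root), and the warping is
#' boundary-anchored, monotone, with unit steps. Zero iff the warped
#' sequences coincide. The value grows with `N`, so comparisons are only
#' meaningful at a shared `N` (reported alongside every value).
#'
#' @param cycle `N x 4` matrix (`q1, q2, qd1, qd2`), e.g. from
#'   [average_period()].
#' @param orbit a [solve_brake_orbit()] brake orbit.
#' @param N common resampling length.
#' @param start_side target side at which both sequences start.
#' @return the mode metric (dimensionless, >= 0).
#' @export
mode_metric <- function(cycle, orbit, N = nrow(cycle), start_side = "left") {
  if (ncol(cycle) != 4) stop("cycle must have 4 columns (q1, q2, qd1, qd2)")
  if (nrow(cycle) != N) cycle <- resample_mat(cycle, N)
  sideA <- if (orbit$qA[1] > 0) "left" else "right"
  ref <- orbit_cycle(orbit, N, from_B = (sideA != start_side))
  dtw_core(ref, as.matrix(cycle))
}

#' Phase lag between motor command and first link
#'
#' Cross-correlation lag between the mean-removed `theta` and `q1` series,
#' reported as the lag of the pendulum link behind the motor command (the
#' drive leads the response) and expressed as a fraction of the period
#' scaled to `2 pi`: `phi = 2 pi lag / T`, wrapped to `[0, 2 pi)`. The
#' series is trimmed to a whole number of periods and the correlation is
#' circular (FFT-based), which avoids the peak bias of windowed estimates
#' on quasi-periodic data; the peak is refined to sub-sample precision by
#' parabolic interpolation.
#'
#' @param log a `trial_log`.
#' @param T oscillation period (s), e.g. `1 / oscillation_frequency(log)`.
#' @param discard initial transient dropped (s).
#' @return phase lag (rad).
#' @export
phase_lag <- function(log, T, discard = 0) {
  d <- log[log$t >= log$t[1] + discard, ]
  fs <- log_fs(log)
  Tn <- round(T * fs)
  n_use <- floor(nrow(d) / Tn) * Tn
  if (n_use < Tn) stop("series shorter than one oscillation period")
  th <- d$theta[1:n_use]
  q1 <- d$q1[1:n_use]
  if (stats::sd(th) == 0 || stats::sd(q1) == 0)
    stop("degenerate (constant) series: phase lag undefined")
  th <- th - mean(th)
  q1 <- q1 - mean(q1)
  # circular cross-correlation r[k] = sum_t theta[t] q1[t + k]:
  # q1(t) = theta(t - L) peaks at k = L
  r <- Re(stats::fft(Conj(stats::fft(th)) * stats::fft(q1),
                     inverse = TRUE))
  cand <- seq_len(Tn) # lags 0 .. Tn - 1, one full period
  i <- which.max(r[cand])
  at <- function(j) r[((j - 1) %% n_use) + 1]
  k <- i - 1
  ym <- at(i - 1); y0 <- at(i); yp <- at(i + 1)
  denom <- ym - 2 * y0 + yp
  if (denom < 0) k <- k + 0.5 * (ym - yp) / denom
  phi <- (2 * pi * (k / fs) / T) %% (2 * pi)
  if (phi > 2 * pi - 1e-9) phi <- 0
  phi
}

#' Deflection ratio of the motor command
#'
#' Per period (same-side turning point to same-side return), the absolute
#' peaks `max |theta|` and `max |q1|` are taken and their quotient averaged
#' across periods. Small values indicate resonant amplification.
#'
#' @param log a `trial_log`.
#' @param params parameter set (defaults to the log's).
#' @param discard initial transient dropped (s).
#' @return the ratio (dimensionless).
#' @export
deflection_ratio <- function(log, params = attr(log, "params"), discard = 5) {
  d <- log[log$t >= log$t[1] + discard, ]
  for (a in c("fs", "params")) attr(d, a) <- attr(log, a)
  tp <- find_turnings(d, params)
  if (nrow(tp) < 3) stop("too few periods for a deflection ratio")
  ks <- seq(1, nrow(tp) - 2, by = 2)
  ratios <- vapply(ks, function(k) {
    rng <- tp$idx[k]:tp$idx[k + 2]
    max(abs(d$theta[rng])) / max(abs(d$q1[rng]))
  }, 0)
  mean(ratios)
}

#' Motor-link path length relative to the first link
#'
#' Total variation of `theta` over that of `q1`, as a percentage, over the
#' steady portion of the trial.
#'
#' @inheritParams deflection_ratio
#' @return percentage (0-100+).
#' @export
path_length_ratio <- function(log, discard = 5) {
  d <- log[log$t >= log$t[1] + discard, ]
  denom <- sum(abs(diff(d$q1)))
  if (denom == 0) stop("no pendulum motion: path ratio undefined")
  100 * sum(abs(diff(d$theta))) / denom
}

#' Full metric report for one prepared log
#'
#' Computes the comparison metrics of one combined (or single) scored log
#' against the ideal brake orbit: oscillation frequency, mode metric at
#' length `N`, deflection ratio, phase lag (as a fraction of pi), and the
#' hit/overshoot/undershoot totals carried by the log.
#'
#' @param log a scored `trial_log` (e.g. from [prepare_subject()]).
#' @param orbit the reference [solve_brake_orbit()] brake orbit.
#' @param N mode-metric resampling length.
#' @param discard steady-state window: initial seconds dropped for the
#'   handle-motion descriptors.
#' @return one-row data frame
#'   `f_osc, eta, rho, phi_over_pi, hits, overshoot, undershoot, N`.
#' @export
metrics_report <- function(log, orbit, N = 1000, discard = 5) {
  params <- attr(log, "params")
  f <- oscillation_frequency(log, params)
  cyc <- average_period(log, N)
  if (is.null(cyc)) cyc <- average_period(log, N, require_hits = FALSE)
  eta <- if (is.null(cyc)) NA_real_ else mode_metric(cyc, orbit, N)
  rho <- deflection_ratio(log, params, discard)
  phi <- phase_lag(log, T = 1 / f, discard = discard)
  tot <- attr(log, "totals")
  data.frame(f_osc = f, eta = eta, rho = rho, phi_over_pi = phi / pi,
             hits = unname(tot["hits"]), overshoot = unname(tot["overshoots"]),
             undershoot = unname(tot["undershoots"]), N = N)
}
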