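# Shared fixtures, computed lazily and cached for the whole run.

.fix <- new.env()

p0_family <- function() {
  if (is.null(.fix$p0f))
    .fix$p0f <- continue_mode(preset_params("P0"), 1, E_max = 2.6, dE = 0.25)
  .fix$p0f
}

p90_family <- function() {
  if (is.null(.fix$p90f))
    .fix$p90f <- continue_mode(preset_params("P90"), 1, E_max = 2.6, dE = 0.25)
  .fix$p90f
}

p0_orbit <- function() {
  if (is.null(.fix$p0o)) .fix$p0o <- orbit_at_energy(p0_family(), 2.5)
  .fix$p0o
}

p90_orbit <- function() {
  if (is.null(.fix$p90o)) .fix$p90o <- orbit_at_energy(p90_family(), 2.5)
  .fix$p90o
}

# Exhaustive-enumeration DTW oracle: minimum over every boundary-anchored
# monotone warping path with steps (1,0), (0,1), (1,1), squared-difference
# cost summed over dimensions. Independent of the DP implementation.
brute_dtw <- function(A, B) {
  n <- nrow(A)
  m <- nrow(B)
  cost <- function(i, j) sum((A[i, ] - B[j, ])^2)
  rec <- function(i, j) {
    c0 <- cost(i, j)
    if (i == n && j == m) return(c0)
    best <- Inf
    if (i < n) best <- min(best, rec(i + 1, j))
    if (j < m) best <- min(best, rec(i, j + 1))
    if (i < n && j < m) best <- min(best, rec(i + 1, j + 1))
    c0 + best
  }
  rec(1, 1)
}

# Analytic sinusoidal trial log (theta leads q1 by `lead` rad) for metric
# unit tests; q2 follows q1 with a fixed shape ratio.
make_sine_log <- function(freq = 0.78, A_th = 0.12, A_q1 = 1.0,
                          A_q2 = 0.5, lead = 0, duration = 20, fs = 1000,
                          params = preset_params("P0", damped = TRUE)) {
  t <- seq(0, duration, by = 1 / fs)
  w <- 2 * pi * freq
  q1 <- A_q1 * sin(w * t)
  q2 <- A_q2 * sin(w * t)
  theta <- A_th * sin(w * t + lead)
  log <- data.frame(t = t, theta = theta, q1 = q1, q2 = q2,
                    qd1 = A_q1 * w * cos(w * t), qd2 = A_q2 * w * cos(w * t),
                    tau = params$k1 * (theta - q1))
  attr(log, "fs") <- fs
  attr(log, "params") <- params
  class(log) <- c("trial_log", "data.frame")
  log
}

# Conservative playback of a brake orbit (motor link held at zero),
# starting at rest on a turning point: the reference "perfect" trial.
playback_log <- function(orbit, params, duration = 20, fs = 1000) {
  simulate(conservative(params), controller_hold(0), duration, fs = fs,
           initial = pend_state(orbit$qA))
}

energy_series <- function(log, params) {
  q <- cbind(log$q1, log$q2)
  qd <- cbind(log$qd1, log$qd2)
  vapply(seq_len(nrow(log)), function(i)
    total_energy(pend_state(q[i, ], qd[i, ]), params), 0)
}
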