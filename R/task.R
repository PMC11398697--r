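# Target placement, swing detection and the hit/overshoot/undershoot state
# machine, plus the two characterization protocols (frequency sweep, random
# excitation).

#' Target placement from brake-orbit turning points
#'
#' The two target disks sit on the forward-kinematic tip positions of the
#' turning points of the mode's brake orbit at energy `E`. The target whose
#' generating turning point has positive `q1` is the left one.
#'
#' @param family a [continue_mode()] family.
#' @param E energy level (J).
#' @param r_t target radius (m); the study used 0.1 m (0.05 m in the
#'   increased-accuracy variant).
#' @return a `pend_targets` object: `list(centers, radius)` with `centers`
#'   a data frame `side, cx, cy`.
#' @export
place_targets <- function(family, E, r_t = 0.1) {
  orb <- orbit_at_energy(family, E)
  tips <- rbind(forward_kinematics(orb$qA, family$params),
                forward_kinematics(orb$qB, family$params))
  sides <- ifelse(c(orb$qA[1], orb$qB[1]) > 0, "left", "right")
  new_targets(data.frame(side = sides, cx = tips[, 1], cy = tips[, 2]), r_t)
}

new_targets <- function(centers, r_t) {
  stopifnot(r_t > 0, nrow(centers) == 2,
            sum((centers$cx - rev(centers$cx))^2 +
                  (centers$cy - rev(centers$cy))^2) > 0)
  structure(list(centers = centers, radius = r_t), class = "pend_targets")
}

#' @export
print.pend_targets <- function(x, ...) {
  cat(sprintf("targets (r = %g m):\n", x$radius))
  print(x$centers, row.names = FALSE)
  invisible(x)
}

#' Off-mode target placement for the intermediate configuration
#'
#' The intermediate (`P45`) experiment deliberately places the targets off
#' the configuration's own mode: each target sits between the
#' corresponding-side targets of the extended (`P0`) and flexed (`P90`)
#' configurations, at the polar (angle and radius) midpoint about the
#' pendulum base.
#'
#' @param family_p0,family_p90 mode families of the `P0` and `P90` presets.
#' @param E energy level defining the reference targets (J).
#' @param r_t target radius (m).
#' @return a `pend_targets` object.
#' @export
place_targets_p45 <- function(family_p0, family_p90, E = 2.5, r_t = 0.1) {
  t0 <- place_targets(family_p0, E, r_t)$centers
  t90 <- place_targets(family_p90, E, r_t)$centers
  mid <- lapply(c("left", "right"), function(s) {
    a <- t0[t0$side == s, ]
    b <- t90[t90$side == s, ]
    ang <- (atan2(a$cy, a$cx) + atan2(b$cy, b$cx)) / 2
    rad <- (sqrt(a$cx^2 + a$cy^2) + sqrt(b$cx^2 + b$cy^2)) / 2
    data.frame(side = s, cx = rad * cos(ang), cy = rad * sin(ang))
  })
  new_targets(do.call(rbind, mid), r_t)
}

#' Serialize / read targets (CSV `side,cx,cy,radius`)
#' @param targets a `pend_targets` object.
#' @param path CSV path.
#' @export
write_targets <- function(targets, path) {
  df <- cbind(targets$centers, radius = targets$radius)
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path)
  new_targets(df[, c("side", "cx", "cy")], df$radius[1])
}

# Armed turning points of a trial: after each sign change of q1 (the link
# crossing the first joint's equilibrium axis), the swing's turning point is
# the sample of minimal Cartesian tip speed before the next crossing.
find_turnings <- function(log, params = attr(log, "params")) {
  q <- cbind(log$q1, log$q2)
  qd <- cbind(log$qd1, log$qd2)
  sp <- tip_speed(q, qd, params)
  s <- sign(log$q1)
  cross <- which(s[-length(s)] * s[-1] < 0)
  if (length(cross) < 2)
    return(data.frame(idx = integer(), t = numeric(), side = character()))
  out <- lapply(seq_len(length(cross) - 1), function(k) {
    rng <- (cross[k] + 1):cross[k + 1]
    i <- rng[which.min(sp[rng])]
    data.frame(idx = i, t = log$t[i],
               side = if (log$q1[i] > 0) "left" else "right")
  })
  do.call(rbind, out)
}

#' Score a trial against the targets
#'
#' Implements the task's state machine: hit detection re-arms at every
#' crossing of the first joint's equilibrium axis (`q1 = 0`), so the two
#' targets must be hit alternately. At each armed turning point (Cartesian
#' tip-speed minimum of the swing) the outcome is classified: tip inside
#' the closed target disk is a *hit*; a direction reversal short of the
#' target (tip angle short of the target-center angle along the swing
#' direction) is an *undershoot*; turning beyond it is an *overshoot*.
#'
#' @param log an unscored `trial_log`.
#' @param targets a [place_targets()] object.
#' @param params a [pendulum_params()] object (defaults to the log's).
#' @return the log with an `events` attribute (`t, kind, side, idx`) and a
#'   `totals` attribute `c(hits, overshoots, undershoots)`.
#' @export
score_trial <- function(log, targets, params = attr(log, "params")) {
  tp <- find_turnings(log, params)
  ctr <- targets$centers
  ev <- lapply(seq_len(nrow(tp)), function(k) {
    i <- tp$idx[k]
    p <- forward_kinematics(c(log$q1[i], log$q2[i]), params)
    side <- tp$side[k]
    cc <- ctr[ctr$side == side, ]
    d <- sqrt((p[1] - cc$cx)^2 + (p[2] - cc$cy)^2)
    kind <- if (d <= targets$radius) {
      "hit"
    } else {
      s <- if (side == "left") 1 else -1
      a_tip <- atan2(p[2], p[1])
      a_tar <- atan2(cc$cy, cc$cx)
      if (s * (a_tar - a_tip) > 0) "undershoot" else "overshoot"
    }
    data.frame(t = log$t[i], kind = kind, side = side, idx = i)
  })
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(t = numeric(), kind = character(), side = character(),
               idx = integer())
  attr(log, "events") <- ev
  attr(log, "totals") <- c(hits = sum(ev$kind == "hit"),
                           overshoots = sum(ev$kind == "overshoot"),
                           undershoots = sum(ev$kind == "undershoot"))
  log
}

#' Table of sweep frequencies and hand-tuned amplitudes
#'
#' The characterization sweep's drive frequencies (1..10 rad/s) with the
#' per-frequency sine amplitudes that were tuned so the first link reaches
#' about 1 rad of deflection, for the extended (`P0`) and flexed (`P90`)
#' configurations.
#'
#' @param preset `"P0"` or `"P90"`.
#' @return data frame with columns `omega` (rad/s) and `A` (rad).
#' @export
sweep_table <- function(preset = c("P0", "P90")) {
  preset <- match.arg(preset)
  A <- switch(preset,
              P0 = c(1.0, 0.8, 0.65, 0.35, 0.12, 0.55, 1.2, 1.6, 2.3, 3.0),
              P90 = c(1.0, 0.8, 0.65, 0.55, 0.3, 0.15, 0.6, 1.0, 1.4, 2.5))
  data.frame(omega = 1:10, A = A)
}

#' Frequency-sweep characterization
#'
#' Drives the damped system from rest with `theta = A sin(omega t)` for
#' `t_per` seconds per frequency, discards the transient, and summarizes
#' the steady response.
#'
#' @param params a damped [pendulum_params()] object.
#' @param table data frame `omega, A` as from [sweep_table()].
#' @param t_per seconds simulated per frequency.
#' @param discard transient seconds dropped before computing amplitudes.
#' @param fs control rate (Hz).
#' @return data frame `omega, A, max_q1, amplification` with
#'   `amplification = max |q1| / A`.
#' @export
frequency_sweep <- function(params, table, t_per = 30, discard = 10,
                            fs = 1000) {
  out <- lapply(seq_len(nrow(table)), function(i) {
    ctrl <- controller_sine(A = table$A[i], freq = table$omega[i] / (2 * pi))
    log <- simulate(params, ctrl, t_per, fs = fs)
    steady <- log$q1[log$t >= discard]
    data.frame(omega = table$omega[i], A = table$A[i],
               max_q1 = max(abs(steady)),
               amplification = max(abs(steady)) / table$A[i])
  })
  do.call(rbind, out)
}

#' Random-excitation characterization
#'
#' Commands `A sin(w t)` with `A ~ U(1, 10)` rad and `w ~ U(0, 10)` rad/s
#' redrawn every `reseed_dt` seconds, to outline the pendulum's reachable
#' joint space (which is far larger than the band swept by the mode).
#'
#' @param params a damped [pendulum_params()] object.
#' @param duration trial length (s).
#' @param reseed_dt resampling interval (s).
#' @param seed RNG seed (the run is a pure function of it).
#' @param fs control rate (Hz).
#' @return a `trial_log`.
#' @export
random_excitation <- function(params, duration = 60, reseed_dt = 0.1,
                              seed = 1, fs = 1000) {
  set.seed(seed)
  simulate(params, controller_random(reseed_dt), duration, fs = fs)
}
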