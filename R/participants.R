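# Synthetic participants: a generative stand-in for human joystick
# behavior, built from the minimal mechanism that reproduces the observed
# signatures (resonant entrainment, small command amplitude, an individual
# phase lag held consistently, an optional command plateau at the
# equilibrium crossing). It is a behavioral model for pipeline testing, not
# a claim about human control.

#' Sample a cohort of participant profiles
#'
#' Individual parameters are drawn once per participant and held fixed
#' across all of that participant's trials: intended phase lag
#' `phi_lag ~ U(0.15 pi, 0.70 pi)` (the range observed across people),
#' command equilibrium offset `theta_shift ~ N(0, 0.05)` rad, motor noise
#' `noise_sd ~ U(0.005, 0.02)` rad, a fixed amplitude-adaptation gain, and
#' a coin-flip plateau habit.
#'
#' @param n cohort size.
#' @param seed RNG seed; the cohort is a pure function of it.
#' @param amp_gain amplitude-adaptation gain (rad of command amplitude per
#'   meter of turning-point error).
#' @return data frame of profiles, one row per participant.
#' @export
sample_cohort <- function(n = 20, seed = 1, amp_gain = 0.6) {
  stopifnot(n >= 1)
  set.seed(seed)
  data.frame(subject = seq_len(n),
             phi_lag = stats::runif(n, 0.15 * pi, 0.70 * pi),
             theta_shift = stats::rnorm(n, 0, 0.05),
             noise_sd = stats::runif(n, 0.005, 0.02),
             amp_gain = amp_gain,
             plateau = stats::runif(n) < 0.5,
             seed = seed + 1000L * seq_len(n))
}

#' Closed-loop synthetic participant controller
#'
#' A phase-tracking oscillator: the pendulum phase is estimated from
#' `(q1, qd1)` via the quadrature angle `atan2(-qd1 / w, q1 - shift)` with
#' `w = 2 pi f_res`, and the command is
#' `theta = theta_shift + A_t cos(phase + phi_lag) + noise`, so the command
#' leads the first link by the profile's phase lag. The amplitude `A_t` is
#' adapted at every pendulum turning point: increased in proportion to an
#' undershoot distance, decreased for an overshoot, dead-banded at the
#' target radius. Optionally the command plateaus (is held) for
#' `plateau_dur` after the link crosses `q1 = 0`.
#'
#' @param profile one row of [sample_cohort()].
#' @param family mode family of the configuration being driven.
#' @param E task energy level (J).
#' @param targets the task targets.
#' @param freq optional eigenfrequency override (Hz); computed from the
#'   family at `E` when missing.
#' @param A0 initial command amplitude (rad).
#' @param plateau_dur plateau hold time (s).
#' @return a controller usable by [simulate()].
#' @export
participant_controller <- function(profile, family, E = 2.5, targets,
                                   freq = NULL, A0 = 0.05,
                                   plateau_dur = 0.05) {
  if (is.null(freq)) freq <- eigenfrequency(family, E)
  ctr <- targets$centers
  aL <- atan2(ctr$cy[ctr$side == "left"], ctr$cx[ctr$side == "left"])
  aR <- atan2(ctr$cy[ctr$side == "right"], ctr$cx[ctr$side == "right"])
  ctrl <- new_controller(
    sprintf("synthetic participant (phi = %.2f pi)", profile$phi_lag / pi),
    4L,
    c(w = 2 * pi * freq, phi_lag = profile$phi_lag,
      shift = profile$theta_shift, noise_sd = profile$noise_sd,
      A0 = A0, gain = profile$amp_gain,
      plateau = as.numeric(profile$plateau), plateau_dur = plateau_dur,
      targ_left = aL, targ_right = aR, deadband = targets$radius,
      A_min = 0.01, A_max = 1.2))
  ctrl$freq <- freq
  ctrl
}

#' Experiment plan
#'
#' The trial schedule presented to every participant: which pendulum
#' configurations appear (each exactly `trials` times, in per-participant
#' shuffled order), the trial duration, target radius and task energy.
#'
#' @param configs preset names, e.g. `c("P0", "P45", "P90")`.
#' @param trials trials per configuration.
#' @param duration recorded trial length (s).
#' @param transient settle-in seconds simulated before recording starts.
#' @param r_t target radius (m).
#' @param E task energy level (J).
#' @param fs control rate (Hz).
#' @param seed plan seed (trial order shuffling).
#' @export
experiment_plan <- function(configs = c("P0", "P45", "P90"), trials = 4,
                            duration = 40, transient = 5, r_t = 0.1,
                            E = 2.5, fs = 1000, seed = 1) {
  structure(list(configs = configs, trials = trials, duration = duration,
                 transient = transient, r_t = r_t, E = E, fs = fs,
                 seed = seed),
            class = "experiment_plan")
}

#' Per-configuration task setups
#'
#' Builds, for each configuration in the plan, the damped parameter set,
#' the conservative mode-1 family, the reference brake orbit at the task
#' energy and the targets. The off-mode (`P45`) targets are placed between
#' the `P0` and `P90` targets, so those two families are computed whenever
#' `P45` is requested. Increased-mass variants keep the original (`P0` /
#' `P90`) target positions, whose turning points they still cover at their
#' task energy.
#'
#' @param plan an [experiment_plan()].
#' @param families optional named list of precomputed conservative mode
#'   families (by preset name) to avoid recomputation.
#' @return named list per configuration:
#'   `list(params, family, orbit, targets, E)`.
#' @export
standard_setups <- function(plan, families = NULL) {
  need <- plan$configs
  if ("P45" %in% need) need <- union(need, c("P0", "P90"))
  # heavier-mass variants inherit the base configuration's targets
  need <- union(need, sub("_m2up", "", need[grepl("m2up", need)]))
  fams <- lapply(stats::setNames(need, need), function(nm) {
    if (!is.null(families[[nm]])) return(families[[nm]])
    Emax <- if (grepl("m2up", nm)) 2.4 else max(2.6, plan$E + 0.1)
    continue_mode(preset_params(nm), 1, E_max = Emax)
  })
  setups <- lapply(stats::setNames(plan$configs, plan$configs), function(nm) {
    E_task <- if (grepl("m2up", nm)) 2.3 else plan$E
    targets <- if (nm == "P45") {
      place_targets_p45(fams$P0, fams$P90, plan$E, plan$r_t)
    } else if (grepl("m2up", nm)) {
      base <- sub("_m2up", "", nm)
      place_targets(fams[[base]], plan$E, plan$r_t)
    } else {
      place_targets(fams[[nm]], E_task, plan$r_t)
    }
    list(params = preset_params(nm, damped = TRUE),
         family = fams[[nm]],
         orbit = orbit_at_energy(fams[[nm]], E_task),
         targets = targets, E = E_task)
  })
  setups
}

# deterministic 31-bit per-trial seed
trial_seed <- function(seed, subject, config_i, trial) {
  (seed * 2654435761 + subject * 97911 + config_i * 1009 + trial * 7) %%
    2147483647
}

#' Generate a synthetic experiment dataset
#'
#' Simulates every trial of the plan for every participant: the synthetic
#' controller drives the damped configuration for `transient + duration`
#' seconds, the transient settle-in is dropped (mimicking the recording
#' starting only once a rhythm is found), and the recorded 40 s are scored
#' against the targets. The first trial of each configuration is generated
#' with inflated motor noise so the worst-trial exclusion rule downstream
#' is exercised. The dataset is a pure function of the cohort and plan
#' seeds.
#'
#' @param cohort a [sample_cohort()] data frame.
#' @param plan an [experiment_plan()].
#' @param setups per-configuration setups from [standard_setups()].
#' @param out_dir if non-`NULL`, write
#'   `<out_dir>/subject<i>/<config>/trial<k>.csv` plus a `manifest.yaml`.
#' @param worst_noise_factor noise inflation for each configuration's first
#'   trial.
#' @return nested list `dataset[[subject]][[config]]` of 4 scored
#'   `trial_log`s each, invisibly carrying the plan as an attribute.
#' @export
generate_dataset <- function(cohort, plan, setups = standard_setups(plan),
                             out_dir = NULL, worst_noise_factor = 5) {
  res <- lapply(seq_len(nrow(cohort)), function(si) {
    prof <- cohort[si, ]
    set.seed(prof$seed)
    order <- sample(rep(seq_along(plan$configs), plan$trials))
    counters <- integer(length(plan$configs))
    trials <- lapply(stats::setNames(plan$configs, plan$configs),
                     function(nm) vector("list", plan$trials))
    for (oi in order) {
      counters[oi] <- counters[oi] + 1L
      nm <- plan$configs[oi]
      k <- counters[oi]
      su <- setups[[nm]]
      prof_k <- prof
      if (k == 1) prof_k$noise_sd <- prof$noise_sd * worst_noise_factor
      ctrl <- participant_controller(prof_k, su$family, su$E, su$targets,
                                     freq = 1 / su$orbit$T)
      set.seed(trial_seed(plan$seed, prof$subject, oi, k))
      log <- simulate(su$params, ctrl, plan$transient + plan$duration,
                      fs = plan$fs)
      log <- log[log$t >= plan$transient, , drop = FALSE]
      log$t <- log$t - log$t[1]
      attr(log, "fs") <- plan$fs
      attr(log, "params") <- su$params
      class(log) <- c("trial_log", "data.frame")
      trials[[nm]][[k]] <- score_trial(log, su$targets, su$params)
    }
    trials
  })
  names(res) <- paste0("subject", cohort$subject)
  attr(res, "plan") <- plan
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (si in seq_along(res)) {
      for (nm in plan$configs) {
        d <- file.path(out_dir, names(res)[si], nm)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_len(plan$trials))
          write_trial_log(res[[si]][[nm]][[k]],
                          file.path(d, sprintf("trial%d.csv", k)))
      }
    }
    yaml::write_yaml(list(cohort_seed = cohort$seed[1] - 1000L,
                          plan = unclass(plan), n = length(res)),
                     file.path(out_dir, "manifest.yaml"))
  }
  res
}

#' Cohort-level metric report
#'
#' Runs the full analysis path for every participant and configuration:
#' worst-trial exclusion, trial cutting and concatenation, then the four
#' comparison metrics against the configuration's reference brake orbit.
#'
#' @param dataset output of [generate_dataset()].
#' @param setups the same setups the dataset was generated with.
#' @param N mode-metric resampling length.
#' @return data frame: one row per subject and configuration.
#' @export
cohort_report <- function(dataset, setups, N = 1000) {
  plan <- attr(dataset, "plan")
  rows <- lapply(seq_along(dataset), function(si) {
    per_cfg <- lapply(names(setups), function(nm) {
      comb <- prepare_subject(dataset[[si]][[nm]])
      cbind(data.frame(subject = si, config = nm),
            metrics_report(comb, setups[[nm]]$orbit, N = N))
    })
    do.call(rbind, per_cfg)
  })
  do.call(rbind, rows)
}

#' Baseline strategy report through the identical metrics path
#'
#' Simulates a deterministic baseline controller on the damped system for
#' the same trial duration as the participants, scores it, cuts it the same
#' way, and computes the same metrics.
#'
#' @param controller a baseline controller ([make_bl1()], ...).
#' @param setup one element of [standard_setups()].
#' @param duration trial length (s).
#' @param N mode-metric resampling length.
#' @param fs control rate (Hz).
#' @return one-row data frame as [metrics_report()].
#' @export
baseline_report <- function(controller, setup, duration = 40, N = 1000,
                            fs = 1000) {
  log <- simulate(setup$params, controller, duration, fs = fs)
  log <- score_trial(log, setup$targets, setup$params)
  metrics_report(cut_trial(log), setup$orbit, N = N)
}
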