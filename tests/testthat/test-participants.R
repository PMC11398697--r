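test_that("cohort sampling is reproducible with the stated distributions", {
  a <- sample_cohort(20, seed = 11)
  b <- sample_cohort(20, seed = 11)
  expect_identical(a, b)
  big <- sample_cohort(1000, seed = 12)
  expect_true(all(big$phi_lag >= 0.15 * pi & big$phi_lag <= 0.70 * pi))
  expect_true(all(big$noise_sd >= 0.005 & big$noise_sd <= 0.02))
  expect_lt(abs(mean(big$theta_shift)), 0.01)
  # continuous draws: all profiles distinct
  expect_equal(anyDuplicated(a[, c("phi_lag", "theta_shift")]), 0L)
})

test_that("synthetic participants entrain to the mode and keep their lag", {
  fam <- p0_family()
  orb <- p0_orbit()
  tg <- place_targets(fam, 2.5)
  p <- preset_params("P0", damped = TRUE)
  # a phase-locked drive away from quadrature detunes the loop slightly,
  # so the entrainment band is tightest for mid-range lags
  cases <- list(list(phi = 0.2 * pi, tol = 0.08),
                list(phi = 0.3 * pi, tol = 0.05),
                list(phi = 0.45 * pi, tol = 0.05),
                list(phi = 0.6 * pi, tol = 0.05),
                list(phi = 0.7 * pi, tol = 0.08))
  for (cs in cases) {
    prof <- data.frame(subject = 1, phi_lag = cs$phi, theta_shift = 0,
                       noise_sd = 0, amp_gain = 0.6, plateau = FALSE,
                       seed = 1)
    ctrl <- participant_controller(prof, fam, 2.5, tg, freq = 1 / orb$T)
    log <- simulate(p, ctrl, 50)
    steady <- log[log$t >= 20, ]
    attr(steady, "fs") <- 1000
    attr(steady, "params") <- p
    class(steady) <- class(log)
    f <- oscillation_frequency(steady)
    expect_equal(f * orb$T, 1, tolerance = cs$tol)
    expect_lt(abs(phase_lag(steady, T = 1 / f) - cs$phi), 0.05 * pi)
    expect_lt(deflection_ratio(steady, p, discard = 0), 0.35)
  }
})

test_that("no amplitude adaptation from a weak start means no hits", {
  fam <- p0_family()
  tg <- place_targets(fam, 2.5)
  p <- preset_params("P0", damped = TRUE)
  prof <- data.frame(subject = 1, phi_lag = 0.45 * pi, theta_shift = 0,
                     noise_sd = 0, amp_gain = 0, plateau = FALSE, seed = 1)
  ctrl <- participant_controller(prof, fam, 2.5, tg, freq = 1 / p0_orbit()$T,
                                 A0 = 0.02)
  log <- score_trial(simulate(p, ctrl, 20), tg, p)
  expect_identical(unname(attr(log, "totals")["hits"]), 0L)
  expect_lt(max(abs(log$q1)), 0.6)
})

test_that("dataset generation: counts, determinism, worst-first degradation", {
  plan <- experiment_plan(configs = c("P0", "P90"), trials = 4,
                          duration = 10, transient = 2, seed = 21)
  setups <- standard_setups(plan, families = list(P0 = p0_family(),
                                                  P90 = p90_family()))
  coh <- sample_cohort(2, seed = 22)
  ds1 <- generate_dataset(coh, plan, setups)
  expect_length(ds1, 2)
  expect_named(ds1[[1]], c("P0", "P90"))
  expect_length(ds1[[1]]$P0, 4)
  expect_equal(nrow(ds1[[2]]$P90[[3]]), 10 * 1000 + 1)
  ds2 <- generate_dataset(coh, plan, setups)
  expect_equal(ds1[[1]]$P0[[2]]$q1, ds2[[1]]$P0[[2]]$q1)
  expect_equal(ds1[[2]]$P90[[4]]$theta, ds2[[2]]$P90[[4]]$theta)
})

test_that("dataset writing round-trips through the CSV layout", {
  plan <- experiment_plan(configs = "P0", trials = 4, duration = 6,
                          transient = 1, seed = 31)
  setups <- standard_setups(plan, families = list(P0 = p0_family()))
  coh <- sample_cohort(1, seed = 32)
  dir <- tempfile("dataset")
  ds <- generate_dataset(coh, plan, setups, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  f <- file.path(dir, "subject1", "P0", "trial2.csv")
  expect_true(file.exists(f))
  back <- read_trial_log(f, fs = 1000, params = setups$P0$params)
  expect_equal(back$q1, ds[[1]]$P0[[2]]$q1, tolerance = 1e-15)
  ev <- attr(ds[[1]]$P0[[2]], "events")
  if (nrow(ev) > 0)
    expect_equal(nrow(attr(back, "events")), nrow(ev))
  unlink(dir, recursive = TRUE)
})

test_that("analysis pipeline recovers the planted phase lags across a cohort", {
  plan <- experiment_plan(configs = "P0", trials = 4, duration = 15,
                          transient = 3, seed = 41)
  setups <- standard_setups(plan, families = list(P0 = p0_family()))
  coh <- sample_cohort(8, seed = 42)
  ds <- generate_dataset(coh, plan, setups)
  rep <- cohort_report(ds, setups, N = 200)
  r <- pearson_correlation(coh$phi_lag, rep$phi_over_pi * pi)
  expect_gt(r$r, 0.9)
})
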