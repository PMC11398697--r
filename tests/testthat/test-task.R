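test_that("forward kinematics of the tip", {
  p <- preset_params("P0")
  expect_equal(unname(forward_kinematics(c(0, 0), p)), c(1, 0))
  expect_equal(unname(forward_kinematics(c(0, pi), p)), c(0, 0),
               tolerance = 1e-12)
  # matrix input agrees with rowwise evaluation
  q <- rbind(c(0.2, 0.5), c(-1, 0.3))
  P <- forward_kinematics(q, p)
  expect_equal(unname(P[2, ]), unname(forward_kinematics(q[2, ], p)))
})

test_that("P0 targets sit symmetric about the bisector axis", {
  tg <- place_targets(p0_family(), 2.5)
  ctr <- tg$centers
  l <- ctr[ctr$side == "left", ]
  r <- ctr[ctr$side == "right", ]
  expect_equal(l$cx, r$cx, tolerance = 1e-6)
  expect_equal(l$cy, -r$cy, tolerance = 1e-6)
  expect_gt(l$cy, 0)
  expect_equal(tg$radius, 0.1)
})

test_that("off-mode targets lie between the P0 and P90 targets", {
  t45 <- place_targets_p45(p0_family(), p90_family(), 2.5)
  t0 <- place_targets(p0_family(), 2.5)$centers
  t90 <- place_targets(p90_family(), 2.5)$centers
  for (s in c("left", "right")) {
    a0 <- with(t0[t0$side == s, ], atan2(cy, cx))
    a90 <- with(t90[t90$side == s, ], atan2(cy, cx))
    a45 <- with(t45$centers[t45$centers$side == s, ], atan2(cy, cx))
    expect_gt(a45, min(a0, a90))
    expect_lt(a45, max(a0, a90))
  }
})

test_that("targets serialization round-trips", {
  tg <- place_targets(p0_family(), 2.5, r_t = 0.05)
  path <- tempfile(fileext = ".csv")
  write_targets(tg, path)
  back <- read_targets(path)
  expect_equal(back$centers$cx, tg$centers$cx, tolerance = 1e-12)
  expect_equal(back$radius, 0.05)
  unlink(path)
})

test_that("scoring: ideal playback hits alternately on every swing", {
  p <- preset_params("P0")
  tg <- place_targets(p0_family(), 2.5)
  log <- playback_log(p0_orbit(), p, duration = 20)
  log <- score_trial(log, tg, p)
  ev <- attr(log, "events")
  tot <- attr(log, "totals")
  expect_gt(nrow(ev), 20)
  expect_true(all(ev$kind == "hit"))
  expect_identical(unname(tot["hits"]), nrow(ev))
  # alternation: consecutive armed turning points are on opposite sides
  expect_true(all(ev$side[-1] != ev$side[-nrow(ev)]))
  # outcome counts partition the armed turning points
  expect_identical(sum(tot), nrow(ev))
})

test_that("scoring: short and excessive swings classify as under/overshoot", {
  p <- preset_params("P0")
  tg <- place_targets(p0_family(), 2.5)
  base <- playback_log(p0_orbit(), p, duration = 15)
  shrink <- base
  for (cl in c("q1", "q2", "qd1", "qd2")) shrink[[cl]] <- 0.8 * base[[cl]]
  shrink <- score_trial(shrink, tg, p)
  expect_identical(unname(attr(shrink, "totals")["hits"]), 0L)
  expect_true(all(attr(shrink, "events")$kind == "undershoot"))
  grow <- base
  for (cl in c("q1", "q2", "qd1", "qd2")) grow[[cl]] <- 1.2 * base[[cl]]
  grow <- score_trial(grow, tg, p)
  expect_identical(unname(attr(grow, "totals")["hits"]), 0L)
  expect_true(all(attr(grow, "events")$kind == "overshoot"))
})

test_that("frequency sweep peaks near resonance with unit link deflection", {
  p <- preset_params("P0", damped = TRUE)
  tab <- sweep_table("P0")
  sw <- frequency_sweep(p, tab[tab$omega %in% 4:6, ])
  expect_equal(sw$omega[which.max(sw$amplification)], 5)
  expect_true(all(sw$max_q1 > 0.5 & sw$max_q1 < 1.5))
  expect_equal(sw$amplification, sw$max_q1 / sw$A)
})

test_that("random excitation roams far beyond the mode's band", {
  p <- preset_params("P0", damped = TRUE)
  log <- random_excitation(p, duration = 30, seed = 4)
  pts <- cbind(log$q1, log$q2)
  hull <- grDevices::chull(pts)
  poly <- pts[hull, ]
  area <- function(xy) {
    n <- nrow(xy)
    j <- c(2:n, 1)
    abs(sum(xy[, 1] * xy[j, 2] - xy[j, 1] * xy[, 2])) / 2
  }
  orb <- as.matrix(p0_orbit()$path[, c("q1", "q2")])
  expect_gt(area(poly), 5 * area(orb[grDevices::chull(orb), ]))
  # the trajectory rarely tracks the mode path
  sub <- pts[seq(1, nrow(pts), by = 20), ]
  near <- vapply(seq_len(nrow(sub)), function(i) {
    min(pmax(abs(orb[, 1] - sub[i, 1]), abs(orb[, 2] - sub[i, 2]))) < 0.05
  }, TRUE)
  expect_lt(mean(near), 0.5)
})
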