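test_that("mass matrix matches hand-evaluated values and its structure", {
  p <- preset_params("P0")
  # hand evaluation with l = 0.5, m = (0.5, 0.25), J_i = m_i l^2 / 12:
  # M11 = J1 + J2 + l^2/4 (m1 + 5 m2 + 4 m2) = 0.015625 + 0.171875
  M <- mass_matrix(c(0, 0), p)
  expect_equal(M[1, 1], 0.1875, tolerance = 1e-12)
  expect_equal(M[1, 2], 0.25 * 0.25 * 0.25 * 3 + 0.25 * 0.25 / 12,
               tolerance = 1e-12)
  expect_equal(M[2, 2], 0.25 * 0.25 * 0.25 + 0.25 * 0.25 / 12,
               tolerance = 1e-12)

  set.seed(1)
  for (i in 1:25) {
    q <- stats::runif(2, -pi, pi)
    M <- mass_matrix(q, p)
    expect_identical(M, t(M))
    # even in q2, and independent of q1
    expect_equal(M, mass_matrix(c(stats::rnorm(1), -q[2]), p))
    expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  }
})

test_that("Coriolis matrix is the Christoffel construction: dM/dt - 2C skew", {
  p <- preset_params("P90")
  set.seed(2)
  eps <- 1e-6
  for (i in 1:1000) {
    q <- stats::runif(2, -pi, pi)
    qd <- stats::runif(2, -5, 5)
    C <- coriolis_matrix(q, qd, p)
    Mdot <- (mass_matrix(q + eps * qd, p) - mass_matrix(q - eps * qd, p)) /
      (2 * eps)
    S <- Mdot - 2 * C
    expect_lt(max(abs(S + t(S))), 1e-8)
  }
  # no velocity, no Coriolis force
  expect_equal(drop(coriolis_matrix(c(0.3, 1.2), c(0, 0), p) %*% c(0, 0)),
               c(0, 0))
  # centrifugal coupling vanishes with the links aligned
  expect_equal(drop(coriolis_matrix(c(0.5, 0), c(1, 0), p) %*% c(1, 0)),
               c(0, 0))
})

test_that("energy is zero at equilibrium and quadratic at rest", {
  p <- preset_params("P90")
  expect_identical(total_energy(pend_state(p$q_eq), p), 0)
  # 1 rad deflection of the first spring (k1 = 5) stores the task energy
  expect_equal(total_energy(pend_state(p$q_eq + c(1, 0)), p), 2.5)
  set.seed(3)
  for (i in 1:20) {
    q <- p$q_eq + stats::rnorm(2)
    e <- total_energy(pend_state(q), p, parts = TRUE)
    expect_identical(unname(e["kinetic"]), 0)
    expect_equal(unname(e["potential"]), potential_energy(q, p))
    expect_gte(total_energy(pend_state(q, stats::rnorm(2)), p), 0)
  }
})

test_that("acceleration field: equilibrium, spring direction, conservation", {
  p <- preset_params("P45")
  expect_equal(accel(pend_state(p$q_eq), p$q_eq[1], p), c(0, 0))
  # a positive motor step pulls the first link toward it
  a <- accel(pend_state(p$q_eq), p$q_eq[1] + 0.5, p)
  expect_gt(a[1], 0)
  # conservative flow preserves total energy: directional derivative of E
  # along the vector field vanishes
  set.seed(4)
  for (i in 1:50) {
    st <- pend_state(p$q_eq + stats::rnorm(2, 0, 0.5), stats::rnorm(2))
    f <- c(st$qdot, accel(st, p$q_eq[1], p))
    h <- 1e-7
    yp <- pend_state(st$q + h * f[1:2], st$qdot + h * f[3:4])
    ym <- pend_state(st$q - h * f[1:2], st$qdot - h * f[3:4])
    dE <- (total_energy(yp, p) - total_energy(ym, p)) / (2 * h)
    expect_lt(abs(dE), 1e-6 * max(1, total_energy(st, p)))
  }
})

test_that("simulation conserves energy on an undriven conservative orbit", {
  p <- preset_params("P0")
  log <- playback_log(p0_orbit(), p, duration = 40)
  E <- energy_series(log, p)
  expect_lt(max(E) - min(E), 1e-6)
  # periodic with the family period (tolerance reflects rounding the
  # period to whole 1 ms samples)
  fs <- attr(log, "fs")
  Tn <- round(p0_orbit()$T * fs)
  expect_lt(max(abs(log$q1[1:(nrow(log) - Tn)] -
                      log$q1[(Tn + 1):nrow(log)])), 5e-3)
})

test_that("damped undriven simulation is passive", {
  p <- preset_params("P90", damped = TRUE)
  log <- simulate(p, controller_hold(p$q_eq[1]), 10,
                  initial = pend_state(p$q_eq + c(0.8, 0.3)))
  E <- energy_series(log, p)
  expect_true(all(diff(E) <= 1e-10))
  expect_lt(E[length(E)], E[1])
})

test_that("trial logs satisfy their invariants", {
  p <- preset_params("P0", damped = TRUE)
  log <- simulate(p, controller_sine(0.2, 0.8), 2, fs = 500)
  expect_equal(nrow(log), 1001)
  expect_equal(diff(log$t), rep(1 / 500, 1000))
  expect_identical(log$tau, p$k1 * (log$theta - log$q1))
  # minimal duration: exactly two samples
  tiny <- simulate(p, controller_hold(0), 1 / 500, fs = 500)
  expect_equal(nrow(tiny), 2)
  expect_error(simulate(p, function(t, s, th) NaN, 0.1), "non-finite")
})

test_that("compiled and R controller paths agree", {
  p <- preset_params("P90", damped = TRUE)
  lc <- simulate(p, controller_sine(0.3, 0.7), 1.5, fs = 200)
  lr <- simulate(p, function(t, s, th) 0.3 * sin(2 * pi * 0.7 * t), 1.5,
                 fs = 200)
  expect_equal(lr$q1, lc$q1, tolerance = 1e-12)
  expect_equal(lr$theta, lc$theta, tolerance = 1e-12)
})
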