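test_that("linearized modes: 1-DOF limit and ordering", {
  # degenerate single pendulum: omega = sqrt(k1 / (m l^2 / 3)) = sqrt(120)
  p <- preset_params("P0")
  p$m2 <- 0; p$k2 <- 0; p$J2 <- 0
  lm <- linear_modes(p)
  expect_length(lm, 1)
  expect_equal(lm[[1]]$omega, sqrt(120), tolerance = 1e-12)

  lm0 <- linear_modes(preset_params("P0"))
  expect_length(lm0, 2)
  expect_gt(lm0[[1]]$omega, 0)
  expect_gt(lm0[[2]]$omega, lm0[[1]]$omega)
  expect_equal(sum(lm0[[1]]$v^2), 1)
})

test_that("low-energy brake orbits approach the linear mode", {
  fam <- p0_family()
  lm <- linear_modes(preset_params("P0"))
  # first continued orbit sits at E = 1e-3 J
  expect_equal(fam$E[1], 1e-3)
  expect_equal(fam$orbits[[1]]$T, 2 * pi / lm[[1]]$omega, tolerance = 1e-3)
})

test_that("brake orbits satisfy their defining invariants", {
  p <- preset_params("P0")
  orb <- p0_orbit()
  expect_lt(abs(orb$residual), 1e-8)
  expect_equal(potential_energy(orb$qA, p), 2.5, tolerance = 1e-9)
  expect_equal(potential_energy(orb$qB, p), 2.5, tolerance = 1e-7)
  # energy constant along the stored path
  Epath <- vapply(seq_len(nrow(orb$path)), function(i)
    total_energy(pend_state(c(orb$path$q1[i], orb$path$q2[i]),
                            c(orb$path$qd1[i], orb$path$qd2[i])), p), 0)
  expect_lt(max(abs(Epath - 2.5)), 1e-7)
  # path starts and ends at qA
  n <- nrow(orb$path)
  expect_equal(c(orb$path$q1[1], orb$path$q2[1]), unname(orb$qA),
               tolerance = 1e-9)
  expect_equal(c(orb$path$q1[n], orb$path$q2[n]), unname(orb$qA),
               tolerance = 1e-5)
})

test_that("time-reversal symmetry: shooting from either turning point", {
  p <- preset_params("P90")
  orb <- p90_orbit()
  shA <- shoot_half_orbit(p, orb$qA)
  expect_true(shA$braking)
  expect_equal(shA$q_end, unname(orb$qB), tolerance = 1e-6)
  expect_equal(2 * shA$t_half, orb$T, tolerance = 1e-8)
  shB <- shoot_half_orbit(p, orb$qB)
  expect_equal(shB$q_end, unname(orb$qA), tolerance = 1e-6)
})

test_that("off-generator starts do not brake cleanly", {
  p <- preset_params("P0")
  orb <- p0_orbit()
  for (dpsi in c(-0.25, 0.2)) {
    q0 <- pendmode:::level_point(p, 2.5, orb$psi + dpsi)
    sh <- shoot_half_orbit(p, q0)
    expect_true(sh$braking)
    expect_gt(abs(sh$residual), 1e-3)
  }
  # a tight time cap signals a non-braking trajectory
  sh <- shoot_half_orbit(p, orb$qA, t_cap = 0.05)
  expect_false(sh$braking)
})

test_that("continuation is step-size robust and orbit lookup consistent", {
  p <- preset_params("P0")
  famA <- continue_mode(p, 1, E_max = 2.5, dE = 0.2)
  famB <- continue_mode(p, 1, E_max = 2.5, dE = 0.1)
  oA <- orbit_at_energy(famA, 2.5)
  oB <- orbit_at_energy(famB, 2.5)
  expect_equal(oA$T, oB$T, tolerance = 1e-6)
  expect_equal(oA$qA, oB$qA, tolerance = 1e-6)
  # energies strictly increasing, turning points continuous
  expect_true(all(diff(famB$E) > 0))
  qA1 <- vapply(famB$orbits, function(o) o$qA[1], 0)
  expect_lt(max(abs(diff(qA1))), 0.2)
  # stored energy returns the stored orbit; out of range errors
  expect_identical(orbit_at_energy(famB, famB$E[3]), famB$orbits[[3]])
  expect_error(orbit_at_energy(famB, 10), "range")
  # frequency-period consistency
  expect_equal(eigenfrequency(famB, 2.5), 1 / oB$T, tolerance = 1e-9)
})

test_that("generator table export round-trips", {
  fam <- p0_family()
  path <- tempfile(fileext = ".csv")
  df <- write_mode_family(fam, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("E", "qA1", "qA2", "qB1", "qB2", "T"))
  expect_equal(back$T, df$T, tolerance = 1e-12)
  unlink(path)
})
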