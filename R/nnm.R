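# Brake-orbit shooting and numerical continuation for the conservative
# pendulum. A brake orbit is a rest-to-rest periodic orbit with exactly two
# turning points; the energy-parametrized family continued from a linear
# eigenmode is the nonlinear normal mode, and the map E -> turning points is
# its generator.

# conservative RHS (motor link fixed at q_eq1, no damping) for deSolve
cons_rhs <- function(t, y, p) {
  q2 <- y[2]; qd1 <- y[3]; qd2 <- y[4]
  c2 <- cos(q2); s2 <- sin(q2); l2 <- p$l1^2
  M11 <- p$J1 + p$J2 + 0.25 * l2 * (p$m1 + 5 * p$m2 + 4 * p$m2 * c2)
  M12 <- p$J2 + 0.25 * l2 * p$m2 * (1 + 2 * c2)
  M22 <- p$J2 + 0.25 * l2 * p$m2
  h <- -0.5 * l2 * p$m2 * s2
  r1 <- -(h * qd2 * qd1 + h * (qd1 + qd2) * qd2) - p$k1 * (y[1] - p$q_eq[1])
  r2 <- h * qd1^2 - p$k2 * (q2 - p$q_eq[2])
  det <- M11 * M22 - M12^2
  list(c(qd1, qd2,
         (M22 * r1 - M12 * r2) / det,
         (M11 * r2 - M12 * r1) / det))
}

#' Linearized modes at the stable equilibrium
#'
#' Solves the generalized eigenproblem of the potential-energy Hessian
#' (here simply `K = diag(k1, k2)`) against `M(q_eq)`. Frequencies are
#' returned sorted ascending with unit-norm mode shapes. The degenerate
#' single-pendulum case (`m2 = k2 = 0`) collapses to the 1-DOF oscillator
#' with `omega = sqrt(k1 / J1)`.
#'
#' @param params a conservative [pendulum_params()] object.
#' @return a list of modes, each `list(omega, v)`.
#' @export
linear_modes <- function(params) {
  if (params$m2 == 0 && params$k2 == 0) {
    # 1-DOF single pendulum: total inertia about the joint is
    # J1 + m1 (l/2)^2 = m1 l^2 / 3
    J <- params$J1 + 0.25 * params$m1 * params$l1^2
    return(list(list(omega = sqrt(params$k1 / J), v = c(1, 0))))
  }
  M <- mass_matrix(params$q_eq, params)
  K <- diag(c(params$k1, params$k2))
  eg <- eigen(solve(M, K))
  if (any(Re(eg$values) <= 0) || any(abs(Im(eg$values)) > 1e-12))
    stop("equilibrium is not stable: potential Hessian not positive definite")
  lam <- Re(eg$values)
  ord <- order(lam)
  lapply(ord, function(i) {
    v <- Re(eg$vectors[, i])
    list(omega = sqrt(lam[i]), v = v / sqrt(sum(v^2)))
  })
}

#' Shoot half a brake orbit from rest
#'
#' Integrates the conservative system from rest at `q_start` until the next
#' near-rest event where the first joint velocity crosses zero. Two guards
#' make the event the swing's actual turning point rather than a spurious
#' crossing: it is armed only once the kinetic energy has first exceeded a
#' quarter of the total energy (a braking swing must pass through the
#' high-speed region), and a crossing is accepted only if the kinetic
#' energy there is below `E/8` (at a turning point almost all energy is
#' potential; mid-swing wiggles of `qd1` carry large `qd2` and are skipped).
#' At a true brake-orbit turning point both joints come to rest
#' simultaneously, so the second joint velocity at the accepted event is
#' the shooting residual.
#'
#' @param params conservative [pendulum_params()].
#' @param q_start starting configuration (rad, length 2), at rest.
#' @param t_cap time cap (s); if no rest event occurs before it, the
#'   trajectory is flagged as non-braking.
#' @param rtol,atol integration tolerances.
#' @return `list(q_end, t_half, residual, braking)`; `braking = FALSE`
#'   signals the cap was reached without a `qd1` zero crossing.
#' @export
shoot_half_orbit <- function(params, q_start, t_cap = NULL,
                             rtol = 1e-12, atol = 1e-12) {
  stopifnot(is_conservative(params))
  lm <- linear_modes(params)
  if (is.null(t_cap)) t_cap <- 20 / lm[[1]]$omega
  y0 <- c(q_start[1], q_start[2], 0, 0)
  E <- potential_energy(q_start, params)
  # phase 1: run until the kinetic energy first reaches E/4
  kin <- function(t, y, p) {
    0.5 * drop(crossprod(y[3:4], mass_matrix(y[1:2], p) %*% y[3:4])) - E / 4
  }
  lead <- deSolve::lsodar(y0, c(0, t_cap), cons_rhs, params,
                          rootfunc = kin, rtol = rtol, atol = atol)
  if (is.null(attr(lead, "troot")) || length(attr(lead, "troot")) == 0) {
    return(list(q_end = NULL, t_half = NA_real_, residual = NA_real_,
                braking = FALSE))
  }
  t1 <- attr(lead, "troot")[1]
  y1 <- lead[nrow(lead), -1]
  # phase 2: armed qd1 = 0 events, accepted only near rest
  for (k in 1:50) {
    out <- deSolve::lsodar(y1, c(t1, t_cap), cons_rhs, params,
                           rootfunc = function(t, y, p) y[3],
                           rtol = rtol, atol = atol)
    troot <- attr(out, "troot")
    if (is.null(troot) || length(troot) == 0) break
    yf <- out[nrow(out), -1]
    kin_ev <- 0.5 * drop(crossprod(yf[3:4],
                                   mass_matrix(yf[1:2], params) %*% yf[3:4]))
    if (kin_ev < E / 8) {
      return(list(q_end = unname(yf[1:2]), t_half = troot[1],
                  residual = unname(yf[4]), braking = TRUE))
    }
    # spurious mid-swing crossing: step off the root and keep integrating
    hop <- deSolve::ode(yf, c(troot[1], troot[1] + 1e-4), cons_rhs, params,
                        method = "lsoda", rtol = rtol, atol = atol)
    t1 <- troot[1] + 1e-4
    y1 <- hop[nrow(hop), -1]
    if (t1 >= t_cap) break
  }
  list(q_end = NULL, t_half = NA_real_, residual = NA_real_,
       braking = FALSE)
}

# The energy constraint V(q) = E leaves one unknown: position along the
# potential level set, an ellipse around q_eq. psi parametrizes it as
# dq = sqrt(2 E) (cos(psi)/sqrt(k1), sin(psi)/sqrt(k2)).
level_point <- function(params, E, psi) {
  params$q_eq + sqrt(2 * E) * c(cos(psi) / sqrt(params$k1),
                                sin(psi) / sqrt(params$k2))
}

level_angle <- function(params, q) {
  dq <- q - params$q_eq
  atan2(sqrt(params$k2) * dq[2], sqrt(params$k1) * dq[1])
}

#' Solve a single brake orbit at a given energy
#'
#' Scalar shooting: the turning point is constrained to the potential level
#' set `V(q) = E` and moved along it by a damped Newton iteration (numeric
#' derivative) until the half-orbit residual from [shoot_half_orbit()]
#' vanishes.
#'
#' @param params conservative [pendulum_params()].
#' @param E orbit energy (J).
#' @param guess starting configuration near the level set (rad, length 2);
#'   only its direction from `q_eq` is used.
#' @param tol residual tolerance (rad/s).
#' @param maxit Newton iteration cap.
#' @return a `brake_orbit`: `list(E, qA, qB, T, psi, residual, path)` with
#'   `path` the orbit sampled at `n_path` points over one period (row 1 and
#'   row `n_path` at `qA`).
#' @param n_path samples per period stored in the orbit path.
#' @export
solve_brake_orbit <- function(params, E, guess, tol = 1e-9, maxit = 40,
                              n_path = 1000) {
  stopifnot(E > 0)
  psi <- level_angle(params, guess)
  res_at <- function(p) {
    sh <- shoot_half_orbit(params, level_point(params, E, p))
    if (!sh$braking) NA_real_ else sh$residual
  }
  noconv <- function(msg, psi, r) {
    stop(structure(class = c("brake_orbit_noconv", "error", "condition"),
                   list(message = msg, call = NULL, psi = psi,
                        residual = r)))
  }
  r <- res_at(psi)
  if (is.na(r)) noconv("non-braking trajectory at the initial guess",
                       psi, NA_real_)
  it <- 0
  dpsi_fd <- 1e-7
  while (abs(r) > tol && it < maxit) {
    rp <- res_at(psi + dpsi_fd)
    if (is.na(rp)) noconv("non-braking trajectory during Newton iteration",
                          psi, r)
    dr <- (rp - r) / dpsi_fd
    step <- -r / dr
    step <- max(min(step, 0.3), -0.3)
    psi_new <- psi + step
    r_new <- res_at(psi_new)
    # fall back to halved steps if the residual does not improve
    k <- 0
    while ((is.na(r_new) || abs(r_new) > abs(r)) && k < 8) {
      step <- step / 2
      psi_new <- psi + step
      r_new <- res_at(psi_new)
      k <- k + 1
    }
    if (is.na(r_new)) noconv("non-braking trajectory during Newton iteration",
                             psi, r)
    psi <- psi_new
    r <- r_new
    it <- it + 1
  }
  if (abs(r) > tol) {
    noconv(sprintf(
      "brake-orbit shooting did not converge (residual %.3g at psi %.6f)",
      r, psi), psi, r)
  }
  qA <- level_point(params, E, psi)
  sh <- shoot_half_orbit(params, qA)
  T <- 2 * sh$t_half
  times <- seq(0, T, length.out = n_path)
  path <- deSolve::ode(c(qA[1], qA[2], 0, 0), times, cons_rhs, params,
                       method = "lsoda", rtol = 1e-11, atol = 1e-12)
  path <- data.frame(t = path[, 1], q1 = path[, 2], q2 = path[, 3],
                     qd1 = path[, 4], qd2 = path[, 5])
  structure(list(E = E, qA = qA, qB = sh$q_end, T = T, psi = psi,
                 residual = r, path = path),
            class = "brake_orbit")
}

#' @export
print.brake_orbit <- function(x, ...) {
  cat(sprintf("brake orbit: E = %.4g J, T = %.6g s (f = %.4g Hz)\n",
              x$E, x$T, 1 / x$T))
  cat(sprintf("  qA = (%.4f, %.4f), qB = (%.4f, %.4f), residual = %.2g\n",
              x$qA[1], x$qA[2], x$qB[1], x$qB[2], x$residual))
  invisible(x)
}

#' Continue a nonlinear normal mode over energy
#'
#' Starts from the linearized mode at a minimal energy and raises the
#' energy in steps, re-solving the brake orbit at each level with a linear
#' predictor for the turning-point position along the level set. Failed
#' steps are retried with halved `dE`; if `dE` falls below `dE_min` the
#' partial family is returned with a warning.
#'
#' @param params conservative [pendulum_params()].
#' @param mode_index 1 (default, the more stable mode used throughout the
#'   task pipeline) or 2.
#' @param E_max continue at least to this energy (J).
#' @param dE nominal energy step (J).
#' @param E_min starting energy (J).
#' @param dE_min smallest step before giving up.
#' @return a `mode_family` with elements `mode_index`, `params`, `orbits`
#'   (list of [solve_brake_orbit()] results ordered by energy), and vectors
#'   `E`, `psi`, `T`.
#' @export
continue_mode <- function(params, mode_index = 1, E_max = 2.6, dE = 0.05,
                          E_min = 1e-3, dE_min = 1e-3) {
  stopifnot(is_conservative(params), mode_index %in% c(1, 2),
            E_max > E_min, dE > 0)
  lm <- linear_modes(params)[[mode_index]]
  guess <- params$q_eq + lm$v * sqrt(2 * E_min /
    sum(c(params$k1, params$k2) * lm$v^2))
  orbits <- list(solve_brake_orbit(params, E_min, guess))
  Es <- E_min
  step <- dE
  repeat {
    E_last <- Es[length(Es)]
    if (E_last >= E_max) break
    E_next <- min(E_last + step, E_max)
    n <- length(Es)
    psi_pred <- if (n >= 2) {
      orbits[[n]]$psi + (orbits[[n]]$psi - orbits[[n - 1]]$psi) *
        (E_next - Es[n]) / (Es[n] - Es[n - 1])
    } else orbits[[n]]$psi
    ok <- tryCatch({
      orb <- solve_brake_orbit(params, E_next,
                               level_point(params, E_next, psi_pred))
      orbits[[n + 1]] <- orb
      Es <- c(Es, E_next)
      TRUE
    }, brake_orbit_noconv = function(e) FALSE)
    if (ok) {
      step <- min(dE, 2 * step)
    } else {
      step <- step / 2
      if (step < dE_min) {
        warning("continuation stalled at E = ", E_last,
                "; returning partial family")
        break
      }
    }
  }
  structure(list(mode_index = mode_index, params = params, orbits = orbits,
                 E = Es, psi = vapply(orbits, `[[`, 0, "psi"),
                 T = vapply(orbits, `[[`, 0, "T")),
            class = "mode_family")
}

#' @export
print.mode_family <- function(x, ...) {
  cat(sprintf("mode %d family: %d brake orbits, E in [%.3g, %.3g] J\n",
              x$mode_index, length(x$E), min(x$E), max(x$E)))
  cat(sprintf("  period %.4g -> %.4g s over the family\n",
              x$T[1], x$T[length(x$T)]))
  invisible(x)
}

#' Brake orbit of a family at an arbitrary energy
#'
#' Re-solves a fresh orbit at energy `E`, seeded by interpolating the
#' family's turning-point positions (not mere interpolation of the orbit).
#' If `E` coincides with a stored orbit's energy, that orbit is returned.
#'
#' @param family a [continue_mode()] family.
#' @param E energy (J), within the family's range.
#' @export
orbit_at_energy <- function(family, E) {
  if (E < min(family$E) || E > max(family$E))
    stop("E = ", E, " outside the family range [",
         min(family$E), ", ", max(family$E), "]")
  hit <- which(abs(family$E - E) < 1e-12)
  if (length(hit) > 0) return(family$orbits[[hit[1]]])
  psi0 <- stats::approx(family$E, family$psi, xout = E)$y
  solve_brake_orbit(family$params, E, level_point(family$params, E, psi0))
}

#' Eigenfrequency of a mode at an energy level
#'
#' The reciprocal of the brake-orbit period, `1 / T(E)`.
#'
#' @inheritParams orbit_at_energy
#' @return frequency (Hz).
#' @export
eigenfrequency <- function(family, E) 1 / orbit_at_energy(family, E)$T

#' Export the generator table of a mode family
#'
#' CSV with one row per continued orbit: `E,qA1,qA2,qB1,qB2,T`.
#'
#' @param family a [continue_mode()] family.
#' @param path CSV file path.
#' @export
write_mode_family <- function(family, path) {
  df <- do.call(rbind, lapply(family$orbits, function(o) {
    data.frame(E = o$E, qA1 = o$qA[1], qA2 = o$qA[2],
               qB1 = o$qB[1], qB2 = o$qB[2], T = o$T)
  }))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Energy whose turning points lie nearest given targets
#'
#' Scans the family's energy range for the orbit whose forward-kinematic
#' turning points minimize the summed distance to the target centers. Used
#' to pick the task-relevant energy level when system parameters are
#' perturbed but the targets stay fixed.
#'
#' @param family a [continue_mode()] family.
#' @param targets a [place_targets()] object.
#' @return `list(E, dist)`.
#' @export
match_energy_to_targets <- function(family, targets) {
  obj <- function(E) {
    orb <- orbit_at_energy(family, E)
    tips <- rbind(forward_kinematics(orb$qA, family$params),
                  forward_kinematics(orb$qB, family$params))
    ctr <- as.matrix(targets$centers[, c("cx", "cy")])
    # match each turning point to its nearest target
    d1 <- sqrt(rowSums((tips - ctr)^2))
    d2 <- sqrt(rowSums((tips - ctr[2:1, , drop = FALSE])^2))
    min(sum(d1), sum(d2))
  }
  opt <- stats::optimize(obj, range(family$E), tol = 1e-4)
  list(E = opt$minimum, dist = opt$objective)
}
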