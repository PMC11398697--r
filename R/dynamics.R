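#' Mass matrix of the compliant double pendulum
#'
#' With each link's mass concentrated at its center and link inertias
#' `J_i = m_i l^2 / 3`, the configuration-dependent mass matrix is
#' \deqn{M(q) = \begin{pmatrix}
#'   J_1 + J_2 + \tfrac{l^2}{4}(m_1 + 5 m_2 + 4 m_2 \cos q_2) &
#'   J_2 + \tfrac{l^2}{4} m_2 (1 + 2\cos q_2) \\
#'   J_2 + \tfrac{l^2}{4} m_2 (1 + 2\cos q_2) &
#'   \tfrac{l^2}{4} m_2 + J_2 \end{pmatrix}}
#' It depends on the configuration only through `cos(q2)` and is symmetric
#' positive definite for all `q`.
#'
#' @param q joint angles (rad, length 2; `q2` relative to link 1).
#' @param params a [pendulum_params()] object.
#' @return a 2x2 numeric matrix.
#' @export
mass_matrix <- function(q, params) {
  l2 <- params$l1^2
  c2 <- cos(q[2])
  m12 <- params$J2 + 0.25 * l2 * params$m2 * (1 + 2 * c2)
  matrix(c(params$J1 + params$J2 +
             0.25 * l2 * (params$m1 + 5 * params$m2 + 4 * params$m2 * c2),
           m12, m12,
           0.25 * l2 * params$m2 + params$J2),
         2, 2)
}

#' Coriolis/centrifugal matrix
#'
#' Derived from the mass matrix via Christoffel symbols of the first kind,
#' the unique construction for which `dM/dt - 2 C` is skew-symmetric. For
#' this system \eqn{C = h \begin{pmatrix} \dot q_2 & \dot q_1 + \dot q_2 \\
#' -\dot q_1 & 0\end{pmatrix}} with \eqn{h = -\tfrac12 l^2 m_2 \sin q_2}.
#'
#' @inheritParams mass_matrix
#' @param qdot joint velocities (rad/s, length 2).
#' @return a 2x2 numeric matrix.
#' @export
coriolis_matrix <- function(q, qdot, params) {
  h <- -0.5 * params$l1^2 * params$m2 * sin(q[2])
  matrix(c(h * qdot[2], -h * qdot[1],
           h * (qdot[1] + qdot[2]), 0), 2, 2)
}

#' Total mechanical energy
#'
#' `E = T + V` with kinetic energy `T = qdot' M(q) qdot / 2` and potential
#' energy `V = (q - q_eq)' K (q - q_eq) / 2`, `K = diag(k1, k2)`. Zero
#' exactly at rest in the spring equilibrium.
#'
#' @param state list with elements `q` and `qdot` (each length 2), as
#'   produced by [pend_state()].
#' @param params a [pendulum_params()] object.
#' @param parts if `TRUE`, return `c(kinetic, potential)` instead of the sum.
#' @return energy in J.
#' @export
total_energy <- function(state, params, parts = FALSE) {
  Tkin <- 0.5 * drop(crossprod(state$qdot, mass_matrix(state$q, params) %*% state$qdot))
  dq <- state$q - params$q_eq
  V <- 0.5 * (params$k1 * dq[1]^2 + params$k2 * dq[2]^2)
  if (parts) c(kinetic = Tkin, potential = V) else Tkin + V
}

#' Potential energy of a configuration
#' @inheritParams mass_matrix
#' @return energy in J.
#' @export
potential_energy <- function(q, params) {
  dq <- q - params$q_eq
  0.5 * (params$k1 * dq[1]^2 + params$k2 * dq[2]^2)
}

#' Construct a pendulum state
#' @param q joint angles (rad, length 2).
#' @param qdot joint velocities (rad/s, length 2); default at rest.
#' @export
pend_state <- function(q, qdot = c(0, 0)) {
  stopifnot(length(q) == 2, length(qdot) == 2, all(is.finite(c(q, qdot))))
  list(q = as.numeric(q), qdot = as.numeric(qdot))
}

#' Joint accelerations under a commanded motor-link angle
#'
#' Solves `M(q) qddot = -C(q, qdot) qdot - k1 (q1 - theta) e1
#' - k2 (q2 - q_eq2) e2 - D qdot`: the motor-link angle `theta` is the
#' moving equilibrium of the first spring, the second spring restores
#' toward its fixed equilibrium, and damping acts on the joint velocities.
#'
#' @inheritParams total_energy
#' @param theta commanded motor-link angle (rad).
#' @return joint accelerations (rad/s^2, length 2).
#' @export
accel <- function(state, theta, params) {
  Cq <- coriolis_matrix(state$q, state$qdot, params) %*% state$qdot
  spring <- c(params$k1 * (state$q[1] - theta),
              params$k2 * (state$q[2] - params$q_eq[2]))
  damp <- c(params$d1, params$d2) * state$qdot
  drop(solve(mass_matrix(state$q, params), -Cq - spring - damp))
}

#' Planar tip position of the second link
#'
#' `p = l1 u(q1) + l2 u(q1 + q2)` with `u(a) = (cos a, sin a)`. The `q1 = 0`
#' axis is the line bisecting the two targets; positive angles point toward
#' the left target.
#'
#' @param q joint angles, either a length-2 vector or an n x 2 matrix.
#' @param params a [pendulum_params()] object.
#' @return planar position(s) in m: a length-2 vector or an n x 2 matrix.
#' @export
forward_kinematics <- function(q, params) {
  if (is.matrix(q)) {
    cbind(x = params$l1 * cos(q[, 1]) + params$l2 * cos(q[, 1] + q[, 2]),
          y = params$l1 * sin(q[, 1]) + params$l2 * sin(q[, 1] + q[, 2]))
  } else {
    c(x = params$l1 * cos(q[1]) + params$l2 * cos(q[1] + q[2]),
      y = params$l1 * sin(q[1]) + params$l2 * sin(q[1] + q[2]))
  }
}

#' Cartesian tip speed along a joint trajectory
#'
#' @param q n x 2 matrix of joint angles.
#' @param qdot n x 2 matrix of joint velocities.
#' @param params a [pendulum_params()] object.
#' @return tip speed (m/s), length n.
#' @export
tip_speed <- function(q, qdot, params) {
  s1 <- q[, 1]
  s12 <- q[, 1] + q[, 2]
  vd12 <- qdot[, 1] + qdot[, 2]
  vx <- -params$l1 * sin(s1) * qdot[, 1] - params$l2 * sin(s12) * vd12
  vy <- params$l1 * cos(s1) * qdot[, 1] + params$l2 * cos(s12) * vd12
  sqrt(vx^2 + vy^2)
}
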