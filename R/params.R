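#' Pendulum parameter set
#'
#' Builds a validated parameter set for the horizontally swinging compliant
#' double pendulum. Both links share the same length `l`, carry their mass
#' distributed along the link (center of mass at `l/2`, central inertia
#' `J_i = m_i * l^2 / 12`, so a single link's total inertia about its joint
#' is the familiar `m l^2 / 3`). Joint damping defaults to the viscous
#' coefficients `d_i = 0.02 * k_i` used in the driven (experimental) system;
#' pass `damped = FALSE` for the conservative system used in mode
#' computation.
#'
#' @param l1,l2 link lengths (m); must be equal.
#' @param m1,m2 link masses (kg).
#' @param k1,k2 joint spring stiffnesses (N m / rad).
#' @param q_eq spring equilibrium angles (rad, length 2; `q2` is relative to
#'   link 1).
#' @param damped logical; if `TRUE` apply `d_i = 0.02 * k_i` viscous joint
#'   friction, else `d_i = 0`.
#' @param d1,d2 explicit damping overrides (N m s / rad).
#' @return an object of class `pendulum_params`.
#' @export
pendulum_params <- function(l1 = 0.5, l2 = 0.5, m1 = 0.5, m2 = 0.25,
                            k1 = 5, k2 = 3, q_eq = c(0, 0),
                            damped = FALSE,
                            d1 = if (damped) 0.02 * k1 else 0,
                            d2 = if (damped) 0.02 * k2 else 0) {
  stopifnot(l1 > 0, l2 > 0, isTRUE(all.equal(l1, l2)),
            m1 > 0, m2 > 0, k1 > 0, k2 > 0,
            length(q_eq) == 2, all(is.finite(q_eq)),
            d1 >= 0, d2 >= 0)
  p <- list(l1 = l1, l2 = l2, m1 = m1, m2 = m2, k1 = k1, k2 = k2,
            q_eq = as.numeric(q_eq), d1 = d1, d2 = d2,
            J1 = m1 * l1^2 / 12, J2 = m2 * l2^2 / 12)
  class(p) <- "pendulum_params"
  p
}

#' Named pendulum presets
#'
#' The configurations studied in the experiments: `P0` (extended,
#' `q_eq = (0, 0)`), `P90` (flexed, `q_eq = (0, pi/2)`), `P45`
#' (`q_eq = (0, pi/4)`), and the increased-mass variants `P0_m2up` /
#' `P90_m2up` with `m2 = 0.625` kg. All use the experimental geometry
#' (`l = 0.5` m, `m1 = 0.5` kg, `m2 = 0.25` kg, `k1 = 5`, `k2 = 3` N m/rad).
#'
#' @param name preset name.
#' @param damped logical, see [pendulum_params()].
#' @param k1 first-spring stiffness override (the wrist-stiffness
#'   what-if analyses re-run presets with `k1 = 4.75` or `k1 = 6`).
#' @return a `pendulum_params` object.
#' @export
preset_params <- function(name = c("P0", "P90", "P45", "P0_m2up", "P90_m2up"),
                          damped = FALSE, k1 = 5) {
  name <- match.arg(name)
  q2e <- switch(name, P0 = 0, P0_m2up = 0, P90 = pi / 2, P90_m2up = pi / 2,
                P45 = pi / 4)
  m2 <- if (grepl("m2up", name)) 0.625 else 0.25
  pendulum_params(m2 = m2, k1 = k1, q_eq = c(0, q2e), damped = damped)
}

#' @export
print.pendulum_params <- function(x, ...) {
  cat(sprintf("compliant double pendulum: l=%g m, m=(%g, %g) kg, k=(%g, %g) N m/rad\n",
              x$l1, x$m1, x$m2, x$k1, x$k2))
  cat(sprintf("  q_eq = (%.4g, %.4g) rad, d = (%g, %g) N m s/rad\n",
              x$q_eq[1], x$q_eq[2], x$d1, x$d2))
  invisible(x)
}

#' Serialize / read a parameter set
#'
#' Flat key-value YAML with keys matching the field names.
#'
#' @param params a `pendulum_params` object.
#' @param path file path.
#' @export
write_params <- function(params, path) {
  yaml::write_yaml(list(l1 = params$l1, l2 = params$l2, m1 = params$m1,
                        m2 = params$m2, k1 = params$k1, k2 = params$k2,
                        q_eq = params$q_eq, d1 = params$d1, d2 = params$d2),
                   path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  pendulum_params(l1 = x$l1, l2 = x$l2, m1 = x$m1, m2 = x$m2,
                  k1 = x$k1, k2 = x$k2, q_eq = unlist(x$q_eq),
                  d1 = x$d1, d2 = x$d2)
}

# flat numeric vector handed to the compiled core
param_vec <- function(params) {
  c(l1 = params$l1, m1 = params$m1, m2 = params$m2,
    k1 = params$k1, k2 = params$k2,
    qe1 = params$q_eq[1], qe2 = params$q_eq[2],
    d1 = params$d1, d2 = params$d2, J1 = params$J1, J2 = params$J2)
}

conservative <- function(params) {
  params$d1 <- 0
  params$d2 <- 0
  params
}

is_conservative <- function(params) params$d1 == 0 && params$d2 == 0
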