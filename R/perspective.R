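#' Perspective-taking state
#'
#' The internal visual frame of reference: three Euler angle biases
#' `mu = (mu_x, mu_y, mu_z)` defining the rotation
#' `R_mu = R_x(mu_x) R_y(mu_y) R_z(mu_z)` applied to every visual motion
#' direction, plus momentum buffers for their gradient-descent adaptation.
#' Angle features are one-dimensional and hence never rotated. The angles
#' are unbounded (no wrapping); convergence is measured by the
#' wrap-safe orientation difference, see [orientation_difference()].
#'
#' @param mu numeric length-3 vector of Euler angles, radians.
#' @param eta_mu learning rate of the angle adaptation (default 0.0075).
#' @param m_mu momentum factor (default 0.85).
#' @return an object of class `perspective_state`.
#' @export
perspective_state <- function(mu = c(0, 0, 0), eta_mu = 0.0075, m_mu = 0.85) {
  mu <- as.numeric(mu)
  if (length(mu) != 3L || any(!is.finite(mu)))
    stop("mu must be three finite angles")
  structure(list(mu = mu, velocity = c(0, 0, 0),
                 eta_mu = eta_mu, m_mu = m_mu),
            class = "perspective_state")
}

#' @export
print.perspective_state <- function(x, ...) {
  cat(sprintf("<perspective_state> mu = (%.4f, %.4f, %.4f) rad\n",
              x$mu[1], x$mu[2], x$mu[3]))
  invisible(x)
}

rot_x <- function(a) matrix(c(1, 0, 0,
                              0, cos(a), -sin(a),
                              0, sin(a), cos(a)), 3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a),
                              0, 1, 0,
                              -sin(a), 0, cos(a)), 3, 3, byrow = TRUE)
rot_z <- function(a) matrix(c(cos(a), -sin(a), 0,
                              sin(a), cos(a), 0,
                              0, 0, 1), 3, 3, byrow = TRUE)

drot_x <- function(a) matrix(c(0, 0, 0,
                               0, -sin(a), -cos(a),
                               0, cos(a), -sin(a)), 3, 3, byrow = TRUE)
drot_y <- function(a) matrix(c(-sin(a), 0, cos(a),
                               0, 0, 0,
                               -cos(a), 0, -sin(a)), 3, 3, byrow = TRUE)
drot_z <- function(a) matrix(c(-sin(a), -cos(a), 0,
                               cos(a), -sin(a), 0,
                               0, 0, 0), 3, 3, byrow = TRUE)

#' Euler rotation matrix of the perspective module
#'
#' `R_mu = R_x(mu_x) R_y(mu_y) R_z(mu_z)` (z-y-x Euler sequence acting on
#' column vectors), with the standard right-handed sign layout of the three
#' axis rotations.
#'
#' @param mu numeric length-3 vector `(mu_x, mu_y, mu_z)` in radians.
#' @return 3x3 rotation matrix.
#' @export
euler_rotation_matrix <- function(mu) {
  rot_x(mu[1]) %*% rot_y(mu[2]) %*% rot_z(mu[3])
}

# partial derivatives dR/dmu_a, a = 1..3, as a list of 3x3 matrices
euler_rotation_grad <- function(mu) {
  Rx <- rot_x(mu[1]); Ry <- rot_y(mu[2]); Rz <- rot_z(mu[3])
  list(drot_x(mu[1]) %*% Ry %*% Rz,
       Rx %*% drot_y(mu[2]) %*% Rz,
       Rx %*% Ry %*% drot_z(mu[3]))
}

#' Rotate visual motion directions by the internal perspective
#'
#' @param directions 3 x N matrix (or length-3N vector) of visual motion
#'   directions, one column per feature.
#' @param state a [perspective_state()] (or a bare 3x3 rotation matrix).
#' @return rotated directions in the same shape as the input.
#' @export
rotate_visual <- function(directions, state) {
  R <- if (is.matrix(state) && all(dim(state) == 3L)) state
       else euler_rotation_matrix(state$mu)
  if (is.matrix(directions)) {
    stopifnot(nrow(directions) == 3L)
    R %*% directions
  } else {
    as.vector(R %*% matrix(directions, nrow = 3L))
  }
}

#' Gradient-descent-with-momentum update of the Euler biases
#'
#' `velocity <- m_mu * velocity - eta_mu * grad; mu <- mu + velocity`.
#'
#' @param state a [perspective_state()].
#' @param grad length-3 gradient of the prediction-error energy with
#'   respect to `(mu_x, mu_y, mu_z)`.
#' @return the updated `perspective_state`.
#' @export
update_angles <- function(state, grad) {
  stopifnot(inherits(state, "perspective_state"))
  grad <- as.numeric(grad)
  if (length(grad) != 3L || any(!is.finite(grad)))
    stop("non-finite perspective gradient (upstream instability)")
  state$velocity <- state$m_mu * state$velocity - state$eta_mu * grad
  state$mu <- state$mu + state$velocity
  state
}
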