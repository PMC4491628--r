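#' Stage I configuration
#'
#' Stage Ia applies a constant input scaling `alpha` and exponential
#' smoothing with update factor `lambda` to every scalar input; Stage Ib
#' turns the smoothed signal into a per-feature velocity and softly
#' normalizes it to a direction of magnitude at most 1. `alpha` decides
#' which raw velocities count as genuine motion: any feature whose raw
#' velocity magnitude reaches `1/alpha` per frame is normalized to unit
#' length, smaller velocities pass through unscaled.
#'
#' @param alpha input scaling (> 0, default 5000).
#' @param lambda smoothing update factor in `[0, 1)` (default 0.95); the
#'   smoothed signal is `lambda * previous + (1 - lambda) * alpha * x`.
#' @return an object of class `stage1_config`.
#' @export
stage1_config <- function(alpha = 5000, lambda = 0.95) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (lambda < 0 || lambda >= 1) stop("lambda must be in [0, 1)")
  structure(list(alpha = alpha, lambda = lambda), class = "stage1_config")
}

#' Initialize Stage I state
#'
#' The smoothing buffer is seeded lazily with the first scaled input, so
#' the first frame has zero velocity instead of a spurious startup
#' transient.
#'
#' @param n_inputs number of scalar inputs (3N + M; default 44).
#' @return an object of class `stage1_state`.
#' @export
stage1_init <- function(n_inputs = 44L) {
  structure(list(n = as.integer(n_inputs), smoothed = NULL,
                 prev_smoothed = NULL), class = "stage1_state")
}

#' Scale and smooth one input frame
#'
#' @param x numeric vector of raw scalar inputs (length `state$n`).
#' @param state a [stage1_init()] state.
#' @param cfg a [stage1_config()].
#' @return list with `smoothed` (the new smoothed vector) and `state` (the
#'   advanced state; `prev_smoothed` holds the previous value for the
#'   velocity difference).
#' @export
scale_and_smooth <- function(x, state, cfg) {
  stopifnot(inherits(state, "stage1_state"), inherits(cfg, "stage1_config"))
  x <- as.numeric(x)
  if (length(x) != state$n)
    stop(sprintf("input length %d does not match state dimension %d",
                 length(x), state$n))
  scaled <- cfg$alpha * x
  s <- if (is.null(state$smoothed)) scaled
       else cfg$lambda * state$smoothed + (1 - cfg$lambda) * scaled
  state$prev_smoothed <- if (is.null(state$smoothed)) s else state$smoothed
  state$smoothed <- s
  list(smoothed = s, state = state)
}

# soft normalization gain: min(1 / ||v||, 1); zero velocity passes through
soft_norm_gain <- function(norms) {
  g <- rep(1, length(norms))
  big <- norms > 1
  g[big] <- 1 / norms[big]
  g
}

#' Per-feature normalized directional velocity
#'
#' Computes the one-step difference of the smoothed signal, grouped into 3D
#' vectors for visual features and scalars for angle features, and applies
#' the soft normalization `v * min(1 / ||v||, 1)`: the output magnitude is
#' `min(||v||, 1)`, so saturated features carry a pure direction while
#' sub-threshold features keep their magnitude (robustness to small motion
#' signals).
#'
#' @param smoothed current smoothed vector (from [scale_and_smooth()]).
#' @param state the Stage I state holding `prev_smoothed`.
#' @param n_visual number of 3D visual features N.
#' @param n_proprio number of scalar angle features M.
#' @return list with `direction` (length 3N + M), `norms` (per-feature
#'   output magnitudes, length N + M).
#' @export
directional_velocity <- function(smoothed, state, n_visual = 12L,
                                 n_proprio = 8L) {
  stopifnot(inherits(state, "stage1_state"))
  if (is.null(state$prev_smoothed))
    stop("at least two frames must be processed before a velocity exists")
  v <- smoothed - state$prev_smoothed
  dir_from_velocity(v, n_visual, n_proprio)
}

dir_from_velocity <- function(v, n_visual, n_proprio) {
  nv <- 3L * n_visual
  vis <- matrix(v[seq_len(nv)], nrow = 3L)
  vnorm <- sqrt(colSums(vis^2))
  pnorm <- abs(v[nv + seq_len(n_proprio)])
  norms <- c(vnorm, pnorm)
  gain <- soft_norm_gain(norms)
  out <- numeric(length(v))
  out[seq_len(nv)] <- as.vector(vis * rep(gain[seq_len(n_visual)], each = 3L))
  out[nv + seq_len(n_proprio)] <- v[nv + seq_len(n_proprio)] *
    gain[n_visual + seq_len(n_proprio)]
  list(direction = out, norms = pmin(norms, 1))
}

#' Stage I over a whole trial, vectorized
#'
#' Runs scaling, smoothing and directional-velocity extraction over all
#' frames of a feature matrix at once. Frame 1 has zero velocity by the
#' first-frame seeding convention.
#'
#' @param X `T x (3N + M)` raw feature matrix (visual triples first).
#' @param cfg a [stage1_config()].
#' @param n_visual,n_proprio feature counts N and M.
#' @return list with `directions` (`T x (3N + M)`), `norms`
#'   (`T x (N + M)` output magnitudes).
#' @export
stage1_directions <- function(X, cfg = stage1_config(), n_visual = 12L,
                              n_proprio = 8L) {
  stopifnot(is.matrix(X), ncol(X) == 3L * n_visual + n_proprio)
  scaled <- cfg$alpha * X
  S <- apply(scaled, 2L, function(col)
    stats::filter(c(col[1], (1 - cfg$lambda) * col[-1]), cfg$lambda,
                  method = "recursive", init = 0))
  V <- rbind(0, diff(S))
  nv <- 3L * n_visual
  Tn <- nrow(X)
  vis <- V[, seq_len(nv), drop = FALSE]
  vnorm2 <- matrix(0, Tn, n_visual)
  for (n in seq_len(n_visual))
    vnorm2[, n] <- rowSums(vis[, 3L * (n - 1L) + 1:3, drop = FALSE]^2)
  vnorm <- sqrt(vnorm2)
  pnorm <- abs(V[, nv + seq_len(n_proprio), drop = FALSE])
  norms <- cbind(vnorm, pnorm)
  gain <- 1 / pmax(norms, 1)
  D <- V
  for (n in seq_len(n_visual))
    D[, 3L * (n - 1L) + 1:3] <- vis[, 3L * (n - 1L) + 1:3] * gain[, n]
  D[, nv + seq_len(n_proprio)] <- V[, nv + seq_len(n_proprio), drop = FALSE] *
    gain[, n_visual + seq_len(n_proprio), drop = FALSE]
  list(directions = D, norms = pmin(norms, 1))
}
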