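#' Top-down prediction error
#'
#' The difference between the winner pattern's instar prediction and the
#' observed population activation, `delta_i = w_ik - o_i`, zeroed on
#' unavailable feature slices. Its squared norm is the energy that the
#' perspective adaptation descends.
#'
#' @param activation population activation vector.
#' @param layer a [pattern_layer()].
#' @param winner winner pattern index (select one with [activate()] or
#'   [step_pattern_layer()] first).
#' @param pop a [population_config()] (needed to mask by feature).
#' @param gains per-feature availability gains (default all 1).
#' @return numeric error vector `delta` of length `pop$total`.
#' @export
prediction_error <- function(activation, layer, winner, pop, gains = NULL) {
  delta <- layer$instar[winner, ] - activation
  if (!is.null(gains)) delta <- delta * population_mask(pop, gains)
  delta
}

#' Backpropagate the prediction error to the Euler biases
#'
#' Chains the error through the population tuning (transpose of the
#' direction-selective weight matrix), the static no-motion neurons
#' (through the slice length `l`), and the rotation Jacobians
#' `dR/dmu_a` applied to the pre-rotation directions. Angle-feature
#' slices are one-dimensional, are never rotated and contribute zero.
#' Because the rotation sits downstream of the Stage I normalization and
#' the tuning set is isotropic, the returned gradient of
#' `E = 0.5 * ||delta||^2` with respect to `mu` is exact.
#'
#' @param delta prediction error from [prediction_error()] (already
#'   masked).
#' @param pop a [population_config()].
#' @param qvis `3 x N` matrix of pre-rotation visual directions for the
#'   current frame (cached from the forward pass).
#' @param mu the current Euler biases (length 3).
#' @return length-3 gradient `dE/d(mu_x, mu_y, mu_z)`.
#' @export
backprop_to_perspective <- function(delta, pop, qvis, mu) {
  if (is.null(qvis)) stop("missing cached forward state (pre-rotation directions)")
  N <- pop$n_visual
  stopifnot(is.matrix(qvis), nrow(qvis) == 3L, ncol(qvis) == N)
  R <- euler_rotation_matrix(mu)
  U <- pop$W3 %*% (R %*% qvis)                     # 26 x N
  vis_dir_idx <- unlist(lapply(seq_len(N), function(n) pop$slices[[n]][1:26]))
  vis_static_idx <- vapply(seq_len(N), function(n) pop$slices[[n]][27L], 1L)
  os <- sqrt(pmax(0, pop$L^2 - colSums(U^2)))
  dU <- -matrix(delta[vis_dir_idx], nrow = 26L)     # dE/dU
  ds <- -delta[vis_static_idx]                      # dE/do_s
  live <- os > 1e-9
  if (any(live))                                    # o_s = sqrt(L^2 - |U|^2)
    dU[, live] <- dU[, live] -
      U[, live, drop = FALSE] * rep(ds[live] / os[live], each = 26L)
  G <- t(pop$W3) %*% dU                             # dE/d(rotated direction)
  dR <- euler_rotation_grad(mu)
  grad <- c(sum(G * (dR[[1]] %*% qvis)),
            sum(G * (dR[[2]] %*% qvis)),
            sum(G * (dR[[3]] %*% qvis)))
  if (any(!is.finite(grad))) stop("non-finite perspective gradient")
  grad
}

#' Orientation difference between derived and encoded views
#'
#' The minimal rotation angle, about an arbitrary axis, between a trained
#' view `P` and the orientation currently derived by the model. The
#' stimulus reaches the model already rotated by the exogenous `R_nu` and
#' is then internally rotated by `R_mu`, so the derived orientation is the
#' composition `R_mu %*% R_nu`; the OD is
#' `acos((tr(t(P) %*% R_mu %*% R_nu) - 1) / 2)`, clipped against rounding.
#' It reaches 0 exactly when the model compensates the exogenous rotation
#' (`R_mu = P %*% t(R_nu)`) and is pi for antipodal orientations.
#'
#' @param P trained-view rotation matrix.
#' @param R_nu exogenous rotation applied to the stimulus.
#' @param R_mu the model's internal rotation.
#' @return orientation difference in radians, in `[0, pi]`.
#' @export
orientation_difference <- function(P, R_nu, R_mu) {
  check_rotation(P); check_rotation(R_nu); check_rotation(R_mu)
  tr <- sum(diag(crossprod(P, R_mu %*% R_nu)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}

#' Winning exclusiveness per pattern
#'
#' For each trained pattern that ever won, the number of winning steps
#' under its preferred labelled condition divided by its total winning
#' steps: 1 means the pattern responded to a single view-dependent
#' movement only; the lower bound is `1/n_conditions` for a pattern
#' winning equally often everywhere.
#'
#' @param record a [winner_record()] with per-step `conditions`, or a
#'   data.frame with columns `winner` and `label`.
#' @return data.frame with `pattern`, `wins`, `exclusiveness`, and the
#'   preferred `condition`.
#' @export
exclusiveness <- function(record) {
  if (inherits(record, "winner_record")) {
    if (is.null(record$conditions))
      stop("winner record has no condition labels")
    df <- data.frame(winner = record$winners,
                     label = record$conditions)
  } else df <- record[, c("winner", "label")]
  tab <- table(df$winner, df$label)
  wins <- rowSums(tab)
  best <- apply(tab, 1L, which.max)
  data.frame(pattern = as.integer(rownames(tab)),
             wins = as.integer(wins),
             exclusiveness = apply(tab, 1L, max) / wins,
             condition = colnames(tab)[best],
             row.names = NULL)
}

#' RMS proprioceptive inference error
#'
#' How well the winner pattern, selected from vision alone, predicts the
#' proprioceptive population activations: the RMS difference between the
#' winner's instar and a ground-truth (full-information) encoding over
#' the proprioceptive slices.
#'
#' @param model a [bm_model()] with a trained layer.
#' @param visual_activation population activation with proprioceptive
#'   gains 0 (vision-only drive).
#' @param truth_activation the shadow full-gain activation of the same
#'   frame.
#' @param winner optional forced winner index; default: selected from the
#'   vision-only activation with learning disabled.
#' @return list with `rms` and `winner`.
#' @export
proprio_inference_error <- function(model, visual_activation,
                                    truth_activation, winner = NULL) {
  pop <- model$pop; ly <- model$layer
  if (is.null(winner))
    winner <- activate(ly, visual_activation, include_free = FALSE)$winner
  pr_idx <- unlist(pop$slices[pop$n_visual + seq_len(pop$n_proprio)])
  rms <- sqrt(mean((ly$instar[winner, pr_idx] - truth_activation[pr_idx])^2))
  list(rms = rms, winner = winner)
}
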