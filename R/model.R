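#' Assemble the three-stage biological-motion model
#'
#' Bundles the feature assignment, Stage I preprocessing, Stage II
#' population coding, the Stage III pattern layer and the perspective
#' state into one model object. Defaults are the reference
#' parameterization: `alpha = 5000`, `lambda = 0.95`, `eta = 0.01`,
#' `eta_mu = 0.0075`, `m_mu = 0.85`, `theta = cos(60 deg)`, `b = 0.034`,
#' `epsilon = 0.001`, `eta_l = 0.6`.
#'
#' @param feature_spec a [body_feature_spec()]; default
#'   [default_feature_spec()].
#' @param alpha,lambda Stage I scaling and smoothing, see
#'   [stage1_config()].
#' @param theta,epsilon,b,eta,eta_l pattern-layer parameters, see
#'   [pattern_layer()].
#' @param eta_mu,m_mu perspective adaptation parameters, see
#'   [perspective_state()].
#' @param seed seed of the pattern layer's owned generator.
#' @return an object of class `bm_model`.
#' @export
bm_model <- function(feature_spec = default_feature_spec(),
                     alpha = 5000, lambda = 0.95,
                     theta = cos(pi / 3), epsilon = 0.001, b = 0.034,
                     eta = 0.01, eta_l = 0.6,
                     eta_mu = 0.0075, m_mu = 0.85, seed = 1L) {
  pop <- population_config(feature_spec$n_visual, feature_spec$n_proprio)
  structure(list(
    spec = feature_spec,
    s1 = stage1_config(alpha, lambda),
    pop = pop,
    layer = pattern_layer(n_input = pop$total, theta = theta,
                          epsilon = epsilon, b = b, eta = eta,
                          eta_l = eta_l, seed = seed),
    pstate = perspective_state(eta_mu = eta_mu, m_mu = m_mu)),
    class = "bm_model")
}

#' @export
print.bm_model <- function(x, ...) {
  cat(sprintf("<bm_model> %d inputs -> %d population neurons -> %d trained patterns (+1 free)\n",
              3L * x$spec$n_visual + x$spec$n_proprio, x$pop$total,
              x$layer$P - 1L))
  invisible(x)
}

#' Run Stages I-II over a whole sequence (fixed perspective)
#'
#' Extracts features, applies Stage I scaling/smoothing and directional
#' velocity, and population-encodes every frame, with the internal
#' rotation held at identity (the training regime: no error-driven frame
#' adaptation). Also returns the pre-rotation directions needed by the
#' adaptive observation loop.
#'
#' @param model a [bm_model()].
#' @param seq a [motion_sequence()] (already view-transformed if desired).
#' @param gains per-feature availability gains, length N + M (default all
#'   1).
#' @return list with `activation` (`T x total` matrix), `directions`
#'   (`T x (3N + M)` Stage I output), `gains`.
#' @export
encode_sequence <- function(model, seq, gains = NULL) {
  N <- model$spec$n_visual; M <- model$spec$n_proprio
  fm <- extract_feature_matrix(seq, model$spec)
  X <- cbind(fm$visual, fm$proprio)
  s1 <- stage1_directions(X, model$s1, N, M)
  if (is.null(gains)) gains <- rep(1, N + M)
  gmat <- matrix(gains, nrow(X), N + M, byrow = TRUE) * fm$available
  list(activation = encode_all(s1$directions, model$pop, gmat),
       directions = s1$directions, gains = gains)
}

#' Train the model on a set of motion trials
#'
#' Drives the pattern layer frame by frame over each trial (in order),
#' repeated `repetitions` times, with learning and recruitment enabled and
#' the visual frame of reference frozen — the embodied self-observation
#' regime. Stage I/II encodings are computed once per trial and reused
#' across repetitions.
#'
#' @param model a [bm_model()].
#' @param trials a [motion_sequence()] or list of them (apply views with
#'   [apply_view()] beforehand).
#' @param repetitions number of passes over the trial list (default 1).
#' @param labels optional per-trial condition labels, recorded with the
#'   winners.
#' @return list with `model`, and `record`: data.frame with `repetition`,
#'   `trial`, `label`, `step`, `winner`.
#' @export
train_model <- function(model, trials, repetitions = 1L, labels = NULL) {
  if (inherits(trials, "motion_sequence")) trials <- list(trials)
  if (is.null(labels)) labels <- paste0("trial", seq_along(trials))
  acts <- lapply(trials, function(s) encode_sequence(model, s)$activation)
  ly <- model$layer
  out <- vector("list", repetitions * length(trials))
  idx <- 0L
  for (rep_i in seq_len(repetitions)) {
    for (tr in seq_along(acts)) {
      A <- acts[[tr]]
      winners <- integer(nrow(A))
      for (f in seq_len(nrow(A)))
        winners[f] <- step_pattern_layer(ly, A[f, ], learn = TRUE)$winner
      idx <- idx + 1L
      out[[idx]] <- data.frame(repetition = rep_i, trial = tr,
                               label = labels[tr], step = seq_len(nrow(A)),
                               winner = winners)
    }
  }
  list(model = model, record = do.call(rbind, out))
}

#' Observe a motion under an unknown view, adapting the perspective
#'
#' The action-observation regime: pattern learning is disabled (the free
#' pattern does not compete), the winner's instar provides the top-down
#' prediction, and the prediction error is backpropagated to the three
#' Euler angle biases, which descend with momentum. The observed sequence
#' is recycled until `steps` frames have been processed.
#'
#' @param model a [bm_model()].
#' @param seq the observed [motion_sequence()] (untransformed).
#' @param view a [view_transform()], 3x3 rotation matrix, or `NULL`
#'   (identity): the exogenous transformation applied to the stimulus.
#' @param steps number of time steps (default one pass over the frames).
#' @param adapt enable perspective adaptation (default TRUE).
#' @param gains per-feature availability gains, length N + M; set the
#'   proprioceptive entries to 0 to drive the model by vision only.
#' @param reset_mu reset the Euler biases to 0 at trial start (default
#'   TRUE).
#' @param od_views named list of trained-view rotation matrices for the
#'   orientation-difference trace (default [canonical_views()]); ignored
#'   unless `view` is a pure rotation.
#' @param od_every record the OD trace every this many steps (default 10).
#' @param track_proprio also report the RMS prediction error on the
#'   proprioceptive population slices against a full-information shadow
#'   encoding (used for feature inference).
#' @return list with `model` (updated perspective state), `trace` (one row
#'   per recorded step: `step`, `winner`, `energy`, per-view `od_*` in
#'   radians, optionally `proprio_rms`), `final_od` (per view, radians),
#'   `winners` (full winner sequence), `R_mu` (final internal rotation).
#' @export
observe <- function(model, seq, view = NULL, steps = NULL, adapt = TRUE,
                    gains = NULL, reset_mu = TRUE,
                    od_views = canonical_views(), od_every = 10L,
                    track_proprio = FALSE) {
  N <- model$spec$n_visual; M <- model$spec$n_proprio
  pop <- model$pop; ly <- model$layer
  L2 <- pop$L^2

  R_nu <- NULL
  if (is.null(view)) {
    obs_seq <- seq
    R_nu <- diag(3)
  } else if (is.matrix(view)) {
    obs_seq <- apply_view(seq, view_transform(view))
    R_nu <- view
  } else {
    obs_seq <- apply_view(seq, view)
    if (!view$project_2d && !view$mirror_horizontal) R_nu <- view$rotation
  }

  enc <- encode_sequence(model, obs_seq, gains = gains)
  if (is.null(gains)) gains <- rep(1, N + M)
  Tn <- nrow(enc$activation)
  if (is.null(steps)) steps <- Tn

  # per-frame precomputation: pre-rotation visual directions, their slice
  # statics (rotation-invariant by tuning isotropy), proprio slices
  D <- enc$directions
  base_act <- enc$activation        # encoding at identity internal rotation
  vis_dir_idx <- unlist(lapply(seq_len(N), function(n) pop$slices[[n]][1:26]))
  shadow <- NULL
  if (track_proprio) {
    pr_idx <- unlist(pop$slices[N + seq_len(M)])
    shadow <- encode_sequence(model, obs_seq)$activation[, pr_idx, drop = FALSE]
  }

  pst <- model$pstate
  if (reset_mu) pst <- perspective_state(eta_mu = pst$eta_mu, m_mu = pst$m_mu)
  gvis <- gains[seq_len(N)]
  mask <- population_mask(pop, gains)

  rec_steps <- unique(c(seq(1L, steps, by = od_every), steps))
  trace <- vector("list", length(rec_steps)); ri <- 0L
  winners <- integer(steps)
  pure_rotation <- !is.null(R_nu) && length(od_views) > 0L

  for (s in seq_len(steps)) {
    f <- ((s - 1L) %% Tn) + 1L
    o <- base_act[f, ]
    R <- euler_rotation_matrix(pst$mu)
    qvis <- matrix(D[f, seq_len(3L * N)], nrow = 3L)    # pre-rotation dirs
    dvis <- R %*% qvis
    U <- pop$W3 %*% dvis                                # 26 x N
    o[vis_dir_idx] <- as.vector(U) * rep(gvis, each = 26L)

    st <- step_pattern_layer(ly, o, learn = FALSE)
    winners[s] <- st$winner
    delta <- (ly$instar[st$winner, ] - o) * mask
    energy <- 0.5 * sum(delta^2)

    if (adapt) {
      grad <- backprop_to_perspective(delta, pop, qvis, pst$mu)
      pst <- update_angles(pst, grad)
    }

    if (s %in% rec_steps) {
      ri <- ri + 1L
      row <- list(step = s, winner = st$winner, energy = energy)
      if (pure_rotation) {
        Rm <- euler_rotation_matrix(pst$mu)
        for (vn in names(od_views))
          row[[paste0("od_", vn)]] <-
            orientation_difference(od_views[[vn]], R_nu, Rm)
      }
      if (track_proprio) {
        pr_idx <- unlist(pop$slices[N + seq_len(M)])
        row$proprio_rms <- sqrt(mean((ly$instar[st$winner, pr_idx] -
                                        shadow[f, ])^2))
      }
      trace[[ri]] <- as.data.frame(row)
    }
  }

  trace <- do.call(rbind, trace[seq_len(ri)])
  Rm <- euler_rotation_matrix(pst$mu)
  final_od <- NULL
  if (pure_rotation)
    final_od <- vapply(od_views, orientation_difference, numeric(1),
                       R_nu = R_nu, R_mu = Rm)
  model$pstate <- pst
  list(model = model, trace = trace, final_od = final_od,
       winners = winners, R_mu = Rm)
}
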