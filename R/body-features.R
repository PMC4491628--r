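#' Body feature specification
#'
#' Defines the static assignment of bodily features to model inputs: N
#' relative visual features, each the difference `p_a - p_b` between two
#' landmark positions, and M proprioceptive angle features, each the angle
#' between two segment vectors `(p_a - p_b)` and `(p_c - p_d)`. The
#' assignment is manual by design; automatic feature selection is out of
#' scope.
#'
#' @param visual_pairs character matrix or data.frame with columns `a`, `b`:
#'   N ordered landmark pairs defining relative positions.
#' @param angle_defs character matrix or data.frame with columns `a`, `b`,
#'   `c`, `d`: M quadruples defining the angle between segments `a-b` and
#'   `c-d` (radians, in `[0, pi]`).
#' @return an object of class `body_feature_spec` with fields
#'   `visual_pairs`, `angle_defs`, `n_visual`, `n_proprio`.
#' @export
body_feature_spec <- function(visual_pairs, angle_defs = NULL) {
  vp <- as.matrix(visual_pairs)
  if (ncol(vp) != 2L || nrow(vp) < 1L)
    stop("visual_pairs must have at least one row and columns (a, b)")
  colnames(vp) <- c("a", "b")
  if (is.null(angle_defs)) {
    ad <- matrix(character(), 0L, 4L)
  } else {
    ad <- as.matrix(angle_defs)
    if (ncol(ad) == 3L)       # triple (a, b, c): angle at b between a-b, c-b
      ad <- cbind(ad[, 1], ad[, 2], ad[, 3], ad[, 2])
    if (ncol(ad) != 4L) stop("angle_defs must have 3 or 4 columns")
  }
  colnames(ad) <- c("a", "b", "c", "d")
  structure(list(visual_pairs = vp, angle_defs = ad,
                 n_visual = nrow(vp), n_proprio = nrow(ad)),
            class = "body_feature_spec")
}

#' @export
print.body_feature_spec <- function(x, ...) {
  cat(sprintf("<body_feature_spec> N = %d relative positions, M = %d angles (%d inputs)\n",
              x$n_visual, x$n_proprio, 3L * x$n_visual + x$n_proprio))
  invisible(x)
}

#' Default feature specification for the synthetic skeleton
#'
#' Twelve limb-segment relative positions and eight joint angles (elbows,
#' shoulders, knees, hips) over the 15-landmark synthetic articulated body,
#' giving the default 44-neuron input layer (12 x 3 + 8).
#'
#' @return a [body_feature_spec()].
#' @export
default_feature_spec <- function() {
  vp <- rbind(
    c("l_hand", "l_elbow"), c("r_hand", "r_elbow"),
    c("l_elbow", "l_shoulder"), c("r_elbow", "r_shoulder"),
    c("l_foot", "l_knee"), c("r_foot", "r_knee"),
    c("l_knee", "l_hip"), c("r_knee", "r_hip"),
    c("l_shoulder", "chest"), c("r_shoulder", "chest"),
    c("head", "chest"), c("chest", "pelvis"))
  ad <- rbind(
    c("l_hand", "l_elbow", "l_shoulder", "l_elbow"),    # elbow flexion L
    c("r_hand", "r_elbow", "r_shoulder", "r_elbow"),    # elbow flexion R
    c("l_elbow", "l_shoulder", "chest", "l_shoulder"),  # shoulder L
    c("r_elbow", "r_shoulder", "chest", "r_shoulder"),  # shoulder R
    c("l_foot", "l_knee", "l_hip", "l_knee"),           # knee flexion L
    c("r_foot", "r_knee", "r_hip", "r_knee"),           # knee flexion R
    c("l_knee", "l_hip", "pelvis", "l_hip"),            # hip L
    c("r_knee", "r_hip", "pelvis", "r_hip"))            # hip R
  body_feature_spec(vp, ad)
}

check_spec_landmarks <- function(spec, seq) {
  used <- unique(c(spec$visual_pairs, spec$angle_defs))
  missing <- setdiff(used, seq$landmark_names)
  if (length(missing))
    stop("feature spec references unknown landmarks: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Extract model input features for one frame
#'
#' Visual feature n is the relative position `p_a(t) - p_b(t)`; angle
#' feature m is `acos` of the normalized inner product of its two segment
#' vectors. A degenerate angle (zero-length segment) is flagged unavailable
#' rather than raising an error.
#'
#' @param seq a [motion_sequence()]
#' @param spec a [body_feature_spec()]
#' @param t frame index
#' @return an object of class `feature_frame` with fields `visual` (N x 3
#'   matrix), `proprio` (length-M vector of radians), `available` (logical,
#'   length N + M, visual first).
#' @export
extract_features <- function(seq, spec, t) {
  fm <- extract_feature_matrix(seq, spec, frames = t)
  structure(list(
    visual = matrix(fm$visual[1, ], ncol = 3L, byrow = TRUE),
    proprio = as.numeric(fm$proprio[1, ]),
    available = as.logical(fm$available[1, ])),
    class = "feature_frame")
}

#' Extract model input features for all (or selected) frames
#'
#' Vectorized companion of [extract_features()]: returns per-frame matrices
#' ready for the Stage I velocity pipeline.
#'
#' @param seq a [motion_sequence()]
#' @param spec a [body_feature_spec()]
#' @param frames integer vector of frame indices (default all)
#' @return list with `visual` (T x 3N, feature-major x/y/z triples),
#'   `proprio` (T x M, radians), `available` (T x (N+M) logical matrix).
#' @export
extract_feature_matrix <- function(seq, spec, frames = NULL) {
  stopifnot(inherits(seq, "motion_sequence"), inherits(spec, "body_feature_spec"))
  check_spec_landmarks(spec, seq)
  if (is.null(frames)) frames <- seq_len(n_frames(seq))
  if (any(frames < 1L | frames > n_frames(seq)))
    stop("frame index out of range")
  N <- spec$n_visual; M <- spec$n_proprio
  Tn <- length(frames)
  P <- seq$frames[frames, , , drop = FALSE]         # T x K x 3
  seg <- function(a, b)                              # T x 3 per feature
    P[, a, , drop = FALSE] - P[, b, , drop = FALSE]

  vis <- matrix(0, Tn, 3L * N)
  for (n in seq_len(N)) {
    d <- seg(spec$visual_pairs[n, 1], spec$visual_pairs[n, 2])
    vis[, 3L * (n - 1L) + 1:3] <- d
  }
  pro <- matrix(0, Tn, max(M, 1L))[, seq_len(M), drop = FALSE]
  avail <- matrix(TRUE, Tn, N + M)
  if (M > 0) for (m in seq_len(M)) {
    u <- matrix(seg(spec$angle_defs[m, 1], spec$angle_defs[m, 2]), Tn, 3L)
    v <- matrix(seg(spec$angle_defs[m, 3], spec$angle_defs[m, 4]), Tn, 3L)
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    bad <- nu == 0 | nv == 0
    cosang <- rowSums(u * v) / (nu * nv)
    cosang[bad] <- NA_real_
    pro[, m] <- acos(pmin(1, pmax(-1, cosang)))
    pro[bad, m] <- 0
    avail[bad, N + m] <- FALSE
  }
  list(visual = vis, proprio = pro, available = avail)
}

#' @export
print.feature_frame <- function(x, ...) {
  cat(sprintf("<feature_frame> %d visual relative positions, %d angles; %d/%d available\n",
              nrow(x$visual), length(x$proprio), sum(x$available),
              length(x$available)))
  invisible(x)
}
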