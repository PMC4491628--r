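#' Gait generator parameters
#'
#' Parameters of the synthetic articulated-gait generator. The generator is
#' a two-level kinematic chain (torso with head, two arms, two legs; 15
#' landmarks) driven by sinusoidal joint angles, emulating periodic whole
#' body motions: about 6 gait cycles per 360 frames at 120 Hz by default.
#' Distinct "subjects" are emulated by per-segment morphology scaling plus
#' white posture-control noise on the joint angles.
#'
#' @param n_cycles_per_360_frames gait cycles per 360 frames; `NULL`
#'   (default) uses the kind-specific value (6 for `gaitA`, 8 for `gaitB`,
#'   5 for `gaitC`).
#' @param joint_amplitudes named list of sinusoid amplitudes in radians
#'   (`hip`, `knee`, `shoulder`, `elbow`); kind-specific defaults are used
#'   for entries not given.
#' @param phase_offsets named list of phase offsets in radians added to the
#'   joint sinusoids.
#' @param morphology_scale named numeric multipliers (> 0) on segment
#'   lengths: `torso`, `head`, `shoulder_w`, `hip_w`, `upper_arm`,
#'   `forearm`, `thigh`, `shank`; or a single number scaling all.
#' @param posture_noise_sd sd of white Gaussian noise added to each joint
#'   angle, radians (default 0.02).
#' @param seed integer seed; identical seeds give identical output.
#' @return an object of class `gait_params`.
#' @export
gait_params <- function(n_cycles_per_360_frames = NULL,
                        joint_amplitudes = list(),
                        phase_offsets = list(),
                        morphology_scale = 1,
                        posture_noise_sd = 0.02,
                        seed = 1L) {
  if (!is.null(n_cycles_per_360_frames) && n_cycles_per_360_frames <= 0)
    stop("cycle count must be positive")
  if (any(unlist(joint_amplitudes) < 0)) stop("amplitudes must be >= 0")
  if (length(morphology_scale) == 1L && is.null(names(morphology_scale)))
    morphology_scale <- stats::setNames(rep(morphology_scale, 8),
      c("torso", "head", "shoulder_w", "hip_w", "upper_arm", "forearm",
        "thigh", "shank"))
  if (any(morphology_scale <= 0)) stop("morphology scales must be > 0")
  if (posture_noise_sd < 0) stop("posture_noise_sd must be >= 0")
  structure(list(n_cycles_per_360_frames = n_cycles_per_360_frames,
                 joint_amplitudes = joint_amplitudes,
                 phase_offsets = phase_offsets,
                 morphology_scale = morphology_scale,
                 posture_noise_sd = posture_noise_sd,
                 seed = as.integer(seed)),
            class = "gait_params")
}

gait_landmarks <- c("pelvis", "chest", "head", "l_shoulder", "r_shoulder",
                    "l_elbow", "r_elbow", "l_hand", "r_hand", "l_hip",
                    "r_hip", "l_knee", "r_knee", "l_foot", "r_foot")

# base segment lengths in meters
gait_segments <- c(torso = 0.50, head = 0.25, shoulder_w = 0.20, hip_w = 0.12,
                   upper_arm = 0.30, forearm = 0.28, thigh = 0.45,
                   shank = 0.43)

# kind-specific gait programs: frequency, amplitude pattern and an
# asymmetric right-arm component (the asymmetry is what disambiguates
# mirrored 2D projections)
gait_kind_defaults <- function(kind) {
  switch(kind,
    gaitA = list(n_cycles = 6, hip = 0.50, knee = 0.60, shoulder = 0.35,
                 elbow_base = 0.40, elbow = 0.15, r_arm_gain = 1.35,
                 r_lat = 0.20, sway = 0.02, bob = 0.03),
    gaitB = list(n_cycles = 8, hip = 0.75, knee = 1.00, shoulder = 0.50,
                 elbow_base = 1.00, elbow = 0.25, r_arm_gain = 1.25,
                 r_lat = 0.12, sway = 0.03, bob = 0.05),
    gaitC = list(n_cycles = 5, hip = 0.25, knee = 0.35, shoulder = 0.15,
                 elbow_base = 0.60, elbow = 0.10, r_arm_gain = 3.0,
                 r_lat = 0.45, sway = 0.02, bob = 0.02),
    stop("unknown motion kind: ", kind))
}

#' Generate a synthetic articulated periodic motion
#'
#' Forward-kinematic gait-like motion of a 15-landmark body. The three
#' kinds differ in cycle frequency, joint-amplitude pattern and the
#' strength of an asymmetric right-arm component (`gaitA`: walk-like,
#' `gaitB`: run-like, `gaitC`: dribble-like with a dominant pumping arm).
#' Output is deterministic given `params$seed`.
#'
#' @param kind one of `"gaitA"`, `"gaitB"`, `"gaitC"`.
#' @param params a [gait_params()].
#' @param frames number of frames T (>= 2).
#' @return a [motion_sequence()] at 120 Hz in meters.
#' @export
generate_motion <- function(kind = c("gaitA", "gaitB", "gaitC"),
                            params = gait_params(), frames = 360L) {
  kind <- match.arg(kind)
  stopifnot(inherits(params, "gait_params"), frames >= 2L)
  kd <- gait_kind_defaults(kind)
  if (!is.null(params$n_cycles_per_360_frames))
    kd$n_cycles <- params$n_cycles_per_360_frames
  amp <- utils::modifyList(
    list(hip = kd$hip, knee = kd$knee, shoulder = kd$shoulder,
         elbow = kd$elbow), params$joint_amplitudes)
  ph <- utils::modifyList(list(hip = 0, knee = -pi / 2, shoulder = 0,
                               elbow = 0), params$phase_offsets)
  sc <- gait_segments
  ms <- params$morphology_scale
  if (length(ms) == 1L) ms <- stats::setNames(rep(ms, length(sc)), names(sc))
  sc[names(ms)] <- sc[names(ms)] * ms

  tt <- seq_len(frames) - 1L
  w <- 2 * pi * kd$n_cycles / 360
  # posture-control noise is low-frequency: AR(1) with ~0.25 s time
  # constant at 120 Hz, stationary sd = posture_noise_sd
  noise <- with_seed(params$seed, {
    rho <- exp(-1 / 30)
    e <- matrix(stats::rnorm(frames * 8L), frames, 8L)
    n <- apply(e, 2L, function(col)
      stats::filter(col * sqrt(1 - rho^2), rho, method = "recursive"))
    matrix(n, frames, 8L) * params$posture_noise_sd
  })
  s <- function(a, phase, col) a * sin(w * tt + phase) + noise[, col]
  # leg flexion antiphase L/R; knees lag hips by a quarter cycle
  hipL <- s(amp$hip, ph$hip, 1);            hipR <- s(amp$hip, ph$hip + pi, 2)
  kneL <- abs(s(amp$knee, ph$knee, 3));     kneR <- abs(s(amp$knee, ph$knee + pi, 4))
  # arms swing antiphase to their ipsilateral leg
  shoL <- s(amp$shoulder, ph$shoulder + pi, 5)
  shoR <- s(amp$shoulder * kd$r_arm_gain, ph$shoulder, 6)
  elbL <- kd$elbow_base + s(amp$elbow, ph$elbow, 7)
  elbR <- kd$elbow_base + s(amp$elbow * kd$r_arm_gain, ph$elbow + pi / 2, 8)
  # right-arm lateral (out-of-sagittal) component: pure asymmetry
  latR <- kd$r_lat * sin(w * tt + pi / 3)

  out <- array(0, dim = c(frames, length(gait_landmarks), 3L))
  dimnames(out) <- list(NULL, gait_landmarks, c("x", "y", "z"))
  # bob/sway/twist amplitudes scale with their segment so that uniform
  # morphology scaling is a global similarity (angles exactly invariant)
  tsc <- sc["torso"] / gait_segments["torso"]
  wsc <- sc["shoulder_w"] / gait_segments["shoulder_w"]
  pelvis <- cbind(tsc * kd$sway * sin(w * tt),
                  1.0 + tsc * kd$bob * sin(2 * w * tt), 0)
  chest <- pelvis + cbind(0.3 * tsc * kd$sway * sin(w * tt + pi),
                          rep(sc["torso"], frames), 0)
  head <- chest + cbind(0, rep(sc["head"], frames), 0)
  twist <- 0.05 * wsc * sin(w * tt)         # torso twist: shoulders counter z
  shoulderL <- chest + cbind(-sc["shoulder_w"], 0, +twist)
  shoulderR <- chest + cbind(+sc["shoulder_w"], 0, -twist)
  hipLp <- pelvis + cbind(rep(-sc["hip_w"], frames), 0, 0)
  hipRp <- pelvis + cbind(rep(+sc["hip_w"], frames), 0, 0)

  swing_dir <- function(theta, lat = 0) {
    cl <- cos(lat)
    cbind(sin(lat), -cos(theta) * cl, sin(theta) * cl)
  }
  elbowL <- shoulderL + sc["upper_arm"] * swing_dir(shoL)
  elbowR <- shoulderR + sc["upper_arm"] * swing_dir(shoR, latR)
  handL <- elbowL + sc["forearm"] * swing_dir(shoL + elbL)
  handR <- elbowR + sc["forearm"] * swing_dir(shoR + elbR, latR)
  kneeL <- hipLp + sc["thigh"] * swing_dir(hipL)
  kneeR <- hipRp + sc["thigh"] * swing_dir(hipR)
  footL <- kneeL + sc["shank"] * swing_dir(hipL - kneL)
  footR <- kneeR + sc["shank"] * swing_dir(hipR - kneR)

  pos <- list(pelvis = pelvis, chest = chest, head = head,
              l_shoulder = shoulderL, r_shoulder = shoulderR,
              l_elbow = elbowL, r_elbow = elbowR,
              l_hand = handL, r_hand = handR,
              l_hip = hipLp, r_hip = hipRp,
              l_knee = kneeL, r_knee = kneeR,
              l_foot = footL, r_foot = footR)
  for (nm in gait_landmarks) out[, nm, ] <- pos[[nm]]
  motion_sequence(out, landmark_names = gait_landmarks, sample_rate = 120)
}

## ------------------------------------------------------------- views ------

#' View transformation
#'
#' A rigid view change: a proper rotation, optionally followed by a parallel
#' 2D projection (depth coordinate z set to 0) and/or horizontal mirroring
#' (x negated). Projection and mirroring commute.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det 1 within
#'   1e-9).
#' @param project_2d set the depth (z) coordinate to 0.
#' @param mirror_horizontal negate the horizontal (x) coordinate.
#' @return an object of class `view_transform`.
#' @export
view_transform <- function(rotation = diag(3), project_2d = FALSE,
                           mirror_horizontal = FALSE) {
  check_rotation(rotation)
  structure(list(rotation = rotation, project_2d = isTRUE(project_2d),
                 mirror_horizontal = isTRUE(mirror_horizontal)),
            class = "view_transform")
}

check_rotation <- function(R, tol = 1e-9) {
  if (!is.matrix(R) || !all(dim(R) == 3L))
    stop("rotation must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation matrix is not orthonormal with det 1")
  invisible(TRUE)
}

#' Apply a view transformation to a motion sequence
#'
#' Every landmark position is rotated by the view's rotation matrix; then,
#' if requested, the depth coordinate is zeroed (parallel projection) and
#' the horizontal coordinate negated (mirroring).
#'
#' @param seq a [motion_sequence()]
#' @param view a [view_transform()] or a bare 3x3 rotation matrix
#' @return the transformed [motion_sequence()].
#' @export
apply_view <- function(seq, view) {
  stopifnot(inherits(seq, "motion_sequence"))
  if (is.matrix(view)) view <- view_transform(view)
  stopifnot(inherits(view, "view_transform"))
  m <- flatten_frames(seq)                       # T x 3K
  Tn <- nrow(m); K <- ncol(m) %/% 3L
  pts <- matrix(t(m), nrow = 3L)                 # 3 x (K*T)
  pts <- view$rotation %*% pts
  if (view$project_2d) pts[3L, ] <- 0
  if (view$mirror_horizontal) pts[1L, ] <- -pts[1L, ]
  out <- t(matrix(pts, nrow = 3L * K))           # back to T x 3K
  motion_sequence(unflatten_frames(out, K), landmark_names = seq$landmark_names,
                  sample_rate = seq$sample_rate, up_axis = seq$up_axis)
}

#' Haar-uniform random rotation matrix
#'
#' Samples a rotation uniformly from SO(3) via a normalized Gaussian
#' quaternion. With a seed the draw is reproducible and the global RNG
#' state is left untouched; without one the current RNG stream is used.
#'
#' @param seed optional integer seed.
#' @return 3x3 rotation matrix (orthonormal, det 1).
#' @export
random_rotation <- function(seed = NULL) {
  q <- if (is.null(seed)) stats::rnorm(4) else with_seed(seed, stats::rnorm(4))
  q <- q / sqrt(sum(q^2))
  quat_to_matrix(q)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Rotation about the vertical (y) axis
#' @param angle radians
#' @return 3x3 rotation matrix
#' @export
rotation_about_vertical <- function(angle) {
  matrix(c(cos(angle), 0, sin(angle),
           0, 1, 0,
           -sin(angle), 0, cos(angle)), 3, 3, byrow = TRUE)
}

#' The four canonical training views
#'
#' Egocentric, right, facing and left views: rotations about the vertical
#' axis by 0, 90, 180 and 270 degrees, dividing the orientation space
#' consistently about the vertical.
#'
#' @return named list of four 3x3 rotation matrices.
#' @export
canonical_views <- function() {
  list(egocentric = rotation_about_vertical(0),
       right = rotation_about_vertical(pi / 2),
       facing = rotation_about_vertical(pi),
       left = rotation_about_vertical(3 * pi / 2))
}

# evaluate expr under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
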