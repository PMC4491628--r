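#' Experiment run configuration
#'
#' All reference network parameters with their default values, plus the
#' trial schedule knobs used by the experiment drivers. Any override is
#' recorded in the returned object (and thus in each experiment's
#' manifest).
#'
#' @param alpha,lambda,eta,eta_mu,m_mu,theta,b,epsilon,eta_l network
#'   parameters (defaults: 5000, 0.95, 0.01, 0.0075, 0.85, cos 60 deg,
#'   0.034, 0.001, 0.6).
#' @param interval_frames frames per trial interval (default 360).
#' @param repetitions training repetitions (default 20).
#' @param n_test_runs number of randomly rotated test runs in the
#'   perspective experiment (default 50; the full-scale study used 500).
#' @param test_steps adaptation steps per test run (default 5000).
#' @param success_deg orientation-difference success criterion in degrees
#'   (default 35).
#' @param posture_noise_sd posture-control noise, radians (default 0.02).
#' @param seed master seed; every stochastic component derives its own
#'   stream from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(alpha = 5000, lambda = 0.95, eta = 0.01,
                       eta_mu = 0.0075, m_mu = 0.85, theta = cos(pi / 3),
                       b = 0.034, epsilon = 0.001, eta_l = 0.6,
                       interval_frames = 360L, repetitions = 20L,
                       n_test_runs = 50L, test_steps = 5000L,
                       success_deg = 35, posture_noise_sd = 0.02,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

cfg_model <- function(cfg) {
  bm_model(alpha = cfg$alpha, lambda = cfg$lambda, theta = cfg$theta,
           epsilon = cfg$epsilon, b = cfg$b, eta = cfg$eta,
           eta_l = cfg$eta_l, eta_mu = cfg$eta_mu, m_mu = cfg$m_mu,
           seed = sub_seed(cfg$seed, 777L))
}

# deterministic sub-stream seeds below 2^31 (double arithmetic: no
# integer overflow for any input seed)
sub_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 10007 + as.numeric(k)) %% 2147483587)

# a "subject": morphology scaling plus posture noise, derived from a seed
subject_params <- function(cfg, k) {
  ms <- with_seed(sub_seed(cfg$seed, 500L + k),
                  exp(stats::rnorm(8, sd = 0.08)))
  names(ms) <- c("torso", "head", "shoulder_w", "hip_w", "upper_arm",
                 "forearm", "thigh", "shank")
  gait_params(morphology_scale = ms,
              posture_noise_sd = cfg$posture_noise_sd,
              seed = sub_seed(cfg$seed, 900L + k))
}

gait_kinds <- c("gaitA", "gaitB", "gaitC")

# the 12 training conditions: 3 motion kinds x 4 canonical views
training_trials <- function(cfg, subject = 1L) {
  views <- canonical_views()
  trials <- list(); labels <- character()
  for (kind in gait_kinds) {
    base <- generate_motion(kind, subject_params(cfg, subject),
                            frames = cfg$interval_frames)
    for (vn in names(views)) {
      trials[[length(trials) + 1L]] <- apply_view(base, views[[vn]])
      labels <- c(labels, paste(kind, vn, sep = "."))
    }
  }
  list(trials = trials, labels = labels)
}

#' Single-motion pattern learning and free-run simulation
#'
#' Trains the model on one cyclic synthetic motion for `repetitions`
#' intervals, reports the per-interval winner histograms and the
#' repetition at which they converge, then clamps all population gains to
#' zero and free-runs the pattern layer for the same number of intervals,
#' comparing the noise-driven winner cycle to the stimulus-driven one.
#'
#' @param cfg a [run_config()].
#' @param kind motion kind (default `"gaitA"`).
#' @return list with `model`, `histograms` (repetition x pattern matrix),
#'   `converged_at` (first repetition whose histogram L1-change drops
#'   below 5 percent of the interval length), `n_patterns`,
#'   `pattern_growth` (trained patterns after each repetition),
#'   `trained_cycle` and `free_cycle` (distinct-winner orders), and
#'   `free_histogram`.
#' @export
exp_single_motion <- function(cfg = run_config(), kind = "gaitA") {
  model <- cfg_model(cfg)
  trial <- generate_motion(kind, subject_params(cfg, 1L),
                           frames = cfg$interval_frames)
  growth <- integer(cfg$repetitions)
  hists <- list()
  rec <- NULL
  acts <- encode_sequence(model, trial)$activation
  ly <- model$layer
  for (rep_i in seq_len(cfg$repetitions)) {
    winners <- integer(nrow(acts))
    for (f in seq_len(nrow(acts)))
      winners[f] <- step_pattern_layer(ly, acts[f, ], learn = TRUE)$winner
    growth[rep_i] <- ly$P - 1L
    hists[[rep_i]] <- winners
  }
  nP <- ly$P - 1L
  H <- t(vapply(hists, tabulate, integer(nP), nbins = nP))
  dH <- rowSums(abs(H[-1L, , drop = FALSE] - H[-nrow(H), , drop = FALSE]))
  # stable convergence: every later repetition changes by < 5% of the
  # interval length
  unstable <- which(dH >= 0.05 * cfg$interval_frames)
  converged_at <- if (length(unstable) == nrow(H) - 1L) NA_integer_ else
    if (length(unstable)) max(unstable) + 1L else 2L

  fr <- free_run(ly, cfg$repetitions * cfg$interval_frames)
  list(model = model,
       histograms = H,
       converged_at = converged_at,
       n_patterns = nP,
       pattern_growth = growth,
       trained_cycle = distinct_cycle(hists[[cfg$repetitions]]),
       free_cycle = distinct_cycle(fr$winners),
       free_histogram = fr$histogram,
       trained_winners = hists,
       free_winners = fr$winners,
       config = cfg)
}

# order of distinct winners (run-length collapsed)
distinct_cycle <- function(winners) rle(winners)$values

#' Winner transition table
#'
#' Collapses a winner sequence to its distinct-winner runs and counts the
#' transitions `k -> j`, normalized to per-source shares.
#'
#' @param winners integer winner sequence.
#' @return matrix of transition shares (rows: from, columns: to).
#' @export
transition_table <- function(winners) {
  v <- rle(winners)$values
  if (length(v) < 2L) return(matrix(numeric(), 0L, 0L))
  lev <- sort(unique(winners))
  tab <- table(factor(v[-length(v)], levels = lev),
               factor(v[-1L], levels = lev))
  sweep(unclass(tab), 1L, pmax(rowSums(tab), 1L), "/")
}

# does the free-run successor structure reproduce the trained cycle?
# every pattern that (a) carries a non-negligible share of steps in both
# records and (b) has an unambiguous stimulus-driven successor must have
# its free-run modal successor equal to that successor. Hub patterns with
# context-dependent successors are excluded: first-order lateral weights
# encode ambiguous sequences probabilistically, not by context.
same_cyclic_order <- function(trained, free, min_share = 0.05,
                              min_dominance = 0.6) {
  tt <- transition_table(trained); tf <- transition_table(free)
  P <- max(trained, free)
  sh_t <- tabulate(trained, P) / length(trained)
  sh_f <- tabulate(free, P) / length(free)
  common <- intersect(rownames(tt), rownames(tf))
  common <- common[sh_t[as.integer(common)] >= min_share &
                     sh_f[as.integer(common)] >= min_share]
  common <- common[apply(tt[common, , drop = FALSE], 1L, max) >= min_dominance]
  if (!length(common)) return(FALSE)
  ok <- vapply(common, function(k) {
    succ_f <- colnames(tf)[which.max(tf[k, ])]
    succ_t <- colnames(tt)[which.max(tt[k, ])]
    identical(succ_f, succ_t)
  }, logical(1))
  all(ok)
}

#' Multiple movements and perspectives: exclusiveness analysis
#'
#' Trains the 12 view-dependent conditions (3 synthetic motion kinds x 4
#' canonical views) consecutively for `repetitions` passes, then drives
#' the model with held-out "subjects" of the same conditions (learning
#' disabled) and scores each trained pattern's winning exclusiveness.
#'
#' @param cfg a [run_config()].
#' @return list with `model`, `n_patterns`, `exclusiveness` (data.frame,
#'   see [exclusiveness()]), and the test `record`.
#' @export
exp_multiview <- function(cfg = run_config()) {
  model <- cfg_model(cfg)
  tt <- training_trials(cfg, subject = 1L)
  tr <- train_model(model, tt$trials, repetitions = cfg$repetitions,
                    labels = tt$labels)
  te <- training_trials(cfg, subject = 2L)
  recs <- list()
  for (i in seq_along(te$trials)) {
    ob <- observe(model, te$trials[[i]], view = NULL, adapt = FALSE,
                  od_views = NULL, od_every = cfg$interval_frames)
    recs[[i]] <- data.frame(winner = ob$winners, label = te$labels[i])
  }
  record <- do.call(rbind, recs)
  list(model = model, n_patterns = model$layer$P - 1L,
       exclusiveness = exclusiveness(record), record = record,
       train_record = tr$record, config = cfg)
}

#' Perspective-taking under random orientations
#'
#' Trains the 12 conditions once, then runs `n_test_runs` observation
#' episodes: each applies an independent Haar-uniform rotation to a
#' held-out subject of one of the motion kinds and adapts the Euler
#' biases for `test_steps` steps. A run succeeds when the orientation
#' difference to at least one trained view falls below `success_deg`
#' degrees.
#'
#' @param cfg a [run_config()].
#' @param model optionally a pre-trained model (from [exp_multiview()])
#'   to reuse; default trains afresh.
#' @return list with `success_rate` (in percent), `runs` (per-run
#'   data.frame: kind, min/final OD in degrees, success, reached view),
#'   and `model`.
#' @export
exp_perspective <- function(cfg = run_config(), model = NULL) {
  if (is.null(model)) {
    model <- cfg_model(cfg)
    tt <- training_trials(cfg, subject = 1L)
    train_model(model, tt$trials, repetitions = cfg$repetitions,
                labels = tt$labels)
  }
  views <- canonical_views()
  runs <- vector("list", cfg$n_test_runs)
  for (i in seq_len(cfg$n_test_runs)) {
    kind <- gait_kinds[(i - 1L) %% 3L + 1L]
    subj <- subject_params(cfg, 10L + i)
    test_seq <- generate_motion(kind, subj, frames = cfg$interval_frames)
    R_nu <- random_rotation(sub_seed(cfg$seed, 3000L + i))
    ob <- observe(model, test_seq, view = R_nu, steps = cfg$test_steps,
                  adapt = TRUE, od_views = views, od_every = 50L)
    od_deg <- ob$final_od * 180 / pi
    runs[[i]] <- data.frame(run = i, kind = kind,
                            od_final = min(od_deg),
                            view = names(views)[which.min(od_deg)],
                            success = min(od_deg) < cfg$success_deg)
  }
  runs <- do.call(rbind, runs)
  list(success_rate = 100 * mean(runs$success), runs = runs,
       model = model, config = cfg)
}

#' Bistable perception of projected walkers
#'
#' Trains the egocentric and facing views of the asymmetric walk-like
#' motion with full visuo-proprioceptive drive (self-observation), then
#' presents the same data again as a point-light observation — vision
#' only, since watching another walker yields no proprioceptive input —
#' in 3D, as a parallel 2D projection, and as a mirrored 2D projection.
#' Recognition is scored by which view's pattern group (labelled from the
#' training record) wins the majority of steps: the asymmetric arm breaks
#' the 2D ambiguity, and mirroring a projection flips the recognized view.
#'
#' @param cfg a [run_config()].
#' @return list with `table` (one row per test setup: `shown`,
#'   `projected`, `mirrored`, `recognized`, `margin`), `groups` (pattern
#'   to view-group assignment), and `model`.
#' @export
exp_bistable <- function(cfg = run_config()) {
  model <- cfg_model(cfg)
  base <- generate_motion("gaitA", subject_params(cfg, 1L),
                          frames = cfg$interval_frames)
  views <- canonical_views()[c("egocentric", "facing")]
  trials <- lapply(views, function(v) apply_view(base, v))
  tr <- train_model(model, trials, repetitions = cfg$repetitions,
                    labels = names(views))
  # label each trained pattern with the view it responded to while
  # training (early transient repetitions excluded)
  rec <- tr$record[tr$record$repetition > 2L, ]
  groups <- exclusiveness(rec[, c("winner", "label")])
  g_vis <- c(rep(1, model$spec$n_visual), rep(0, model$spec$n_proprio))
  setups <- expand.grid(shown = names(views), projected = c(FALSE, TRUE),
                        mirrored = c(FALSE, TRUE),
                        stringsAsFactors = FALSE)
  setups <- setups[!(setups$mirrored & !setups$projected), ]   # S1..S6
  rows <- lapply(seq_len(nrow(setups)), function(i) {
    s <- setups[i, ]
    vt <- view_transform(views[[s$shown]], project_2d = s$projected,
                         mirror_horizontal = s$mirrored)
    ob <- observe(model, base, view = vt, adapt = FALSE, od_views = NULL,
                  gains = g_vis)
    hits <- groups$condition[match(ob$winners, groups$pattern)]
    tab <- table(factor(hits, levels = names(views)))
    data.frame(s, recognized = names(views)[which.max(tab)],
               margin = as.numeric(max(tab) / sum(tab)))
  })
  list(table = do.call(rbind, rows), groups = groups, model = model,
       config = cfg)
}

#' Inferring proprioception from vision under an unknown view
#'
#' Trains the egocentric walk-like motion with full visuo-proprioceptive
#' drive, then observes a held-out subject rotated 180 degrees about the
#' walking direction followed by 45 degrees about the vertical axis — a
#' near-worst-case orientation — and tracks the RMS prediction error on
#' the proprioceptive population slices while the perspective adapts:
#' once with proprioceptive drive, once driven by vision only, and once
#' as a vision-only control with adaptation frozen.
#'
#' @param cfg a [run_config()].
#' @param steps adaptation steps per condition (default
#'   `cfg$test_steps`).
#' @return list with `traces` (named list of per-step data.frames),
#'   `final_rms` (named vector: `full`, `vision_only`, `frozen`), and
#'   `model`.
#' @export
exp_feature_inference <- function(cfg = run_config(), steps = cfg$test_steps) {
  model <- cfg_model(cfg)
  base <- generate_motion("gaitA", subject_params(cfg, 1L),
                          frames = cfg$interval_frames)
  train_model(model, base, repetitions = cfg$repetitions)
  test <- generate_motion("gaitA", subject_params(cfg, 2L),
                          frames = cfg$interval_frames)
  R_nu <- rotation_about_vertical(pi / 4) %*% rot_z(pi)
  N <- model$spec$n_visual; M <- model$spec$n_proprio
  g_full <- rep(1, N + M)
  g_vis <- c(rep(1, N), rep(0, M))
  run <- function(gains, adapt) {
    observe(model, test, view = R_nu, steps = steps, adapt = adapt,
            gains = gains, od_every = 25L, track_proprio = TRUE)
  }
  obs <- list(full = run(g_full, TRUE),
              vision_only = run(g_vis, TRUE),
              frozen = run(g_vis, FALSE))
  tail_rms <- vapply(obs, function(o) {
    tr <- o$trace
    mean(utils::tail(tr$proprio_rms, max(3L, nrow(tr) %/% 10L)))
  }, numeric(1))
  list(traces = lapply(obs, `[[`, "trace"), final_rms = tail_rms,
       model = model, config = cfg)
}
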