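make_seq <- function(coords) {
  # coords: list of K x 3 matrices (frames)
  a <- array(0, dim = c(length(coords), nrow(coords[[1]]), 3L))
  for (t in seq_along(coords)) a[t, , ] <- coords[[t]]
  motion_sequence(a, landmark_names = paste0("L", seq_len(nrow(coords[[1]]))))
}

test_that("relative positions and angles follow their definitions", {
  # L1 at origin, L2 on x, L3 on y: segment L2-L1 orthogonal to L3-L1
  s <- make_seq(list(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))))
  spec <- body_feature_spec(rbind(c("L2", "L1"), c("L1", "L1")),
                            rbind(c("L2", "L1", "L3", "L1")))
  ff <- extract_features(s, spec, 1)
  expect_equal(ff$visual[1, ], c(1, 0, 0))
  expect_equal(ff$visual[2, ], c(0, 0, 0))   # coincident landmarks
  expect_equal(ff$proprio[1], pi / 2)        # orthogonal segments
  expect_true(all(ff$available))
})

test_that("degenerate angles are flagged unavailable, not errors", {
  s <- make_seq(list(rbind(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0))))
  spec <- body_feature_spec(rbind(c("L2", "L1")),
                            rbind(c("L2", "L1", "L3", "L1")))
  ff <- extract_features(s, spec, 1)
  expect_false(ff$available[2])
  expect_equal(ff$proprio[1], 0)
})

test_that("angles match an independent atan2 oracle on random configurations", {
  set.seed(101)
  spec <- body_feature_spec(rbind(c("L1", "L2")),
                            rbind(c("L1", "L2", "L3", "L4")))
  for (i in 1:100) {
    P <- matrix(rnorm(12), 4, 3)
    s <- make_seq(list(P))
    ff <- extract_features(s, spec, 1)
    u <- P[1, ] - P[2, ]; v <- P[3, ] - P[4, ]
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    oracle <- atan2(sqrt(sum(cr^2)), sum(u * v))
    expect_equal(ff$proprio[1], oracle, tolerance = 1e-12)
    expect_true(ff$proprio[1] >= 0 && ff$proprio[1] <= pi)
  }
})

test_that("visual features are translation invariant, angles similarity invariant", {
  set.seed(7)
  base <- generate_motion("gaitB", gait_params(seed = 2), frames = 30)
  spec <- default_feature_spec()
  fm <- extract_feature_matrix(base, spec)
  for (i in 1:5) {
    shift <- rnorm(3, sd = 10)
    moved <- base
    moved$frames <- sweep(base$frames, 3L, -shift)   # global translation
    fmt <- extract_feature_matrix(moved, spec)
    expect_equal(fmt$visual, fm$visual, tolerance = 1e-9)
    expect_equal(fmt$proprio, fm$proprio, tolerance = 1e-9)
    # rotation + uniform scaling leave angles unchanged
    R <- random_rotation(seed = i)
    rs <- apply_view(base, R)
    rs$frames <- rs$frames * 3.7
    fmr <- extract_feature_matrix(rs, spec)
    expect_equal(fmr$proprio, fm$proprio, tolerance = 1e-9)
  }
})

test_that("per-frame extraction is deterministic and matches the batch path", {
  s <- generate_motion("gaitA", gait_params(seed = 3), frames = 20)
  spec <- default_feature_spec()
  fm <- extract_feature_matrix(s, spec)
  for (t in c(1, 7, 20)) {
    ff <- extract_features(s, spec, t)
    expect_equal(as.vector(t(ff$visual)), fm$visual[t, ])
    expect_equal(ff$proprio, fm$proprio[t, ])
  }
  expect_identical(extract_feature_matrix(s, spec), fm)
  expect_error(extract_features(s, spec, 21), "range")
})
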