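test_that("prediction error is zero at the stored pattern and masked slices", {
  pop <- population_config()
  ly <- toy_trained_layer(2, seed = 23, reps = 400)
  w1 <- ly$instar[1, ]
  expect_equal(prediction_error(w1, ly, 1, pop), rep(0, 348))
  set.seed(1)
  o <- rnorm(348); o <- o / sqrt(sum(o^2))
  g <- rep(1, 20); g[c(3, 15)] <- 0
  d <- prediction_error(o, ly, 1, pop, gains = g)
  expect_equal(d[pop$slices[[3]]], rep(0, 27))
  expect_equal(d[pop$slices[[15]]], rep(0, 3))
  # one training step on a fixed input contracts the error norm
  ly2 <- toy_trained_layer(1, seed = 3, reps = 5)
  e0 <- sum(prediction_error(o, ly2, 1, pop)^2)
  train_winner(ly2, o, 1L)
  e1 <- sum(prediction_error(o, ly2, 1, pop)^2)
  expect_lt(e1, e0)
})

test_that("orientation difference equals the quaternion axis-angle magnitude", {
  # perfect compensation and antipode anchors
  set.seed(33)
  for (i in 1:5) {
    R_nu <- random_rotation(seed = 100 + i)
    P <- canonical_views()[[(i %% 4) + 1]]
    expect_lt(orientation_difference(P, R_nu, P %*% t(R_nu)), 1e-6)
    flip <- euler_rotation_matrix(c(pi, 0, 0))
    expect_equal(orientation_difference(P, R_nu, P %*% flip %*% t(R_nu)), pi,
                 tolerance = 1e-6)
  }
  # random cases vs an independent quaternion oracle
  quat_angle <- function(R) {
    qw <- sqrt(max(0, 1 + R[1, 1] + R[2, 2] + R[3, 3])) / 2
    2 * acos(pmin(1, qw))
  }
  for (i in 1:50) {
    P <- random_rotation(seed = 200 + i)
    R_nu <- random_rotation(seed = 300 + i)
    R_mu <- random_rotation(seed = 400 + i)
    od <- orientation_difference(P, R_nu, R_mu)
    expect_equal(od, quat_angle(crossprod(P, R_mu %*% R_nu)),
                 tolerance = 1e-9)
    expect_gte(od, 0); expect_lte(od, pi)
  }
  expect_error(orientation_difference(diag(3) * 2, diag(3), diag(3)),
               "orthonormal")
})

test_that("exclusiveness scores winner histograms per condition", {
  rec <- data.frame(winner = c(rep(1, 10), rep(2, 12), rep(3, 8)),
                    label = c(rep("a", 10),
                              rep(c("a", "b", "c", "d"), 3),
                              rep(c("a", "b", "b", "b"), 2)))
  ex <- exclusiveness(rec)
  expect_equal(ex$exclusiveness[ex$pattern == 1], 1)          # single condition
  expect_equal(ex$exclusiveness[ex$pattern == 2], 0.25)       # uniform over 4
  expect_equal(ex$exclusiveness[ex$pattern == 3], 0.75)       # 3:1 split
  expect_equal(ex$condition[ex$pattern == 3], "b")
  # 12-condition uniform lower bound
  rec12 <- data.frame(winner = 1, label = rep(letters[1:12], 2))
  expect_equal(exclusiveness(rec12)$exclusiveness, 1 / 12)
})

test_that("vision-only winner predicts proprioception; wrong winner is worse", {
  cfg <- test_cfg(repetitions = 8)
  model <- bm_model(seed = 19)
  s <- generate_motion("gaitA", gait_params(seed = 21), frames = 360)
  train_model(model, s, repetitions = 8)
  pop <- model$pop
  g_vis <- c(rep(1, 12), rep(0, 8))
  enc_full <- encode_sequence(model, s)$activation
  enc_vis <- encode_sequence(model, s, gains = g_vis)$activation
  pr_idx <- unlist(pop$slices[13:20])
  errs_correct <- errs_wrong <- c()
  set.seed(2)
  for (f in seq(30, 360, by = 30)) {
    r <- proprio_inference_error(model, enc_vis[f, ], enc_full[f, ])
    errs_correct <- c(errs_correct, r$rms)
    wrong <- sample(setdiff(seq_len(model$layer$P - 1L), r$winner), 1)
    rw <- proprio_inference_error(model, enc_vis[f, ], enc_full[f, ],
                                  winner = wrong)
    errs_wrong <- c(errs_wrong, rw$rms)
  }
  expect_lt(mean(errs_correct), mean(errs_wrong))
  # exact case: winner instar equal to truth on proprio slices -> zero
  ly <- model$layer
  truth <- enc_full[60, ]
  ly$instar[1, pr_idx] <- truth[pr_idx]
  expect_equal(proprio_inference_error(model, enc_vis[60, ], truth,
                                       winner = 1)$rms, 0)
})
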