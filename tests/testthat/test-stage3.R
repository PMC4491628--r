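test_that("noise calibration and the closed-form recruitment law agree", {
  expect_equal(gamma_from(0.25, 2), 1)            # tan(pi/4) = 1
  g <- gamma_from(0.001, 0.034)
  ly <- list(theta = cos(pi / 3), gamma = g)
  expect_equal(recruitment_probability(ly$theta, ly), 0.5)
  expect_equal(recruitment_probability(ly$theta + 0.034, ly), 0.001,
               tolerance = 1e-12)
  expect_equal(recruitment_probability(ly$theta - 0.034, ly), 0.999,
               tolerance = 1e-12)
  expect_gt(gamma_from(0.49999, 0.034), 100)       # divergence toward 0.5
  expect_error(gamma_from(0, 1), "epsilon")
  expect_error(gamma_from(0.6, 1), "epsilon")
  expect_error(gamma_from(0.1, -1), "b")
})

test_that("net input equals cosine similarity for trained patterns", {
  set.seed(21)
  ly <- toy_trained_layer(3, reps = 50)
  for (i in 1:30) {
    a <- rnorm(348); a <- a / sqrt(sum(a^2))
    nets <- net_input(ly, a)
    for (j in 1:3) {
      w <- ly$instar[j, ]
      oracle <- sum(w * a) / sqrt(sum(w^2)) / sqrt(sum(a^2))
      expect_equal(nets[j], oracle, tolerance = 1e-12)
    }
    expect_true(all(abs(nets[1:3]) <= 1 + 1e-12))
  }
  # parallel and orthogonal anchors
  ly2 <- toy_trained_layer(2, orthogonal = TRUE)
  e1 <- numeric(348); e1[1] <- 1
  e2 <- numeric(348); e2[2] <- 1
  expect_equal(net_input(ly2, e1, j = 1), 1, tolerance = 1e-12)
  expect_equal(net_input(ly2, e2, j = 1), 0, tolerance = 1e-12)
})

test_that("the noiseless limit picks the deterministic argmax", {
  ly <- toy_trained_layer(3, gamma = 1e-12)
  a <- ly$instar[2, ] / sqrt(sum(ly$instar[2, ]^2))
  for (i in 1:10)
    expect_equal(activate(ly, a, include_free = FALSE)$winner, 2L)
})

test_that("recruitment frequency reproduces the closed form (Monte Carlo)", {
  ly <- pattern_layer(seed = 31)
  gam <- ly$gamma; theta <- ly$theta
  n <- 1e5
  # free pattern fires Cauchy(gamma, theta); a best trained pattern fires
  # Cauchy(gamma, net_g): sweep net_g across the sigmoid
  for (net_g in c(theta - 0.034, theta - 0.01, theta, theta + 0.01,
                  theta + 0.034)) {
    p_true <- recruitment_probability(net_g, ly)
    set.seed(1000 + round(net_g * 1e4))
    of <- rcauchy(n, theta, gam); og <- rcauchy(n, net_g, gam)
    phat <- mean(of >= og)
    se <- sqrt(p_true * (1 - p_true) / n)
    expect_lt(abs(phat - p_true), 3 * se + 1e-9)
  }
})

test_that("winner-take-all training converges and recruits on demand", {
  ly <- pattern_layer(seed = 5)
  expect_equal(ly$P, 1L)                      # starts with one free pattern
  a <- rnorm(348); a <- a / sqrt(sum(a^2))
  train_winner(ly, a, 1L)
  expect_equal(ly$P, 2L)                      # recruited, fresh free appended
  expect_equal(ly$norms[1], ly$eta, tolerance = 1e-12)
  expect_gt(ly$norms[1], ly$r)                # eta > r: trained immediately
  # repeated training: geometric approach with factor (1 - eta)
  for (k in 1:100) train_winner(ly, a, 1L)
  expect_equal(ly$instar[1, ], a * (1 - (1 - ly$eta)^101), tolerance = 1e-10)
  before <- ly$instar[1, ]
  train_winner(ly, ly$instar[1, ], 1L)        # fixed point
  expect_equal(ly$instar[1, ], before)
})

test_that("exactly one free pattern exists after every step and counts never shrink", {
  ly <- pattern_layer(seed = 8)
  set.seed(8)
  P_seen <- 1L
  for (t in 1:300) {
    a <- rnorm(348); a <- a / sqrt(sum(a^2))
    step_pattern_layer(ly, a, learn = TRUE)
    expect_gte(ly$P, P_seen)
    P_seen <- ly$P
    norms <- ly$norms[seq_len(ly$P)]
    expect_equal(sum(norms <= ly$r), 1L)      # the single free pattern
    expect_equal(which(norms <= ly$r), ly$P)  # ... always the last one
  }
})

test_that("orthogonal stimuli recruit exactly two patterns at theta = cos 60",  {
  ly <- pattern_layer(gamma = 1e-12, seed = 3)   # noiseless limit
  e1 <- numeric(348); e1[1] <- 1
  e2 <- numeric(348); e2[2] <- 1
  for (k in 1:50) {
    step_pattern_layer(ly, e1, learn = TRUE)
    step_pattern_layer(ly, e2, learn = TRUE)
  }
  expect_equal(ly$P - 1L, 2L)   # cos 0 = 1 > theta within; cos 90 = 0 < theta across
})

test_that("lateral inhibition satisfies its anchors and noise-only contract", {
  gam <- gamma_from()
  expect_equal(lateral_inhibition_term(0.5, gam), 0)
  expect_equal(lateral_inhibition_term(1, gam), 0)         # no facilitation
  expect_equal(lateral_inhibition_term(0, gam), -1, tolerance = 1e-9)
  expect_true(all(lateral_inhibition_term(seq(0, 1, 0.01), gam) <= 0))
  # uncorrected printed variant is maximal at w = 0.5 (kept for comparison)
  expect_lt(lateral_inhibition_term(0.5, gam, compat_printed = TRUE), -0.9)
  # noise-only drive: p(o_j > o_k) tracks the lateral weight
  n <- 1e5
  for (w in c(0.2, 0.35, 0.5)) {
    ly <- toy_trained_layer(2, seed = 40)
    ly$lateral[1, 2] <- w
    ly$prev_winner <- 1L
    zero <- numeric(348)
    hits <- logical(n)
    nets <- net_input(ly, zero)
    set.seed(50 + w * 100)
    oj <- rcauchy(n, nets[2], ly$gamma)
    ok <- rcauchy(n, nets[1], ly$gamma)
    phat <- mean(oj > ok)
    se <- sqrt(w * (1 - w) / n)
    expect_lt(abs(phat - w), 3 * se + 5e-3)
  }
})

test_that("lateral batch learning tracks transition statistics", {
  # equilibrium: identical nets and w = 0.5 leave the weight unchanged
  ly <- toy_trained_layer(3, seed = 12)
  ly$buf <- matrix(rep(c(0.4, 0.4, 0.2, ly$theta), each = 5), 5)
  update_lateral(ly, 1L)
  expect_equal(ly$lateral[1, 2], 0.5)
  expect_lt(ly$lateral[1, 3], 0.5)            # consistently weaker -> inhibited
  expect_equal(nrow(ly$buf), 0L)              # window cleared
  # strict alternation A -> B -> A with a bystander C: the follower weight
  # rises toward 1, weights to the bystander fall toward 0
  e <- function(i) { v <- numeric(348); v[i] <- 1; v }
  ly2 <- pattern_layer(seed = 13)
  c1 <- e(1); c2 <- e(2)
  c3 <- e(3) - 0.2 * (c1 + c2); c3 <- c3 / sqrt(sum(c3^2))
  for (p in list(c1, c2, c3)) {
    train_winner(ly2, p, ly2$P)
    for (r in 1:200) train_winner(ly2, p, ly2$P - 1L)
  }
  ly2$prev_winner <- NA_integer_
  for (k in 1:60) {
    step_pattern_layer(ly2, c1, learn = TRUE)
    step_pattern_layer(ly2, c2, learn = TRUE)
  }
  expect_gt(ly2$lateral[1, 2], 0.9)
  expect_gt(ly2$lateral[2, 1], 0.9)
  expect_lt(ly2$lateral[1, 3], 0.1)
  expect_lt(ly2$lateral[2, 3], 0.1)
})

test_that("free run on symmetric weights is uniform; layer state round-trips", {
  ly <- toy_trained_layer(4, seed = 17)
  ly$prev_winner <- NA_integer_
  fr <- free_run(ly, 4000)
  expect_equal(length(fr$winners), 4000)
  expect_equal(sum(fr$histogram), 4000)
  # all-0.5 lateral weights: no inhibition anywhere, uniform histogram
  expect_true(all(abs(fr$histogram / 4000 - 0.25) < 0.05))
  # serialization: identical behaviour after reload
  f <- tempfile(fileext = ".json")
  save_pattern_layer(ly, f)
  ly2 <- load_pattern_layer(f)
  expect_equal(ly2$P, ly$P)
  expect_equal(ly2$instar[seq_len(ly$P), ], ly$instar[seq_len(ly$P), ],
               tolerance = 1e-12)
  expect_equal(ly2$lateral[seq_len(ly$P), seq_len(ly$P)],
               ly$lateral[seq_len(ly$P), seq_len(ly$P)], tolerance = 1e-12)
  a <- rnorm(348)
  expect_equal(net_input(ly2, a), net_input(ly, a), tolerance = 1e-9)
  # the owned RNG stream is restored: same draws
  expect_equal(activate(ly2, a)$outputs, activate(ly, a)$outputs)
})
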