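test_that("Euler rotation matrix matches its definition and group structure", {
  expect_equal(euler_rotation_matrix(c(0, 0, 0)), diag(3))
  Rpi <- euler_rotation_matrix(c(pi, 0, 0))
  expect_lt(max(abs(Rpi %*% Rpi - diag(3))), 1e-12)
  # independent product oracle with the axis matrices written out
  mu <- c(0.3, -0.7, 1.1)
  Rx <- rbind(c(1, 0, 0), c(0, cos(0.3), -sin(0.3)), c(0, sin(0.3), cos(0.3)))
  Ry <- rbind(c(cos(-0.7), 0, sin(-0.7)), c(0, 1, 0),
              c(-sin(-0.7), 0, cos(-0.7)))
  Rz <- rbind(c(cos(1.1), -sin(1.1), 0), c(sin(1.1), cos(1.1), 0), c(0, 0, 1))
  expect_equal(euler_rotation_matrix(mu), Rx %*% Ry %*% Rz, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:25) {
    R <- euler_rotation_matrix(rnorm(3, sd = 3))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
  }
})

test_that("rotate_visual is an isometry with exact inverse", {
  st <- perspective_state(mu = c(0.4, 1.2, -0.3))
  expect_equal(rotate_visual(c(0, 0, 0), st), c(0, 0, 0))
  set.seed(3)
  D <- matrix(rnorm(3 * 1000), 3)
  RD <- rotate_visual(D, st)
  expect_equal(colSums(RD^2), colSums(D^2), tolerance = 1e-12)
  R <- euler_rotation_matrix(st$mu)
  expect_equal(rotate_visual(RD, t(R)), D, tolerance = 1e-12)
})

test_that("angle updates implement gradient descent with momentum", {
  st <- perspective_state(eta_mu = 0.01, m_mu = 0.85)
  expect_equal(update_angles(st, c(0, 0, 0))$mu, c(0, 0, 0))
  # m_mu = 0: plain SGD
  s0 <- perspective_state(eta_mu = 0.01, m_mu = 0)
  g <- c(1, -2, 0.5)
  for (k in 1:5) s0 <- update_angles(s0, g)
  expect_equal(s0$mu, -5 * 0.01 * g, tolerance = 1e-12)
  # constant gradient with momentum: mu_k = -eta*g * sum_{i<=k} (1-m^i)/(1-m)
  s1 <- perspective_state(eta_mu = 0.01, m_mu = 0.85)
  K <- 12
  for (k in 1:K) s1 <- update_angles(s1, g)
  coef <- sum((1 - 0.85^(1:K)) / (1 - 0.85))
  expect_equal(s1$mu, -0.01 * g * coef, tolerance = 1e-10)
  expect_error(update_angles(s1, c(NaN, 0, 0)), "finite")
})

test_that("backprop gradient matches central finite differences", {
  set.seed(42)
  pop <- population_config()
  ly <- toy_trained_layer(1, reps = 150)
  maxerr <- 0
  for (trial in 1:100) {
    qvis <- matrix(rnorm(36, sd = 0.3), 3, 12)
    qn <- sqrt(colSums(qvis^2))
    qvis <- sweep(qvis, 2, pmax(qn / 0.9, 1), "/")   # sub-threshold regime
    dpro <- runif(8, -0.9, 0.9)
    mu <- rnorm(3)
    enc_at <- function(m)
      encode_all(c(as.vector(euler_rotation_matrix(m) %*% qvis), dpro), pop)
    E_at <- function(m) {
      d <- ly$instar[1, ] - enc_at(m); 0.5 * sum(d^2)
    }
    delta <- prediction_error(enc_at(mu), ly, 1, pop)
    g <- backprop_to_perspective(delta, pop, qvis, mu)
    h <- 1e-6
    gfd <- vapply(1:3, function(a) {
      e <- numeric(3); e[a] <- h
      (E_at(mu + e) - E_at(mu - e)) / (2 * h)
    }, numeric(1))
    maxerr <- max(maxerr, max(abs(g - gfd)) / max(max(abs(gfd)), 1e-8))
  }
  expect_lt(maxerr, 1e-4)
})

test_that("a small descent step reduces the error for rotated stored patterns", {
  set.seed(5)
  pop <- population_config()
  model <- bm_model(seed = 2)
  s <- generate_motion("gaitA", gait_params(seed = 3), frames = 120)
  train_model(model, s, repetitions = 3)
  enc <- encode_sequence(model, s)
  wins <- 0; tries <- 0
  for (trial in 1:40) {
    f <- sample(20:120, 1)
    ang <- rnorm(3, sd = 0.1)               # small random offset
    qvis <- matrix(enc$directions[f, 1:36], 3)
    dpro <- enc$directions[f, 37:44]
    enc_at <- function(m)
      encode_all(c(as.vector(euler_rotation_matrix(m) %*% qvis), dpro), pop)
    o <- enc_at(ang)
    k <- activate(model$layer, o, include_free = FALSE)$winner
    E0 <- 0.5 * sum((model$layer$instar[k, ] - o)^2)
    delta <- prediction_error(o, model$layer, k, pop)
    g <- backprop_to_perspective(delta, pop, qvis, ang)
    if (sqrt(sum(g^2)) < 1e-8) next
    o1 <- enc_at(ang - 1e-3 * g / sqrt(sum(g^2)))
    E1 <- 0.5 * sum((model$layer$instar[k, ] - o1)^2)
    tries <- tries + 1
    if (E1 < E0) wins <- wins + 1
  }
  expect_gt(wins / tries, 0.9)
})
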