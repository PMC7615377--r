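test_that("transition matrix follows constant-acceleration kinematics", {
  F1 <- build_transition(1)
  expect_equal(F1[1, ], c(1, 1, 0.5, 0, 0, 0))
  expect_equal(F1[4, ], c(0, 0, 0, 1, 1, 0.5))
  expect_equal(build_transition(2)[1, 3], 2)        # dt^2 / 2 at dt = 2
  FL <- build_transition(1, model = "linear")
  expect_equal(FL[1, 3], 0)
  expect_equal(FL[2, 3], 0)
  expect_error(build_transition(0), "positive")
  expect_error(build_transition(-1), "positive")
})

test_that("process noise is the white-jerk outer product, symmetric PSD", {
  expect_equal(build_process_noise(3, 0), matrix(0, 6, 6))
  Q <- build_process_noise(1, 1)
  expect_equal(Q[1:3, 1:3],
               matrix(c(0.25, 0.5, 0.5, 0.5, 1, 1, 0.5, 1, 1), 3, 3))
  Q2 <- build_process_noise(7.3, 2.1)
  expect_equal(Q2, t(Q2))
  expect_true(all(eigen(Q2, symmetric = TRUE)$values >= -1e-9))
  expect_error(build_process_noise(1, -1), "non-negative")
})

test_that("prediction integrates position, velocity and acceleration", {
  cfg <- kalman_config(10)  # dt = 100 ms
  P0 <- diag(1e-6, 6)
  still <- predict_state(motion_state(c(5, 0, 0, -3, 0, 0), P0, 0L), cfg)
  expect_equal(still$S[c(1, 4)], c(5, -3))
  expect_equal(still$frame, 1L)

  mv <- predict_state(motion_state(c(0, 1, 0, 0, 0, 0), P0, 0L), cfg)
  expect_equal(mv$S[1], 100)  # 1 mm/s over 100 ms = 100 um

  # 1 mm/s^2 = 1e-3 um/ms^2; x' = a dt^2 / 2 = 5 um
  ac <- predict_state(motion_state(c(0, 0, 1e-3, 0, 0, 0), P0, 0L), cfg)
  expect_equal(ac$S[1], 5)
})

test_that("pairing cost is the reciprocal Gaussian density", {
  P0 <- matrix(0, 6, 6)
  st <- motion_state(rep(0, 6), P0, 0L)
  cfg1 <- kalman_config(25, sigma_obs = 1)   # Sigma = I um^2
  pl <- pairing_cost(st, c(0, 0), cfg1)
  expect_equal(pl$cost, 2 * pi)
  expect_equal(pl$mahal2, 0)

  cfg2 <- kalman_config(25, sigma_obs = 2)   # Sigma = 4 I
  expect_equal(pairing_cost(st, c(0, 0), cfg2)$cost, 8 * pi)

  # monotone in distance and invariant to joint rigid translation
  d <- c(0.5, 1, 2, 5)
  costs <- vapply(d, function(u) pairing_cost(st, c(u, 0), cfg1)$cost,
                  numeric(1))
  expect_true(all(diff(costs) > 0))
  sh <- motion_state(c(123, 0, 0, -77, 0, 0), P0, 0L)
  expect_equal(pairing_cost(sh, c(123 + 1.3, -77 + 0.4), cfg1)$cost,
               pairing_cost(st, c(1.3, 0.4), cfg1)$cost)
})

test_that("update obeys the standard Kalman limits", {
  cfg <- kalman_config(25, sigma_obs = 1)
  P <- diag(c(1, 0, 0, 1, 0, 0))
  pred <- motion_state(c(0, 0, 0, 0, 0, 0), P, 1L)

  # zero innovation leaves the state unchanged
  post0 <- kalman_update(pred, c(0, 0), cfg)
  expect_equal(post0$S, rep(0, 6))

  # scalar analogue: prior var 1, obs var 1 -> posterior var 0.5
  expect_equal(post0$P[1, 1], 0.5)

  # near-perfect measurement pulls the posterior onto the observation
  cfg0 <- kalman_config(25, sigma_obs = 1e-9)
  post1 <- kalman_update(motion_state(rep(0, 6), diag(1, 6), 1L),
                         c(3, -4), cfg0)
  expect_equal(post1$S[c(1, 4)], c(3, -4), tolerance = 1e-6)
})

test_that("noise-free constant-acceleration motion is recovered exactly", {
  dt <- 40
  v_true <- c(1.2, -0.4)          # um/ms
  a_true <- c(0.02, 0.013)        # um/ms^2
  path <- ca_trajectory(c(10, 20), v_true, a_true, dt, 7L)
  cfg <- kalman_config(1000 / dt, sigma_a = 0, sigma_obs = 1e-6)

  ini <- init_state(path[1, ], path[2, ], path[3, ], dt)
  v3 <- ini$v_init + ini$a_init * dt  # state attached at the third frame
  st <- motion_state(c(path[3, 1], v3[1], ini$a_init[1],
                       path[3, 2], v3[2], ini$a_init[2]),
                     diag(kalman_config(1000 / dt)$p0_diag), 2L)
  for (k in 4:6) {
    st <- predict_state(st, cfg)
    st <- kalman_update(st, path[k, ], cfg)
  }
  v_final <- v_true + a_true * 5 * dt    # velocity at the sixth frame
  expect_lt(max(abs(st$S[c(2, 5)] - v_final) / abs(v_final)), 1e-6)
  expect_lt(max(abs(st$S[c(3, 6)] - a_true) / abs(a_true)), 1e-6)
})

test_that("covariance stays symmetric PSD through long predict/update cycles", {
  set.seed(42)
  cfg <- kalman_config(20, sigma_a = 80, sigma_obs = 5)
  st <- motion_state(rep(0, 6), diag(cfg$p0_diag), 0L)
  for (k in 1:50) {
    st <- predict_state(st, cfg)
    st <- kalman_update(st, rnorm(2, sd = 30), cfg)
    expect_lt(max(abs(st$P - t(st$P))), 1e-9)
    expect_true(all(eigen(st$P, symmetric = TRUE,
                          only.values = TRUE)$values >= -1e-9))
  }
})
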