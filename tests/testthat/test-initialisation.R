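test_that("triplet cost captures the smoothness of three-frame motion", {
  # collinear equal steps
  expect_equal(triplet_cost(c(0, 0), c(1, 0), c(2, 0)), 0)
  # exact reversal
  expect_equal(triplet_cost(c(0, 0), c(1, 0), c(0, 0)), 1)
  # right-angle turn with equal step length s
  expect_equal(triplet_cost(c(0, 0), c(1, 0), c(1, 1)), sqrt(2) / 2)
  # stationary bubble: defined as zero rather than 0/0
  expect_equal(triplet_cost(c(3, 3), c(3, 3), c(3, 3)), 0)
})

test_that("triplet cost is invariant to rotation, translation and scaling", {
  set.seed(7)
  for (rep in 1:25) {
    p <- matrix(runif(6, -50, 50), 3, 2)
    base <- triplet_cost(p[1, ], p[2, ], p[3, ])
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    s <- runif(1, 0.1, 20)
    shift <- runif(2, -100, 100)
    q <- s * p %*% R + rep(shift, each = 3)
    expect_equal(triplet_cost(q[1, ], q[2, ], q[3, ]), base,
                 tolerance = 1e-10)
  }
})

test_that("initial state follows central-difference kinematics", {
  # uniform motion: 1 um per 100 ms frame
  ini <- init_state(c(0, 0), c(1, 0), c(2, 0), 100)
  expect_equal(ini$v_init, c(0.01, 0))
  expect_equal(ini$a_init, c(0, 0))

  # L12 = (100, 0), L23 = (300, 0), dt = 100 ms
  ini2 <- init_state(c(0, 0), c(100, 0), c(400, 0), 100)
  expect_equal(ini2$v_init, c(2, 0))                 # mm/s
  expect_equal(ini2$a_init * 1000, c(20, 0))         # mm/s^2

  # reversal cancels the velocity
  ini3 <- init_state(c(0, 0), c(5, 5), c(0, 0), 50)
  expect_equal(ini3$v_init, c(0, 0))

  # exact second difference for true constant acceleration
  path <- ca_trajectory(c(0, 0), c(0.7, -0.2), c(0.011, 0.004), 40, 3L)
  ini4 <- init_state(path[1, ], path[2, ], path[3, ], 40)
  expect_equal(ini4$a_init, c(0.011, 0.004), tolerance = 1e-12)
  expect_equal(ini4$v_init + ini4$a_init * 40,            # velocity at frame 3
               c(0.7, -0.2) + c(0.011, 0.004) * 2 * 40, tolerance = 1e-12)
})

test_that("triplet assignment recovers isolated and parallel tracks", {
  # one straight bubble, no clutter
  one <- solve_triplet_assignment(rbind(c(0, 0)), rbind(c(10, 0)),
                                  rbind(c(20, 0)), gate = 100)
  expect_equal(nrow(one), 1L)
  expect_equal(one$cost, 0)

  # two parallel bubbles far apart relative to the gate
  f1 <- rbind(c(0, 0), c(0, 1000))
  f2 <- rbind(c(20, 0), c(20, 1000))
  f3 <- rbind(c(40, 0), c(40, 1000))
  two <- solve_triplet_assignment(f1, f2, f3, gate = 100)
  expect_equal(nrow(two), 2L)
  expect_equal(two$i, two$j)
  expect_equal(two$j, two$k)

  # empty frames give an empty set, not an error
  expect_equal(nrow(solve_triplet_assignment(NULL, f2, f3, gate = 100)), 0L)
})

test_that("exact small-instance solver matches the exhaustive oracle", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(2:4, 3, replace = TRUE)
    f1 <- matrix(runif(2 * n[1], 0, 200), n[1], 2)
    f2 <- matrix(runif(2 * n[2], 0, 200), n[2], 2)
    f3 <- matrix(runif(2 * n[3], 0, 200), n[3], 2)
    gate <- 250
    sel <- solve_triplet_assignment(f1, f2, f3, gate = gate, cost_cap = 0.9)
    cand <- ulmtrack:::triplet_candidates(f1, f2, f3, gate, 0.9)
    opt <- oracle_triplets(cand)
    expect_equal(nrow(sel), opt$card)
    expect_equal(sum(sel$cost), opt$cost, tolerance = 1e-9)
    # conflict-free: no detection reused
    expect_false(any(duplicated(sel$i)) || any(duplicated(sel$j)) ||
                   any(duplicated(sel$k)))
  }
})

test_that("greedy never beats the exact optimum and respects conflicts", {
  set.seed(13)
  for (rep in 1:15) {
    f <- lapply(1:3, function(i) matrix(runif(10, 0, 150), 5, 2))
    cand <- ulmtrack:::triplet_candidates(f[[1]], f[[2]], f[[3]], 200, 0.9)
    if (nrow(cand) == 0L) next
    gsel <- ulmtrack:::triplet_greedy(cand, 5L, 5L, 5L)
    opt <- oracle_triplets(cand)
    gcard <- length(gsel)
    gcost <- sum(cand$cost[gsel])
    expect_true(gcard < opt$card ||
                  (gcard == opt$card && gcost >= opt$cost - 1e-9))
  }
})
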