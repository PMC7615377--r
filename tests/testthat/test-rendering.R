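test_that("segment acceleration makes the quadratic hit the far endpoint", {
  # consistent straight motion needs no acceleration
  expect_equal(estimate_segment_acceleration(c(0, 0), c(100, 0),
                                             c(1, 0), 100), c(0, 0))
  # 50 um reached from rest in 100 ms: a = 2 * 50 / 100^2 um/ms^2 = 10 mm/s^2
  a <- estimate_segment_acceleration(c(0, 0), c(50, 0), c(0, 0), 100)
  expect_equal(a * 1000, c(10, 0))

  # constructive identity at arbitrary geometry
  set.seed(3)
  for (rep in 1:10) {
    p1 <- runif(2, -100, 100); p2 <- runif(2, -100, 100)
    v1 <- runif(2, -2, 2); dtf <- runif(1, 20, 120)
    ae <- estimate_segment_acceleration(p1, p2, v1, dtf)
    seg <- interpolate_segment(p1, v1, ae, dtf, spacing = 15)
    endp <- unclass(seg)[nrow(seg), c("x", "y")]
    expect_lt(max(abs(endp - p2)), 1e-9)
    expect_equal(unname(unclass(seg)[1, c("x", "y")]), p1)
  }
})

test_that("interpolation respects spacing and reduces to the chord at a = 0", {
  seg <- interpolate_segment(c(0, 0), c(1, 1), c(0, 0), 100, spacing = 10)
  m <- unclass(seg)
  # all points exactly on the straight chord y = x
  expect_lt(max(abs(m[, "x"] - m[, "y"])), 1e-9)
  gaps <- sqrt(diff(m[, "x"])^2 + diff(m[, "y"])^2)
  expect_true(all(gaps <= 10 * (1 + 1e-6)))

  # curved segment: max transverse deviation equals the parabola's sagitta
  # p(t) = (v t, 0.5 ay t^2) with the endpoint forced onto the x-axis
  p2 <- c(100, 0)
  v1 <- c(1, 1)
  a <- estimate_segment_acceleration(c(0, 0), p2, v1, 100)
  seg2 <- unclass(interpolate_segment(c(0, 0), v1, a, 100, spacing = 1))
  # y(t) = t - 0.01 t^2 peaks at t = 50 with height 25
  expect_equal(max(seg2[, "y"]), 25, tolerance = 1e-3)
  gaps2 <- sqrt(diff(seg2[, "x"])^2 + diff(seg2[, "y"])^2)
  expect_true(all(gaps2 <= 1 * (1 + 1e-6)))
})

test_that("speed gradient is signed change per distance", {
  pts <- cbind(x = c(0, 5, 10), y = c(0, 0, 0),
               speed = c(3, 3.5, 4), t = c(0, 50, 100))
  g <- speed_gradient(pts)
  # 0.5 mm/s over 5 um = 100 1/s
  expect_equal(g$gradient, c(100, 100))
  expect_equal(g$x, c(2.5, 7.5))

  # constant speed: all gradients zero
  pts0 <- cbind(x = 0:5 * 10, y = 0, speed = 2, t = 0:5 * 10)
  expect_true(all(speed_gradient(pts0)$gradient == 0))

  # reversing the traversal negates the gradients
  rev_pts <- pts[3:1, ]
  expect_equal(sort(speed_gradient(rev_pts)$gradient), c(-100, -100))

  # per-time variant: 0.5 mm/s per 50 ms = 10 mm/s^2
  gt <- speed_gradient(pts, per = "time")
  expect_equal(gt$gradient, c(10, 10))
})

test_that("map accumulation bins interpolated points conservatively", {
  # one straight track across the grid
  path <- ca_trajectory(c(5, 5), c(1, 0), c(0, 0), 40, 6L)
  fit <- mb_track(detections_from_paths(list(path)),
                  config = kalman_config(25))
  dmap <- accumulate_map(fit, "density", pixel_size = 10)
  ip <- ulmtrack:::interpolate_tracks(fit, 5, per = NULL)$points
  expect_equal(sum(dmap$grid), nrow(ip))
  expect_true(all(dmap$grid >= 0))

  smap <- accumulate_map(fit, "speed", pixel_size = 10)
  expect_true(all(is.na(smap$grid[smap$counts == 0])))
  sampled <- smap$grid[smap$counts > 0]
  expect_equal(mean(sampled), 1, tolerance = 0.05)  # 1 mm/s track

  gmap <- accumulate_map(fit, "gradient", pixel_size = 10)
  expect_true(all(abs(gmap$grid[gmap$counts > 0]) < 1e-6))  # constant speed

  expect_output(print(dmap), "density map")
})

test_that("two overlapping tracks average their speeds in shared pixels", {
  p1 <- ca_trajectory(c(0, 0), c(0.5, 0), c(0, 0), 40, 6L)   # 0.5 mm/s
  p2 <- ca_trajectory(c(0, 0), c(1.0, 0), c(0, 0), 40, 3L)   # 1.0 mm/s
  det <- detections_from_paths(list(p1, p2))
  # separate the bubbles in time so they form two tracks over one path:
  det$frame[det$truth_id == 2] <- det$frame[det$truth_id == 2] + 20L
  fit <- mb_track(det, config = kalman_config(25))
  smap <- accumulate_map(fit, "speed", pixel_size = 1000,
                         extent = list(xlim = c(0, 1000), ylim = c(-500, 500)))
  v <- smap$grid[smap$counts > 0]
  expect_true(all(v > 0.5 - 0.05 & v < 1.0 + 0.05))
})
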