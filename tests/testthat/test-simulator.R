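test_that("pulsatile flow honours mean, period, floor and peak acceleration", {
  # no pulsatility: constant baseline speed
  f0 <- flow_profile(3, 0)
  expect_equal(speed_at(f0, c(0, 0.123, 0.71)), rep(3, 3))

  tg <- seq(0, 1.6, length.out = 32001)
  for (amax in c(37.5, 75, 112.5)) {
    fp <- flow_profile(3, amax, heart_rate = 75)
    s <- speed_at(fp, tg)
    expect_true(all(s > 0))
    # period 60 / 75 = 0.8 s
    expect_equal(speed_at(fp, 0.1), speed_at(fp, 0.9), tolerance = 1e-9)
    # time-mean within 1%
    expect_equal(mean(s[tg < 0.8]), 3, tolerance = 0.01)
    # numerical max |ds/dt| within 1%
    dsdt <- diff(s) / diff(tg)
    expect_equal(max(abs(dsdt)), amax, tolerance = 0.01)
  }
})

test_that("vessel trees have the prescribed topology and are seeded", {
  tr <- make_vessel_tree("branching", seed = 9)
  expect_equal(length(tr$segments), 8L)
  parents <- vapply(tr$segments, `[[`, integer(1), "parent")
  expect_equal(sum(parents == 0L), 2L)          # two mains
  expect_true(all(table(parents[parents > 0]) == 3))  # three children each
  # children start on their parent's endpoint
  for (sg in tr$segments) {
    if (sg$parent == 0L) next
    pend <- tr$segments[[sg$parent]]$points
    expect_equal(unname(sg$points[1, ]), unname(pend[nrow(pend), ]))
  }
  # determinism
  tr2 <- make_vessel_tree("branching", seed = 9)
  expect_identical(tr, tr2)

  single <- make_vessel_tree("single", seed = 2)
  expect_equal(length(single$segments), 1L)
  expect_true(all(diff(single$segments[[1]]$arc) > 0))
})

test_that("simulation advances bubbles by the integrated speed law", {
  tree <- make_vessel_tree("single", seed = 6)
  scene <- simulate_scene(tree, flow_profile(3, 0), 15, 30, n_expected = 1,
                          sigma_loc = 0, one_at_a_time = TRUE, seed = 8,
                          min_separation = 0)
  expect_equal(scene$n_frames, 450L)             # 15 Hz x 30 s
  expect_true(max(scene$detections$frame) <= 449L)

  # noise-free: equal arc steps of s0 / frame_rate = 200 um
  d <- scene$detections
  one <- d[d$truth_id == d$truth_id[1], ]
  steps <- sqrt(diff(one$x_um)^2 + diff(one$y_um)^2)
  # chord is marginally shorter than arc on curved stretches
  expect_true(all(steps <= 200 * 1.001))
  expect_true(stats::median(steps) > 200 * 0.98)

  # pair conservation: one true pair per bubble per consecutive frame pair
  counts <- table(d$truth_id)
  expect_equal(nrow(scene$truth$pairs), sum(pmax(counts - 1L, 0L)))
})

test_that("localisation noise follows the Rayleigh radial-error law", {
  tree <- make_vessel_tree("branching", seed = 1)
  scene <- simulate_scene(tree, flow_profile(3, 0), 25, 30,
                          n_expected = 6, sigma_loc = 10, seed = 33,
                          min_separation = 0)
  d <- scene$detections
  td <- scene$truth$detections
  expect_gte(nrow(d), 1000L)
  r <- sqrt((d$x_um - td$x_true)^2 + (d$y_um - td$y_true)^2)
  expect_equal(mean(r), 10 * sqrt(pi / 2), tolerance = 0.05)
})

test_that("interpolation scenes hold one bubble at a time at 30 mm/s", {
  scene <- make_interpolation_scene(15, seed = 3, duration = 20,
                                    sigma_loc = 0)
  d <- scene$detections
  expect_false(any(duplicated(d$frame)))   # never two bubbles in one frame
  one <- d[d$truth_id == d$truth_id[which.max(tabulate(d$truth_id))], ]
  steps <- sqrt(diff(one$x_um)^2 + diff(one$y_um)^2)
  # 30 mm/s at 15 Hz: about 2 mm along the arc between frames
  expect_true(all(steps <= 2000 * 1.001))
  expect_true(stats::median(steps) > 2000 * 0.9)
  expect_equal(formals(make_interpolation_scene)$duration, 60)
})

test_that("resolvability filter removes sub-diffraction bubble pairs", {
  tree <- make_vessel_tree("branching", seed = 2)
  flow <- flow_profile(3, 0)
  dense <- simulate_scene(tree, flow, 25, 8, n_expected = 8, seed = 5,
                          min_separation = 0)
  filt <- simulate_scene(tree, flow, 25, 8, n_expected = 8, seed = 5,
                         min_separation = 150)
  expect_lte(nrow(filt$detections), nrow(dense$detections))
  td <- filt$truth$detections
  for (fr in unique(td$frame)) {
    xy <- td[td$frame == fr, c("x_true", "y_true")]
    if (nrow(xy) < 2) next
    expect_gte(min(stats::dist(xy)), 150)
  }
})
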