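test_that("confusion counts and rates follow the pair definitions", {
  truth <- data.frame(frame_k = 0:9, det_k = 1:10, det_k1 = 11:20)
  # perfect tracking
  perfect <- within(truth, frame_k1 <- frame_k + 1L)
  cf <- confusion(perfect, truth)
  expect_equal(c(cf$TP, cf$FP, cf$FN), c(10L, 0L, 0L))
  expect_equal(cf$tpr, 1)
  expect_equal(cf$fnr, 0)

  # 9 true links, 1 false, 1 missed: tpr 0.9, fnr 0.1
  mixed <- perfect[1:9, ]
  mixed <- rbind(mixed, data.frame(frame_k = 3L, frame_k1 = 4L,
                                   det_k = 4L, det_k1 = 99L))
  cf2 <- confusion(mixed, truth)
  expect_equal(c(cf2$TP, cf2$FP, cf2$FN), c(9L, 1L, 1L))
  expect_equal(cf2$tpr, 0.9)
  expect_equal(cf2$fnr, 0.1)

  # empty output: tpr undefined (NA), fnr 1
  empty <- truth[0, ]
  cf3 <- confusion(empty, truth)
  expect_true(is.na(cf3$tpr))
  expect_equal(cf3$fnr, 1)
})

test_that("confusion matches a set-intersection oracle on random pair sets", {
  set.seed(19)
  for (rep in 1:30) {
    nt <- sample(0:60, 1); np <- sample(0:60, 1)
    truth <- unique(data.frame(frame_k = sample(0:8, nt, TRUE),
                               det_k = sample(1:30, nt, TRUE),
                               det_k1 = sample(31:60, nt, TRUE)))
    prod <- unique(data.frame(frame_k = sample(0:8, np, TRUE),
                              det_k = sample(1:30, np, TRUE),
                              det_k1 = sample(31:60, np, TRUE)))
    cf <- confusion(prod, truth)
    inter <- nrow(merge(prod, truth))
    expect_equal(cf$TP, inter)
    expect_equal(cf$FP, nrow(prod) - inter)
    expect_equal(cf$FN, nrow(truth) - inter)
    # the printed-definition identities hold exactly
    if (cf$TP + cf$FP > 0) expect_equal(cf$tpr, cf$TP / (cf$TP + cf$FP))
    if (cf$TP + cf$FN > 0)
      expect_equal(cf$fnr, 1 - cf$TP / (cf$TP + cf$FN))
  }
})

test_that("centreline distance matches the circular-arc closed form", {
  # points on the centreline have zero error
  th <- seq(0, pi / 3, length.out = 2000)
  R <- 800
  arc <- cbind(R * cos(th), R * sin(th))
  on_line <- interpolation_error(data.frame(x = arc[seq(1, 2000, 50), 1],
                                            y = arc[seq(1, 2000, 50), 2]),
                                 arc)
  expect_lt(on_line$mean, 1e-9)

  # chord across the arc: max distance is the sagitta R (1 - cos(theta/2))
  chord_t <- seq(0, 1, length.out = 400)
  p1 <- arc[1, ]; p2 <- arc[2000, ]
  chord <- cbind(p1[1] + chord_t * (p2[1] - p1[1]),
                 p1[2] + chord_t * (p2[2] - p1[2]))
  err <- interpolation_error(data.frame(x = chord[, 1], y = chord[, 2]), arc)
  expect_equal(max(err$distances), R * (1 - cos(pi / 6)), tolerance = 1e-3)
})

test_that("SSIM agrees with a direct windowed reference and is symmetric", {
  set.seed(23)
  A <- matrix(runif(24 * 20), 24, 20)
  B <- A + matrix(rnorm(24 * 20, sd = 0.2), 24, 20)
  expect_equal(map_ssim(A, A), 1)
  expect_equal(map_ssim(A, B), map_ssim(B, A))
  expect_lt(map_ssim(A, matrix(0, 24, 20)), 1)
  expect_equal(map_ssim(A, B), oracle_ssim(A, B), tolerance = 1e-6)
  expect_error(map_ssim(A, matrix(0, 5, 5)), "shape")
})

test_that("FRC resolution behaves sanely on synthetic maps", {
  # white-noise localisations: resolution no better than the grid Nyquist
  set.seed(31)
  paths <- lapply(1:40, function(i)
    matrix(runif(12, 0, 2000), 6, 2))
  det <- detections_from_paths(paths)
  fit <- mb_track(det[order(det$frame), ],
                  config = kalman_config(25, v_max = 1e4, cost_cap = 1))
  if (length(unique(fit$tracks$track_id)) >= 2) {
    res <- frc_resolution(fit, pixel_size = 20)
    if (is.finite(res$resolution_um)) expect_gte(res$resolution_um, 40)
    # joint translation leaves the resolution unchanged
    fit2 <- fit
    fit2$tracks$x_um <- fit2$tracks$x_um + 500
    fit2$tracks$y_um <- fit2$tracks$y_um - 300
    res2 <- frc_resolution(fit2, pixel_size = 20)
    expect_equal(res$resolution_um, res2$resolution_um, tolerance = 1e-9)
  }
  expect_error(frc_resolution(structure(list(
    tracks = data.frame(track_id = 1L)), class = "ulm_tracks")), "two tracks")
})

test_that("benchmark grid enumerates the full study design", {
  g <- benchmark_grid("paper")
  expect_equal(nrow(g), 360L)
  expect_true(all(table(g$acceleration) == 90L))
  expect_equal(sort(unique(g$frame_rate)), c(15, 25, 35))
  expect_equal(sort(unique(g$concentration)), c(2.54e7, 3.82e7, 6.36e7))
  expect_equal(length(unique(g$tree_seed)), 10L)

  smoke <- run_benchmark(benchmark_grid("smoke"), duration = 3, seed = 2)
  expect_equal(nrow(smoke), 8L)   # 4 settings x 2 models
  expect_true(all(c("TP", "FP", "FN", "tpr", "fnr") %in% names(smoke)))
  expect_true(all(smoke$TP >= 0))
})

test_that("acoustic and downsampling helpers compute the standard values", {
  expect_equal(half_wavelength_um(5e6), 154)
  expect_equal(downsampled_rate(100, 4), 25)
  expect_error(downsampled_rate(100, 2.5), "integer")
})
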