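# Evaluation of tracking and interpolation against simulator ground truth.
#
# Pairing metrics follow the super-resolution challenge convention: the
# "true positive rate" is TP / (TP + FP) over microbubble pairs (the
# quantity usually called precision) and the false negative rate is
# 1 - TP / (TP + FN) over ground-truth pairs.  Ratios with zero denominator
# are reported as NA, never as 0 or 1.

#' Pairing confusion counts
#'
#' Compares the consecutive-frame links produced by the tracker with the
#' ground-truth pairs of a simulated scene.  A produced pair is a true
#' positive iff its two detections carry the same ground-truth identity in
#' consecutive frames; remaining produced pairs are false positives and
#' unproduced truth pairs are false negatives.
#'
#' @param produced data.frame of produced links with columns `frame_k`,
#'   `det_k`, `det_k1` (and optionally `frame_k1`; links spanning more than
#'   one frame are never true positives).
#' @param scene an `ulm_scene`, or a data.frame of truth pairs with columns
#'   `frame_k`, `det_k`, `det_k1`.
#' @return object of class `pairing_confusion`: list with integer `TP`,
#'   `FP`, `FN` and the rates `tpr = TP/(TP+FP)`,
#'   `fnr = 1 - TP/(TP+FN)` (NA when undefined).
#' @export
confusion <- function(produced, scene) {
  truth <- if (inherits(scene, "ulm_scene")) scene$truth$pairs else
    as.data.frame(scene)
  produced <- as.data.frame(produced)
  need <- c("frame_k", "det_k", "det_k1")
  if (!all(need %in% names(produced)) || !all(need %in% names(truth)))
    stop("pair tables need columns frame_k, det_k, det_k1")
  if (inherits(scene, "ulm_scene")) {
    nd <- nrow(scene$detections)
    idx <- c(produced$det_k, produced$det_k1)
    if (length(idx) && (any(idx < 1) || any(idx > nd)))
      stop("produced pairs reference unknown detections")
  }
  consec <- if ("frame_k1" %in% names(produced))
    produced$frame_k1 - produced$frame_k == 1L else rep(TRUE, nrow(produced))
  pk <- paste(produced$frame_k, produced$det_k, produced$det_k1)
  tk <- paste(truth$frame_k, truth$det_k, truth$det_k1)
  TP <- sum(consec & pk %in% tk)
  FP <- nrow(produced) - TP
  FN <- nrow(truth) - TP
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN),
                 tpr = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
                 fnr = if (TP + FN > 0) 1 - TP / (TP + FN) else NA_real_),
            class = "pairing_confusion")
}

#' @export
print.pairing_confusion <- function(x, ...) {
  cat(sprintf("Pairing confusion: TP %d, FP %d, FN %d\n", x$TP, x$FP, x$FN))
  cat(sprintf("  TPR (precision over pairs): %s   FNR (miss rate): %s\n",
              format(x$tpr, digits = 4), format(x$fnr, digits = 4)))
  invisible(x)
}

# Minimum distance from each query point to a dense point set.  Fast path:
# one vectorised pass over the 3x3 cell neighbourhood of each query (exact
# whenever the nearest point lies within one cell width); queries without a
# provably minimal candidate fall back to an expanding ring search.
nearest_distances <- function(points, polyline) {
  points <- as.matrix(points)
  polyline <- as.matrix(polyline)
  np <- nrow(points)
  if (np == 0L) return(numeric())
  cell <- 100  # um
  x0 <- min(polyline[, 1], points[, 1])
  y0 <- min(polyline[, 2], points[, 2])
  pix <- floor((polyline[, 1] - x0) / cell)
  piy <- floor((polyline[, 2] - y0) / cell)
  buckets <- split(seq_len(nrow(polyline)), paste(pix, piy))
  qix <- floor((points[, 1] - x0) / cell)
  qiy <- floor((points[, 2] - y0) / cell)
  best <- rep(Inf, np)
  for (dx in -1:1) for (dy in -1:1) {
    hit <- buckets[paste(qix + dx, qiy + dy)]
    len <- lengths(hit)
    if (!any(len > 0L)) next
    qrep <- rep.int(seq_len(np), len)
    pidx <- unlist(hit, use.names = FALSE)
    d2 <- (polyline[pidx, 1] - points[qrep, 1])^2 +
      (polyline[pidx, 2] - points[qrep, 2])^2
    m <- tapply(d2, qrep, min)
    qi <- as.integer(names(m))
    best[qi] <- pmin(best[qi], as.numeric(m))
  }
  # certified if the best candidate is within one cell width (any point
  # outside the 3x3 block is at least `cell` away)
  todo <- which(!(is.finite(best) & best <= cell^2))
  if (length(todo))
    best[todo] <- nearest_distances_ring(points[todo, , drop = FALSE],
                                         polyline, buckets, x0, y0, cell)^2
  sqrt(best)
}

nearest_distances_ring <- function(points, polyline, buckets, x0, y0, cell) {
  np <- nrow(points)
  if (np == 0L) return(numeric())
  key <- function(ix, iy) paste(ix, iy)
  qix <- floor((points[, 1] - x0) / cell)
  qiy <- floor((points[, 2] - y0) / cell)
  out <- numeric(np)
  max_ring <- ceiling(max(diff(range(polyline[, 1])),
                          diff(range(polyline[, 2]))) / cell) + 2L
  for (q in seq_len(np)) {
    best <- Inf
    r <- 0L
    repeat {
      ring <- if (r == 0L) cbind(qix[q], qiy[q]) else {
        d <- -r:r
        unique(rbind(cbind(qix[q] + d, qiy[q] - r),
                     cbind(qix[q] + d, qiy[q] + r),
                     cbind(qix[q] - r, qiy[q] + d),
                     cbind(qix[q] + r, qiy[q] + d)))
      }
      idx <- unlist(buckets[key(ring[, 1], ring[, 2])], use.names = FALSE)
      if (length(idx)) {
        d2 <- (polyline[idx, 1] - points[q, 1])^2 +
          (polyline[idx, 2] - points[q, 2])^2
        best <- min(best, min(d2))
      }
      # any point outside ring r is at least (r * cell) away
      if ((is.finite(best) && best <= (r * cell)^2) || r > max_ring) break
      r <- r + 1L
    }
    out[q] <- sqrt(best)
  }
  out
}

#' Interpolation error against the true centreline
#'
#' Distance from each interpolated point to the nearest point of the densely
#' sampled ground-truth centreline.
#'
#' @param points matrix or data.frame with columns `x`, `y` (um).
#' @param centreline dense centreline matrix (um), e.g. from
#'   [tree_centreline()] at spacing <= 1 um.
#' @return list with per-point `distances` (um) and their `mean`.
#' @export
interpolation_error <- function(points, centreline) {
  points <- as.data.frame(points)
  if (nrow(points) == 0L) stop("no interpolated points supplied")
  if (NROW(centreline) == 0L) stop("empty centreline")
  d <- nearest_distances(cbind(points$x, points$y), centreline)
  list(distances = d, mean = mean(d))
}

#' Velocity estimation error against ground truth
#'
#' Matches each track state to the simulator's true per-frame velocity via
#' the detection it consumed (states whose detections carry no ground-truth
#' identity are skipped) and averages the Euclidean velocity error.
#' The first `skip_initial` states of each track (the initialisation
#' transient) can be excluded.
#'
#' @param fit an `ulm_tracks` object.
#' @param scene the `ulm_scene` the detections came from.
#' @param skip_initial number of leading states per track to exclude.
#' @return list with per-state `errors` (mm/s) and their `mean` (NA when no
#'   state could be matched).
#' @export
velocity_error <- function(fit, scene, skip_initial = 0L) {
  stopifnot(inherits(fit, "ulm_tracks"), inherits(scene, "ulm_scene"))
  tr <- fit$tracks
  if (nrow(tr) == 0L) return(list(errors = numeric(), mean = NA_real_))
  if (skip_initial > 0L) {
    keep <- unlist(lapply(split(seq_len(nrow(tr)), tr$track_id),
                          function(i) i[-seq_len(min(skip_initial,
                                                     length(i)))]))
    tr <- tr[sort(keep), , drop = FALSE]
    if (nrow(tr) == 0L) return(list(errors = numeric(), mean = NA_real_))
  }
  td <- scene$truth$detections
  m <- match(tr$det_index, td$det_index)
  ok <- !is.na(m)
  if (!any(ok)) return(list(errors = numeric(), mean = NA_real_))
  err <- sqrt((tr$vx_mm_s[ok] - td$vx_true[m[ok]])^2 +
                (tr$vy_mm_s[ok] - td$vy_true[m[ok]])^2)
  list(errors = err, mean = mean(err))
}

#' Structural similarity index between two maps
#'
#' Standard SSIM with a Gaussian window (sigma 1.5 px, 11 x 11 support) and
#' constants `K1 = 0.01`, `K2 = 0.03`; the dynamic range is the joint
#' value range of both images.  Non-finite pixels are treated as 0.
#'
#' @param a,b `ulm_map` objects or numeric matrices of identical shape.
#' @return mean SSIM, a scalar in \[-1, 1\].
#' @export
map_ssim <- function(a, b) {
  A <- if (inherits(a, "ulm_map")) a$grid else as.matrix(a)
  B <- if (inherits(b, "ulm_map")) b$grid else as.matrix(b)
  if (!all(dim(A) == dim(B))) stop("maps must have identical shape")
  A[!is.finite(A)] <- 0
  B[!is.finite(B)] <- 0
  L <- max(A, B) - min(A, B)
  if (L == 0) return(1)
  C1 <- (0.01 * L)^2
  C2 <- (0.03 * L)^2
  w <- gaussian_kernel(1.5, 11L)
  muA <- conv2_sep(A, w); muB <- conv2_sep(B, w)
  sA <- conv2_sep(A * A, w) - muA^2
  sB <- conv2_sep(B * B, w) - muB^2
  sAB <- conv2_sep(A * B, w) - muA * muB
  ssim <- ((2 * muA * muB + C1) * (2 * sAB + C2)) /
    ((muA^2 + muB^2 + C1) * (sA + sB + C2))
  mean(ssim)
}

gaussian_kernel <- function(sigma, size) {
  half <- (size - 1L) / 2
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable 2-D convolution with replicated (clamped) borders.
conv2_sep <- function(m, w) {
  half <- (length(w) - 1L) / 2
  ri <- pmin(nrow(m), pmax(1L, seq.int(1L - half, nrow(m) + half)))
  ci <- pmin(ncol(m), pmax(1L, seq.int(1L - half, ncol(m) + half)))
  mp <- m[ri, ci, drop = FALSE]
  # convolve along rows then columns
  out <- apply(mp, 2L, function(col) stats::filter(col, w, sides = 2L))
  out <- t(apply(out, 1L, function(row) stats::filter(row, w, sides = 2L)))
  out[half + seq_len(nrow(m)), half + seq_len(ncol(m)), drop = FALSE]
}

#' Image resolution by Fourier ring correlation
#'
#' Splits the tracks alternately into two halves, renders a density map
#' from each, and correlates the two maps ring by ring in the Fourier
#' domain.  The resolution is the inverse of the first spatial frequency at
#' which the FRC curve falls below the half-bit information threshold.
#'
#' @param fit an `ulm_tracks` object.
#' @param pixel_size rendering pixel size (um).
#' @return list with `resolution_um` (NA when the curve never crosses the
#'   threshold), `freq` (cycles/um), `frc`, and `threshold`.
#' @export
frc_resolution <- function(fit, pixel_size = 10) {
  ids <- unique(fit$tracks$track_id)
  if (length(ids) < 2L) stop("need at least two tracks for an FRC split")
  half1 <- ids[seq_along(ids) %% 2L == 1L]
  sub_tracks <- function(keep) {
    f <- fit
    f$tracks <- fit$tracks[fit$tracks$track_id %in% keep, , drop = FALSE]
    f
  }
  all_pts <- interpolate_tracks(fit, pixel_size / 2, per = NULL)$points
  extent <- list(xlim = range(all_pts$x), ylim = range(all_pts$y))
  m1 <- accumulate_map(sub_tracks(half1), "density", pixel_size, extent)
  m2 <- accumulate_map(sub_tracks(setdiff(ids, half1)), "density",
                       pixel_size, extent)
  frc_from_maps(m1$grid, m2$grid, pixel_size)
}

# Ring-wise Fourier correlation of two equally shaped images.
frc_from_maps <- function(g1, g2, pixel_size) {
  n <- min(dim(g1))
  g1 <- g1[seq_len(n), seq_len(n), drop = FALSE]
  g2 <- g2[seq_len(n), seq_len(n), drop = FALSE]
  F1 <- stats::fft(g1)
  F2 <- stats::fft(g2)
  fx <- c(seq(0, floor(n / 2)), seq(-(n - floor(n / 2) - 1L), -1L)) / n
  R <- sqrt(outer(fx^2, fx^2, "+"))
  ring <- pmin(floor(R * n) + 1L, floor(n / 2))
  nr <- floor(n / 2)
  num <- tapply(Re(F1 * Conj(F2)), ring, sum)
  d1 <- tapply(abs(F1)^2, ring, sum)
  d2 <- tapply(abs(F2)^2, ring, sum)
  cnt <- tapply(rep(1, length(ring)), ring, sum)
  rings <- as.integer(names(num))
  keep <- rings <= nr
  frc <- as.numeric(num[keep]) / sqrt(as.numeric(d1[keep]) *
                                        as.numeric(d2[keep]))
  npx <- as.numeric(cnt[keep])
  thr <- (0.2071 + 1.9102 / sqrt(npx)) / (1.2071 + 0.9102 / sqrt(npx))
  freq <- (rings[keep] - 0.5) / (n * pixel_size)  # cycles per um
  below <- which(frc < thr)
  res <- if (length(below)) 1 / freq[below[1L]] else NA_real_
  list(resolution_um = res, freq = freq, frc = frc, threshold = thr)
}

# Chord (straight-line) interpolation points for every track segment:
# zero-acceleration path whose constant velocity is the chord velocity.
chord_interp_points <- function(fit, spacing = 10) {
  tr <- fit$tracks
  dt <- fit$config$dt
  out <- list()
  for (id in unique(tr$track_id)) {
    h <- tr[tr$track_id == id, , drop = FALSE]
    if (nrow(h) < 2L) next
    for (s in seq_len(nrow(h) - 1L)) {
      p1 <- c(h$x_um[s], h$y_um[s])
      p2 <- c(h$x_um[s + 1L], h$y_um[s + 1L])
      gap <- (h$frame[s + 1L] - h$frame[s]) * dt
      seg <- interpolate_segment(p1, (p2 - p1) / gap, c(0, 0), gap, spacing)
      out[[length(out) + 1L]] <- unclass(seg)[, c("x", "y"), drop = FALSE]
    }
  }
  as.data.frame(do.call(rbind, out))
}

#' Single-vessel interpolation and velocity-error study
#'
#' Reproduces the three-way trajectory-reconstruction comparison on
#' single-vessel constant-speed scenes: acceleration-based nonlinear
#' interpolation on nonlinear-model tracking, nonlinear interpolation on
#' linear-model tracking, and straight-chord interpolation on linear-model
#' tracking, each scored by mean distance to the true centreline; plus the
#' mean velocity-estimation error of both motion models.
#'
#' The tracker's process noise is matched to the scene dynamics: at the
#' study speed the centripetal acceleration `v^2 / R` on the tightest bends
#' reaches a few hundred mm/s^2, so `sigma_a` defaults to 300 mm/s^2 here
#' (a single bubble is in the vessel at a time, making the wider gate
#' harmless).
#'
#' Six vessel replicates are generated (the study design) and errors are
#' averaged across them per frame rate.
#'
#' @param frame_rates acquisition frame rates to test (Hz).
#' @param seeds scene seeds, one vessel per seed (default six vessels).
#' @param duration seconds of acquisition per rate.
#' @param sigma_a tracker process noise for this study (mm/s^2).
#' @param spacing interpolation spacing for error evaluation (um).
#' @return data.frame with one row per frame rate: across-vessel mean
#'   centreline errors `err_nonlinear`, `err_nl_on_linear`, `err_linear`
#'   (um) and mean velocity errors `vel_err_accel`, `vel_err_linear`
#'   (mm/s).
#' @export
interpolation_study <- function(frame_rates = c(15, 25, 35), seeds = 1:6,
                                duration = 30, sigma_a = 300,
                                spacing = 10) {
  rows <- list()
  for (fr in frame_rates) {
    for (sd in seeds) {
      scene <- make_interpolation_scene(fr, seed = sd, duration = duration)
      cl <- tree_centreline(scene$tree, spacing = 1)
      fa <- mb_track(scene$detections,
                     config = kalman_config(fr, model = "accel",
                                            sigma_a = sigma_a))
      fl <- mb_track(scene$detections,
                     config = kalman_config(fr, model = "linear",
                                            sigma_a = sigma_a))
      pa <- interpolate_tracks(fa, spacing, per = NULL)$points
      pl <- interpolate_tracks(fl, spacing, per = NULL)$points
      pc <- chord_interp_points(fl, spacing)
      rows[[length(rows) + 1L]] <- data.frame(
        frame_rate = fr, seed = sd,
        err_nonlinear = interpolation_error(pa, cl)$mean,
        err_nl_on_linear = interpolation_error(pl, cl)$mean,
        err_linear = interpolation_error(pc, cl)$mean,
        vel_err_accel = velocity_error(fa, scene, skip_initial = 2L)$mean,
        vel_err_linear = velocity_error(fl, scene, skip_initial = 2L)$mean)
    }
  }
  det <- do.call(rbind, rows)
  agg <- aggregate(det[, c("err_nonlinear", "err_nl_on_linear", "err_linear",
                           "vel_err_accel", "vel_err_linear")],
                   by = list(frame_rate = det$frame_rate), FUN = mean)
  agg[order(agg$frame_rate), , drop = FALSE]
}

#' Half wavelength of the transmitted ultrasound
#'
#' The diffraction-limited resolution scale `c / f / 2`.
#'
#' @param frequency_hz centre frequency (Hz).
#' @param sound_speed speed of sound (m/s).
#' @return half wavelength in um.
#' @export
half_wavelength_um <- function(frequency_hz, sound_speed = 1540) {
  sound_speed / frequency_hz / 2 * 1e6
}

#' Effective frame rate after temporal downsampling
#'
#' Extracting every `factor`-th frame from an acquisition divides the frame
#' rate accordingly (e.g. a 100 Hz dataset split into 4 interleaved
#' subgroups is tracked at 25 Hz).
#'
#' @param frame_rate original acquisition rate (Hz).
#' @param factor integer downsampling factor (>= 1).
#' @return effective frame rate (Hz).
#' @export
downsampled_rate <- function(frame_rate, factor) {
  if (factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer")
  frame_rate / factor
}

#' Enumerate the full simulation benchmark grid
#'
#' The full study grid crosses vessel-tree replicates, acquisition frame
#' rates, microbubble concentrations and peak flow accelerations; the
#' `"smoke"` grid is a two-setting miniature for pipeline checks.
#'
#' @param grid `"paper"` (10 trees x 3 rates x 3 concentrations x 4
#'   accelerations = 360 settings) or `"smoke"`.
#' @return data.frame with columns `tree_seed`, `frame_rate`,
#'   `concentration`, `acceleration`.
#' @export
benchmark_grid <- function(grid = c("paper", "smoke")) {
  grid <- match.arg(grid)
  if (grid == "paper") {
    expand.grid(tree_seed = 1:10,
                frame_rate = c(15, 25, 35),
                concentration = c(2.54e7, 3.82e7, 6.36e7),
                acceleration = c(0, 37.5, 75, 112.5),
                KEEP.OUT.ATTRS = FALSE)
  } else {
    expand.grid(tree_seed = 1:2,
                frame_rate = c(15, 35),
                concentration = 3.82e7,
                acceleration = c(0, 112.5),
                KEEP.OUT.ATTRS = FALSE)[1:4, ]
  }
}

#' Run the simulate-track-evaluate benchmark
#'
#' For every row of a settings grid and both motion models, simulates a
#' pulsatile branching-tree scene, tracks it, and scores the produced pairs
#' against ground truth.
#'
#' @param settings data.frame like [benchmark_grid()] output; each row is
#'   one scene configuration.
#' @param models character vector among `"accel"`, `"linear"`.
#' @param duration scene duration in seconds (reduced from the full-study
#'   30 s for bounded runtimes).
#' @param seed base seed; each row/model derives its own child seed.
#' @return data.frame with one row per setting x model carrying `TP`, `FP`,
#'   `FN`, `tpr`, `fnr`.
#' @export
run_benchmark <- function(settings, models = c("accel", "linear"),
                          duration = 10, seed = 1L) {
  rows <- list()
  for (r in seq_len(nrow(settings))) {
    st <- settings[r, ]
    child <- (seed * 1000L + r * 7L) %% .Machine$integer.max
    tree <- make_vessel_tree("branching", seed = st$tree_seed)
    flow <- flow_profile(s0 = 3, a_max = st$acceleration, heart_rate = 75)
    scene <- simulate_scene(tree, flow, st$frame_rate, duration,
                            concentration = st$concentration, seed = child)
    for (mdl in models) {
      fit <- mb_track(scene$detections,
                      config = kalman_config(st$frame_rate, model = mdl))
      cf <- confusion(fit$pairs, scene)
      rows[[length(rows) + 1L]] <- data.frame(
        st, model = mdl, seed = child, TP = cf$TP, FP = cf$FP, FN = cf$FN,
        tpr = cf$tpr, fnr = cf$fnr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
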