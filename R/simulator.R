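# Synthetic pulsatile microvasculature scenes with ground-truth identities.
#
# Vessel geometry is generated procedurally from seeded smooth curvature
# processes (the field publishes no coordinates); microbubbles enter vessel
# inlets as a Poisson process, advance along the centreline by the
# integrated pulsatile speed law, and are emitted per frame with Gaussian
# localisation jitter.

# Evaluate code with a locally seeded RNG, restoring the caller's state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pulsatile flow speed profile
#'
#' A periodic raised-cosine systolic pulse
#' `s(t) = s_base + A * (0.5 * (1 - cos(2 pi t / T)))^q` with period
#' `T = 60 / heart_rate`.  The amplitude `A`, exponent `q` and baseline
#' `s_base` are solved numerically so that the time-mean speed equals `s0`
#' and the peak speed change rate `max |ds/dt|` equals `a_max`, with the
#' baseline floored at `0.2 * s0` so the speed never approaches zero.  A
#' plain sinusoid cannot reach high peak accelerations around a low mean
#' speed without going negative, which is why the pulse sharpens (`q`
#' grows) as `a_max` rises.
#'
#' @param s0 time-mean speed (mm/s, > 0).
#' @param a_max peak acceleration `max |ds/dt|` (mm/s^2, >= 0).
#' @param heart_rate cardiac frequency (beats per minute).
#' @param phase phase offset (radians).
#' @return object of class `flow_profile`.
#' @examples
#' fp <- flow_profile(s0 = 3, a_max = 112.5, heart_rate = 75)
#' speed_at(fp, seq(0, 0.8, by = 0.1))
#' @export
flow_profile <- function(s0 = 3, a_max = 0, heart_rate = 75, phase = 0) {
  if (s0 <= 0) stop("'s0' must be positive")
  if (a_max < 0) stop("'a_max' must be non-negative")
  if (heart_rate <= 0) stop("'heart_rate' must be positive")
  period <- 60 / heart_rate                 # s
  omega <- 2 * pi / period                  # rad/s
  tg <- seq(0, period, length.out = 4001L)
  pulse_mean <- function(q) mean((0.5 * (1 - cos(omega * tg)))^q)
  pulse_maxd <- function(q) {
    w <- 0.5 * (1 - cos(omega * tg))
    max(abs(q * w^pmax(q - 1, 0) * 0.5 * omega * sin(omega * tg)))
  }
  if (a_max == 0) {
    A <- 0; q <- 1; s_base <- s0
  } else if (a_max <= 0.8 * s0 * omega / 2 * 2) {  # reachable at q = 1
    q <- 1
    A <- 2 * a_max / omega
    s_base <- s0 - A / 2
  } else {
    s_base <- 0.2 * s0
    f <- function(q) (0.8 * s0 / pulse_mean(q)) * pulse_maxd(q) - a_max
    q <- stats::uniroot(f, c(1, 2000), tol = 1e-10)$root
    A <- 0.8 * s0 / pulse_mean(q)
  }
  structure(list(s0 = s0, a_max = a_max, heart_rate = heart_rate,
                 phase = phase, period = period, A = A, q = q,
                 s_base = s_base),
            class = "flow_profile")
}

#' Instantaneous flow speed
#'
#' @param flow a [flow_profile()].
#' @param t time in seconds (vectorised, >= 0).
#' @return speed in mm/s.
#' @export
speed_at <- function(flow, t) {
  stopifnot(inherits(flow, "flow_profile"))
  omega <- 2 * pi / flow$period
  te <- t + flow$phase / omega
  flow$s_base + flow$A * (0.5 * (1 - cos(omega * te)))^flow$q
}

#' @export
print.flow_profile <- function(x, ...) {
  cat(sprintf(
    "Pulsatile flow: mean %g mm/s, peak |ds/dt| %g mm/s^2, %g bpm\n",
    x$s0, x$a_max, x$heart_rate))
  cat(sprintf("  baseline %.3g mm/s, pulse amplitude %.3g mm/s, exponent %.3g\n",
              x$s_base, x$A, x$q))
  invisible(x)
}

# Smooth random curve: integrate a piecewise-linear random curvature
# process.  start: length-2 (um); heading0: rad; len: um; r_min: minimum
# curvature radius (um); step: polyline step (um).
random_curve <- function(start, heading0, len, r_min, step = 5,
                         knot_spacing = 500, kappa_knots = NULL) {
  n <- ceiling(len / step)
  s_knots <- seq(0, len, length.out = max(3L, ceiling(len / knot_spacing) + 1L))
  k_knots <- if (is.null(kappa_knots))
    stats::runif(length(s_knots), -1 / r_min, 1 / r_min)
  else rep_len(kappa_knots, length(s_knots))
  s <- seq(0, len, length.out = n + 1L)
  kappa <- stats::approx(s_knots, k_knots, xout = s, rule = 2)$y
  theta <- heading0 + c(0, cumsum((kappa[-1] + kappa[-length(kappa)]) / 2 *
                                    diff(s)))
  x <- start[1] + c(0, cumsum(cos(theta[-1]) * diff(s)))
  y <- start[2] + c(0, cumsum(sin(theta[-1]) * diff(s)))
  cbind(x = x, y = y)
}

polyline_arc <- function(pts) {
  c(0, cumsum(sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)))
}

#' Generate a synthetic vessel tree
#'
#' `"branching"` builds two main vessels that each split into three
#' downstream child vessels (eight segments); `"single"` builds one
#' tortuous vessel.  Geometry is a seeded smooth random-curvature process,
#' so the same seed always yields the same tree.
#'
#' @param kind `"branching"` or `"single"`.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param main_length,child_length centreline lengths (um).
#' @param r_min_range minimum-curvature-radius range (um); curvature is
#'   bounded by `1 / min(r_min_range)` with the per-segment bound drawn
#'   from the range.
#' @param single_length length of the single tortuous vessel (um).
#' @return object of class `vessel_tree`: list of `segments`, each with
#'   `id`, `parent` (0 for a root), `points` (polyline, um) and `arc`
#'   (cumulative arc length).
#' @export
make_vessel_tree <- function(kind = c("branching", "single"), seed = NULL,
                             main_length = 3000, child_length = 3000,
                             r_min_range = c(1500, 10000),
                             single_length = 14000) {
  kind <- match.arg(kind)
  with_seed(seed, {
    segs <- list()
    if (kind == "branching") {
      starts <- list(c(0, 1000), c(0, 2400))
      headings <- stats::runif(2, -0.15, 0.15)
      id <- 0L
      for (mi in 1:2) {
        id <- id + 1L
        rmin <- stats::runif(1, r_min_range[1] * 2, r_min_range[2])
        pts <- random_curve(starts[[mi]], headings[mi], main_length, rmin)
        segs[[id]] <- list(id = id, parent = 0L, points = pts,
                           arc = polyline_arc(pts))
        main_id <- id
        endp <- pts[nrow(pts), ]
        dirv <- pts[nrow(pts), ] - pts[nrow(pts) - 1L, ]
        end_heading <- atan2(dirv[2], dirv[1])
        offs <- c(-0.55, 0, 0.55) + stats::runif(3, -0.1, 0.1)
        for (ci in 1:3) {
          id <- id + 1L
          rmin <- stats::runif(1, r_min_range[1], r_min_range[2])
          cpts <- random_curve(endp, end_heading + offs[ci], child_length,
                               rmin)
          segs[[id]] <- list(id = id, parent = main_id, points = cpts,
                             arc = polyline_arc(cpts))
        }
      }
    } else {
      # persistently curved tortuous path: curvature varies slowly (knots
      # every ~4 mm) and is bounded away from zero, giving the smooth
      # S-shaped bends over several frame steps that distinguish chord
      # from quadratic interpolation
      rmin <- stats::runif(1, 2000, 5000)
      nk <- max(3L, ceiling(single_length / 4000) + 1L)
      kappa <- sample(c(-1, 1), nk, replace = TRUE) *
        stats::runif(nk, 0.4, 1) / rmin
      pts <- random_curve(c(0, 1500), stats::runif(1, -0.2, 0.2),
                          single_length, rmin, knot_spacing = 4000,
                          kappa_knots = kappa)
      segs[[1]] <- list(id = 1L, parent = 0L, points = pts,
                        arc = polyline_arc(pts))
    }
    structure(list(segments = segs, kind = kind), class = "vessel_tree")
  })
}

#' @export
print.vessel_tree <- function(x, ...) {
  lens <- vapply(x$segments, function(s) max(s$arc), numeric(1))
  cat(sprintf("Vessel tree (%s): %d segments, total centreline %.1f mm\n",
              x$kind, length(x$segments), sum(lens) / 1000))
  invisible(x)
}

# Total centreline length (um) and lumen volume (mL) at a given diameter.
tree_length_um <- function(tree)
  sum(vapply(tree$segments, function(s) max(s$arc), numeric(1)))

tree_volume_ml <- function(tree, diameter = 50)
  tree_length_um(tree) * pi * (diameter / 2)^2 * 1e-12  # um^3 -> mL

# All root-to-leaf routes as concatenated polylines with cumulative arc.
tree_routes <- function(tree) {
  segs <- tree$segments
  parents <- vapply(segs, `[[`, integer(1), "parent")
  leaves <- setdiff(vapply(segs, `[[`, integer(1), "id"), parents)
  routes <- list()
  for (leaf in leaves) {
    chain <- integer()
    cur <- leaf
    while (cur != 0L) {
      chain <- c(cur, chain)
      cur <- segs[[cur]]$parent
    }
    pts <- segs[[chain[1]]]$points
    if (length(chain) > 1L) for (ci in chain[-1L])
      pts <- rbind(pts, segs[[ci]]$points[-1L, , drop = FALSE])
    routes[[length(routes) + 1L]] <-
      list(chain = chain, points = pts, arc = polyline_arc(pts),
           root = chain[1])
  }
  routes
}

#' Simulate a localisation dataset from a vessel tree and flow profile
#'
#' Microbubbles arrive at vessel inlets as a Poisson process whose rate is
#' set so that the expected number of concurrently present bubbles equals
#' `concentration * lumen volume` (cylindrical lumen of the given
#' diameter).  Each bubble advances along a root-to-leaf route (branch
#' chosen uniformly) by the time integral of the pulsatile speed, and is
#' emitted once per frame with isotropic Gaussian localisation jitter.
#' All randomness is fixed by `seed`.
#'
#' @param tree a [make_vessel_tree()] result.
#' @param flow a [flow_profile()].
#' @param frame_rate acquisition frame rate (Hz).
#' @param duration acquisition duration (s).
#' @param concentration microbubble concentration (MB/mL); ignored when
#'   `n_expected` is given.
#' @param detectable_fraction fraction of circulating bubbles that are
#'   isolated enough to be localised in any one frame.  Localisation
#'   microscopy only resolves sparse, well-separated bubbles, so the
#'   expected concurrent count is `concentration * lumen volume *
#'   detectable_fraction`.
#' @param n_expected expected number of concurrently present bubbles
#'   (overrides `concentration`).
#' @param sigma_loc localisation noise standard deviation (um).
#' @param diameter lumen diameter used for the concentration-to-count
#'   conversion (um).
#' @param p_miss per-frame missed-detection probability.
#' @param min_separation resolvability limit (um): bubbles closer than this
#'   to another bubble in the same frame are not localised (their echoes
#'   overlap within the point spread function and the pair is rejected by
#'   isolated-bubble localisation).  Default is the diffraction scale of a
#'   5 MHz transmit (about a half wavelength).  Set to 0 to disable.
#' @param one_at_a_time if `TRUE`, bubbles enter one by one, each only
#'   after the previous one has left the vessel (interpolation-study
#'   design).
#' @param seed integer seed.
#' @return object of class `ulm_scene`: list with `detections` (data.frame
#'   `frame, x_um, y_um, truth_id`, frame-sorted, with `det_index`),
#'   `truth` (list with per-detection true positions/velocities and the
#'   table of true consecutive-frame pairs), plus the generating `tree`,
#'   `flow` and parameters.
#' @export
simulate_scene <- function(tree, flow, frame_rate, duration,
                           concentration = NULL, detectable_fraction = 2e-3,
                           n_expected = NULL,
                           sigma_loc = 10, diameter = 50, p_miss = 0,
                           min_separation = 150, one_at_a_time = FALSE,
                           seed = 1L) {
  stopifnot(inherits(tree, "vessel_tree"), inherits(flow, "flow_profile"))
  if (frame_rate <= 0 || duration <= 0)
    stop("'frame_rate' and 'duration' must be positive")
  if (is.null(n_expected)) {
    if (is.null(concentration))
      stop("supply 'concentration' or 'n_expected'")
    n_expected <- concentration * tree_volume_ml(tree, diameter) *
      detectable_fraction
  }
  with_seed(seed, {
    routes <- tree_routes(tree)
    roots <- unique(vapply(routes, `[[`, integer(1), "root"))
    route_root <- vapply(routes, `[[`, integer(1), "root")
    route_len <- vapply(routes, function(r) max(r$arc), numeric(1))
    mean_transit_ms <- mean(route_len) / flow$s0  # um / (um/ms)
    dur_ms <- duration * 1000
    dt_ms <- 1000 / frame_rate

    # cumulative travelled arc length C(t) on a fine grid (0.5 ms)
    t0_min <- -1.5 * max(route_len) / flow$s0
    tg <- seq(t0_min, dur_ms, by = 0.5)
    sp <- speed_at(flow, tg / 1000)        # mm/s = um/ms
    Cg <- c(0, cumsum((sp[-1] + sp[-length(sp)]) / 2 * diff(tg)))
    C <- function(t_ms) stats::approx(tg, Cg, xout = t_ms,
                                      ties = "ordered")$y

    # arrivals
    if (one_at_a_time) {
      arrivals <- numeric()
      t0 <- 0
      while (t0 < dur_ms) {
        arrivals <- c(arrivals, t0)
        ridx <- length(arrivals)  # route assigned later
        # exit time: first t with C(t) - C(t0) >= route length (use mean len)
        t0 <- t0 + mean(route_len) / flow$s0 + dt_ms
      }
    } else {
      rate_per_ms <- n_expected / mean_transit_ms
      span <- dur_ms - t0_min
      n_arr <- stats::rpois(1L, rate_per_ms * span)
      if (rate_per_ms * span < 1)
        warning("expected fewer than one microbubble over the run")
      arrivals <- sort(stats::runif(n_arr, t0_min, dur_ms))
    }

    n_frames <- as.integer(round(duration * frame_rate))
    frame_t <- (seq_len(n_frames) - 1L) * dt_ms

    det <- list(); tru <- list()
    for (mb in seq_along(arrivals)) {
      t0 <- arrivals[mb]
      # choose a route whose root is picked uniformly among inlets, then
      # uniform among that root's routes (uniform branch choice)
      root <- if (length(roots) == 1L) roots else sample(roots, 1L)
      cand <- which(route_root == root)
      ridx <- if (length(cand) == 1L) cand else sample(cand, 1L)
      rt <- routes[[ridx]]
      L <- max(rt$arc)
      fidx <- which(frame_t >= t0)
      if (!length(fidx)) next
      s_mb <- C(frame_t[fidx]) - C(t0)
      inside <- s_mb >= 0 & s_mb <= L
      fidx <- fidx[inside]; s_mb <- s_mb[inside]
      if (!length(fidx)) next
      px <- stats::approx(rt$arc, rt$points[, 1], xout = s_mb,
                          ties = "ordered")$y
      py <- stats::approx(rt$arc, rt$points[, 2], xout = s_mb,
                          ties = "ordered")$y
      # unit tangent by finite differences along the polyline
      eps <- 1
      sp1 <- pmin(s_mb + eps, L); sp0 <- pmax(s_mb - eps, 0)
      txv <- stats::approx(rt$arc, rt$points[, 1], xout = sp1)$y -
        stats::approx(rt$arc, rt$points[, 1], xout = sp0)$y
      tyv <- stats::approx(rt$arc, rt$points[, 2], xout = sp1)$y -
        stats::approx(rt$arc, rt$points[, 2], xout = sp0)$y
      tn <- sqrt(txv^2 + tyv^2)
      txv <- txv / tn; tyv <- tyv / tn
      spd <- speed_at(flow, frame_t[fidx] / 1000)
      kept <- if (p_miss > 0) stats::runif(length(fidx)) >= p_miss else
        rep(TRUE, length(fidx))
      if (!any(kept)) next
      det[[length(det) + 1L]] <- data.frame(
        frame = fidx[kept] - 1L,
        x_um = px[kept] + stats::rnorm(sum(kept), 0, sigma_loc),
        y_um = py[kept] + stats::rnorm(sum(kept), 0, sigma_loc),
        truth_id = mb)
      tru[[length(tru) + 1L]] <- data.frame(
        frame = fidx[kept] - 1L, truth_id = mb,
        x_true = px[kept], y_true = py[kept],
        vx_true = txv[kept] * spd[kept], vy_true = tyv[kept] * spd[kept])
    }
    detections <- if (length(det)) do.call(rbind, det) else
      data.frame(frame = integer(), x_um = numeric(), y_um = numeric(),
                 truth_id = integer())
    truth_det <- if (length(tru)) do.call(rbind, tru) else
      data.frame(frame = integer(), truth_id = integer(),
                 x_true = numeric(), y_true = numeric(),
                 vx_true = numeric(), vy_true = numeric())
    ord <- order(detections$frame, detections$truth_id)
    detections <- detections[ord, , drop = FALSE]
    truth_det <- truth_det[ord, , drop = FALSE]
    if (min_separation > 0 && nrow(detections) > 1L) {
      keep <- rep(TRUE, nrow(detections))
      for (fr_rows in split(seq_len(nrow(detections)), detections$frame)) {
        if (length(fr_rows) < 2L) next
        xy <- cbind(truth_det$x_true[fr_rows], truth_det$y_true[fr_rows])
        dm <- as.matrix(stats::dist(xy))
        diag(dm) <- Inf
        keep[fr_rows[apply(dm, 1L, min) < min_separation]] <- FALSE
      }
      detections <- detections[keep, , drop = FALSE]
      truth_det <- truth_det[keep, , drop = FALSE]
    }
    rownames(detections) <- rownames(truth_det) <- NULL
    detections$det_index <- seq_len(nrow(detections))
    truth_det$det_index <- seq_len(nrow(truth_det))
    pairs <- true_pairs(detections)
    structure(list(detections = detections,
                   truth = list(detections = truth_det, pairs = pairs),
                   tree = tree, flow = flow, frame_rate = frame_rate,
                   duration = duration, sigma_loc = sigma_loc,
                   n_expected = n_expected, seed = seed,
                   n_frames = n_frames),
              class = "ulm_scene")
  })
}

# True consecutive-frame pairs: same truth_id present in frames k and k+1.
true_pairs <- function(detections) {
  d <- detections
  if (nrow(d) < 2L)
    return(data.frame(frame_k = integer(), det_k = integer(),
                      det_k1 = integer(), truth_id = integer()))
  nxt <- merge(
    data.frame(frame_k = d$frame, truth_id = d$truth_id, det_k = d$det_index),
    data.frame(frame_k = d$frame - 1L, truth_id = d$truth_id,
               det_k1 = d$det_index),
    by = c("frame_k", "truth_id"))
  nxt <- nxt[order(nxt$frame_k, nxt$det_k), c("frame_k", "det_k", "det_k1",
                                              "truth_id")]
  rownames(nxt) <- NULL
  nxt
}

#' @export
print.ulm_scene <- function(x, ...) {
  cat(sprintf(
    "Simulated ULM scene: %d detections over %d frames at %g Hz\n",
    nrow(x$detections), x$n_frames, x$frame_rate))
  cat(sprintf("  %d ground-truth bubbles, %d true consecutive-frame pairs\n",
              length(unique(x$detections$truth_id)), nrow(x$truth$pairs)))
  cat(sprintf("  flow: mean %g mm/s, peak accel %g mm/s^2; sigma_loc %g um\n",
              x$flow$s0, x$flow$a_max, x$sigma_loc))
  invisible(x)
}

#' Single-vessel interpolation study scene
#'
#' One tortuous vessel traversed by one microbubble at a time at a constant
#' 30 mm/s, imaged for 60 s -- the design used to compare linear and
#' acceleration-based nonlinear trajectory interpolation.
#'
#' @param frame_rate acquisition frame rate (Hz), typically 15, 25 or 35.
#' @param seed integer seed for the vessel geometry and noise.
#' @param duration acquisition duration (s).
#' @param sigma_loc localisation noise (um).
#' @param speed constant bubble speed (mm/s).
#' @return an `ulm_scene`.
#' @export
make_interpolation_scene <- function(frame_rate, seed = 1L, duration = 60,
                                     sigma_loc = 10, speed = 30) {
  tree <- make_vessel_tree("single", seed = seed)
  flow <- flow_profile(s0 = speed, a_max = 0)
  simulate_scene(tree, flow, frame_rate, duration,
                 n_expected = 1, sigma_loc = sigma_loc,
                 one_at_a_time = TRUE, seed = seed + 1L)
}

#' Densely resampled ground-truth centreline
#'
#' @param tree a `vessel_tree`.
#' @param spacing sample spacing along each segment (um).
#' @return matrix with columns `x`, `y` (um).
#' @export
tree_centreline <- function(tree, spacing = 1) {
  pts <- lapply(tree$segments, function(sg) {
    s <- seq(0, max(sg$arc), by = spacing)
    cbind(x = stats::approx(sg$arc, sg$points[, 1], xout = s)$y,
          y = stats::approx(sg$arc, sg$points[, 2], xout = s)$y)
  })
  do.call(rbind, pts)
}
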