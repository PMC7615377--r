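# Track lifecycle and frame-to-frame association.
#
# The tracker processes localisation tables frame by frame: active tracks
# are predicted forward, associated to detections by minimum-total-cost
# one-to-one assignment under a Mahalanobis gate, corrected by the Kalman
# update, and terminated after too many consecutive misses.  Detections that
# no track claims are pooled over three consecutive frames and routed
# through the triplet assignment to seed new tracks with an initial
# velocity and acceleration.

#' Associate predicted tracks with detections in one frame
#'
#' Builds the gated Gaussian-likelihood cost matrix between predicted track
#' states and detections and solves the one-to-one assignment minimising the
#' total pairing cost; pairs whose squared Mahalanobis distance exceeds
#' `cfg$gate_chi2` are forbidden.
#'
#' @param predicted list of predicted `motion_state`s (one per active track).
#' @param detections `n x 2` matrix of detected positions (um).
#' @param cfg a `kalman_config`.
#' @return list of class `frame_pairing` with `pairs` (matrix: track index,
#'   detection index), `unmatched_tracks`, `unmatched_detections`, and
#'   `total_cost`.
#' @export
associate_frame <- function(predicted, detections, cfg) {
  detections <- as.matrix(detections)
  nT <- length(predicted)
  nD <- nrow(detections)
  if (nT == 0L || nD == 0L) {
    return(structure(list(pairs = matrix(integer(), 0L, 2L),
                          unmatched_tracks = seq_len(nT),
                          unmatched_detections = seq_len(nD),
                          total_cost = 0), class = "frame_pairing"))
  }
  cost <- matrix(Inf, nT, nD)
  for (i in seq_len(nT)) {
    for (j in seq_len(nD)) {
      pl <- pairing_cost(predicted[[i]], detections[j, ], cfg)
      if (pl$mahal2 <= cfg$gate_chi2) cost[i, j] <- pl$cost
    }
  }
  sol <- solve_assignment(cost)
  structure(list(pairs = sol$pairs,
                 unmatched_tracks = sol$unmatched_rows,
                 unmatched_detections = sol$unmatched_cols,
                 total_cost = sol$total_cost),
            class = "frame_pairing")
}

# Build the initial 6x6 covariance from the configured diagonal.
initial_covariance <- function(cfg) diag(cfg$p0_diag, 6L)

# Seed a new track record from an accepted triplet.  Detections d1..d3 are
# rows of the localisation table; the full state is attached at the third
# frame.  States at the first two frames are back-extrapolated for the
# output table.
new_track_from_triplet <- function(id, frames, det_rows, pos, cfg) {
  ini <- init_state(pos[1, ], pos[2, ], pos[3, ], cfg$dt)
  a <- if (identical(cfg$model, "linear")) c(0, 0) else ini$a_init
  # v_init is the central-difference velocity, i.e. the velocity at the
  # middle frame for constant acceleration; advance it one frame so the
  # attached state is exact at the third frame.
  v <- ini$v_init + a * cfg$dt
  S3 <- c(pos[3, 1], v[1], a[1], pos[3, 2], v[2], a[2])
  hist <- vector("list", 3L)
  for (q in 1:3) {
    back <- (3 - q) * cfg$dt
    vq <- v - a * back
    hist[[q]] <- c(frames[q], det_rows[q],
                   pos[q, 1], vq[1], a[1], pos[q, 2], vq[2], a[2])
  }
  list(id = id,
       state = motion_state(S3, initial_covariance(cfg), frames[3]),
       hist = hist,
       misses = 0L,
       status = "active")
}

#' Track microbubbles through a localisation table
#'
#' The central fitting function: runs the full acceleration-based Kalman
#' tracking pipeline (predict, gated assignment, update, three-frame
#' initialisation of new tracks, lifecycle management) over a table of
#' per-frame localisations and returns the linked tracks with their
#' estimated velocities and accelerations.
#'
#' @param detections data.frame with columns `frame` (0-based integer),
#'   `x_um`, `y_um`, and optionally `intensity` and `truth_id`; or a path
#'   readable by [read_localisations()].
#' @param config a [kalman_config()]; alternatively pass `frame_rate` and
#'   `model` and a default configuration is built.
#' @param frame_rate,model convenience shortcuts used when `config` is
#'   missing.
#' @return an object of class `ulm_tracks`: a list with `tracks` (data.frame
#'   `track_id, frame, x_um, y_um, vx_mm_s, vy_mm_s, ax_mm_s2, ay_mm_s2,
#'   det_index`), `pairs` (data.frame `frame_k, frame_k1, det_k, det_k1,
#'   track_id` -- the produced consecutive-frame links), `n_detections`,
#'   `config`, and the matched input table.
#' @examples
#' det <- data.frame(frame = 0:9, x_um = 20 * (0:9), y_um = 0)
#' fit <- mb_track(det, frame_rate = 25)
#' fit
#' @export
mb_track <- function(detections, config = NULL, frame_rate = NULL,
                     model = c("accel", "linear")) {
  if (is.character(detections)) detections <- read_localisations(detections)
  if (is.null(config)) {
    if (is.null(frame_rate))
      stop("supply 'config' or at least 'frame_rate'")
    config <- kalman_config(frame_rate, match.arg(model))
  }
  stopifnot(inherits(config, "kalman_config"))
  det <- validate_detections(detections)
  if (nrow(det) == 0L) {
    warning("empty detection table: no tracks produced")
    return(empty_ulm_tracks(config, det))
  }
  det <- det[order(det$frame), , drop = FALSE]
  det$det_index <- seq_len(nrow(det))

  gate_step <- config$v_max * config$dt  # um
  frames <- seq.int(min(det$frame), max(det$frame))
  by_frame <- split(seq_len(nrow(det)), factor(det$frame, levels = frames))

  active <- list()        # track records (see new_track_from_triplet)
  done <- list()
  next_id <- 1L
  # pending pools of unmatched detection rows for the last two frames
  pend1 <- integer()      # frame k-1
  pend2 <- integer()      # frame k-2

  for (fi in seq_along(frames)) {
    k <- frames[fi]
    rows <- by_frame[[fi]]
    dpos <- cbind(det$x_um[rows], det$y_um[rows])

    # 1. predict
    preds <- lapply(active, function(tr) predict_state(tr$state, config))

    # 2. associate
    pairing <- associate_frame(preds, dpos, config)

    # 3. update matched tracks
    if (nrow(pairing$pairs) > 0L) {
      for (r in seq_len(nrow(pairing$pairs))) {
        ti <- pairing$pairs[r, 1L]
        dj <- pairing$pairs[r, 2L]
        post <- kalman_update(preds[[ti]], dpos[dj, ], config)
        tr <- active[[ti]]
        tr$state <- post
        tr$misses <- 0L
        tr$hist[[length(tr$hist) + 1L]] <-
          c(k, rows[dj], post$S[1], post$S[2], post$S[3],
            post$S[4], post$S[5], post$S[6])
        active[[ti]] <- tr
      }
    }

    # 4. lifecycle of unmatched tracks
    keep <- rep(TRUE, length(active))
    for (ti in pairing$unmatched_tracks) {
      tr <- active[[ti]]
      tr$misses <- tr$misses + 1L
      if (tr$misses > config$max_misses) {
        tr$status <- "terminated"
        done[[length(done) + 1L]] <- tr
        keep[ti] <- FALSE
      } else {
        tr$state <- preds[[ti]]  # coast on the prediction
        active[[ti]] <- tr
      }
      if (keep[ti]) active[[ti]] <- tr
    }
    active <- active[keep]

    # 5. three-frame initialisation from pending pools
    un_rows <- rows[pairing$unmatched_detections]
    born <- integer()
    if (length(pend2) && length(pend1) && length(un_rows)) {
      f1 <- cbind(det$x_um[pend2], det$y_um[pend2])
      f2 <- cbind(det$x_um[pend1], det$y_um[pend1])
      f3 <- cbind(det$x_um[un_rows], det$y_um[un_rows])
      trips <- solve_triplet_assignment(f1, f2, f3, gate = gate_step,
                                        cost_cap = config$cost_cap)
      if (nrow(trips) > 0L) {
        used1 <- integer(); used2 <- integer(); used3 <- integer()
        for (r in seq_len(nrow(trips))) {
          r1 <- pend2[trips$i[r]]
          r2 <- pend1[trips$j[r]]
          r3 <- un_rows[trips$k[r]]
          pos <- rbind(c(det$x_um[r1], det$y_um[r1]),
                       c(det$x_um[r2], det$y_um[r2]),
                       c(det$x_um[r3], det$y_um[r3]))
          active[[length(active) + 1L]] <-
            new_track_from_triplet(next_id, c(k - 2L, k - 1L, k),
                                   c(r1, r2, r3), pos, config)
          next_id <- next_id + 1L
          used1 <- c(used1, r1); used2 <- c(used2, r2); used3 <- c(used3, r3)
        }
        pend2 <- setdiff(pend2, used1)
        pend1 <- setdiff(pend1, used2)
        un_rows <- setdiff(un_rows, used3)
      }
    }

    # 6. age the pending pools (depth 3 frames = the initialisation window)
    pend2 <- pend1
    pend1 <- un_rows
  }
  done <- c(done, active)
  assemble_ulm_tracks(done, det, config)
}

validate_detections <- function(det) {
  det <- as.data.frame(det)
  need <- c("frame", "x_um", "y_um")
  miss <- setdiff(need, names(det))
  if (length(miss))
    stop("detection table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(det) == 0L) return(det)
  if (any(!is.finite(det$x_um)) || any(!is.finite(det$y_um)))
    stop("non-finite coordinates in detection table")
  if (any(det$frame < 0) || any(det$frame != round(det$frame)))
    stop("'frame' must contain non-negative integers")
  det$frame <- as.integer(det$frame)
  det
}

empty_ulm_tracks <- function(config, det) {
  structure(list(
    tracks = data.frame(track_id = integer(), frame = integer(),
                        x_um = numeric(), y_um = numeric(),
                        vx_mm_s = numeric(), vy_mm_s = numeric(),
                        ax_mm_s2 = numeric(), ay_mm_s2 = numeric(),
                        det_index = integer()),
    pairs = data.frame(frame_k = integer(), frame_k1 = integer(),
                       det_k = integer(), det_k1 = integer(),
                       track_id = integer()),
    n_detections = nrow(det), config = config, detections = det),
    class = "ulm_tracks")
}

assemble_ulm_tracks <- function(track_list, det, config) {
  keep <- Filter(function(tr) length(tr$hist) >= config$min_track_length,
                 track_list)
  if (length(keep) == 0L) return(empty_ulm_tracks(config, det))
  keep <- keep[order(vapply(keep, `[[`, integer(1), "id"))]
  rows <- list(); prs <- list()
  for (tr in keep) {
    h <- do.call(rbind, tr$hist)
    rows[[length(rows) + 1L]] <- data.frame(
      track_id = tr$id, frame = as.integer(h[, 1]),
      x_um = h[, 3], y_um = h[, 6],
      vx_mm_s = h[, 4], vy_mm_s = h[, 7],
      ax_mm_s2 = h[, 5] / MM_S2_TO_UM_MS2,
      ay_mm_s2 = h[, 8] / MM_S2_TO_UM_MS2,
      det_index = as.integer(h[, 2]))
    if (nrow(h) >= 2L) {
      a <- seq_len(nrow(h) - 1L)
      prs[[length(prs) + 1L]] <- data.frame(
        frame_k = as.integer(h[a, 1]), frame_k1 = as.integer(h[a + 1L, 1]),
        det_k = as.integer(h[a, 2]), det_k1 = as.integer(h[a + 1L, 2]),
        track_id = tr$id)
    }
  }
  structure(list(tracks = do.call(rbind, rows),
                 pairs = if (length(prs)) do.call(rbind, prs) else
                   empty_ulm_tracks(config, det)$pairs,
                 n_detections = nrow(det),
                 config = config,
                 detections = det),
            class = "ulm_tracks")
}

#' @export
print.ulm_tracks <- function(x, ...) {
  nt <- length(unique(x$tracks$track_id))
  cat("Microbubble tracks (", x$config$model, " motion model)\n", sep = "")
  cat(sprintf("  %d tracks from %d detections; %d consecutive-frame links\n",
              nt, x$n_detections, nrow(x$pairs)))
  if (nt > 0) {
    len <- table(x$tracks$track_id)
    cat(sprintf("  track length: median %g, max %d frames\n",
                stats::median(as.numeric(len)), max(len)))
    sp <- sqrt(x$tracks$vx_mm_s^2 + x$tracks$vy_mm_s^2)
    cat(sprintf("  speed: median %.2f mm/s (IQR %.2f-%.2f)\n",
                stats::median(sp), stats::quantile(sp, .25),
                stats::quantile(sp, .75)))
  }
  invisible(x)
}

#' @export
summary.ulm_tracks <- function(object, ...) {
  tr <- object$tracks
  len <- if (nrow(tr)) as.numeric(table(tr$track_id)) else numeric()
  sp <- if (nrow(tr)) sqrt(tr$vx_mm_s^2 + tr$vy_mm_s^2) else numeric()
  acc <- if (nrow(tr)) sqrt(tr$ax_mm_s2^2 + tr$ay_mm_s2^2) else numeric()
  out <- list(n_tracks = length(len), n_detections = object$n_detections,
              n_links = nrow(object$pairs),
              matched_fraction = if (object$n_detections)
                sum(len) / object$n_detections else NA_real_,
              track_length = summary(len), speed_mm_s = summary(sp),
              accel_mm_s2 = summary(acc), model = object$config$model)
  class(out) <- "summary.ulm_tracks"
  out
}

#' @export
print.summary.ulm_tracks <- function(x, ...) {
  cat("Summary of microbubble tracks (", x$model, " model)\n", sep = "")
  cat(sprintf("  tracks: %d   detections: %d (%.1f%% linked)   links: %d\n",
              x$n_tracks, x$n_detections, 100 * x$matched_fraction,
              x$n_links))
  cat("  track length (frames):\n"); print(x$track_length)
  cat("  speed (mm/s):\n"); print(x$speed_mm_s)
  cat("  |acceleration| (mm/s^2):\n"); print(x$accel_mm_s2)
  invisible(x)
}

#' @export
as.data.frame.ulm_tracks <- function(x, ...) x$tracks

#' Plot microbubble tracks
#'
#' Draws every track as a polyline in the image plane, coloured by its
#' median speed.
#'
#' @param x an `ulm_tracks` object.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.ulm_tracks <- function(x, ...) {
  tr <- x$tracks
  if (nrow(tr) == 0L) {
    graphics::plot(0, 0, type = "n", xlab = "x (um)", ylab = "y (um)", ...)
    return(invisible(x))
  }
  graphics::plot(range(tr$x_um), range(rev(range(tr$y_um))), type = "n",
                 xlab = "x (um)", ylab = "y (um)", ylim = rev(range(tr$y_um)),
                 ...)
  ids <- unique(tr$track_id)
  sp_med <- vapply(ids, function(id) {
    i <- tr$track_id == id
    stats::median(sqrt(tr$vx_mm_s[i]^2 + tr$vy_mm_s[i]^2))
  }, numeric(1))
  pal <- grDevices::hcl.colors(64L, "viridis")
  col <- pal[pmin(64L, 1L + floor(63 * sp_med / max(sp_med, 1e-9)))]
  for (q in seq_along(ids)) {
    i <- tr$track_id == ids[q]
    graphics::lines(tr$x_um[i], tr$y_um[i], col = col[q])
  }
  invisible(x)
}
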