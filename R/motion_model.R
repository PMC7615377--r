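# Constant-acceleration Kalman motion model for microbubble tracking.
#
# Internal canonical units are micrometres and milliseconds, so velocities in
# um/ms are numerically equal to mm/s.  Accelerations are stored in um/ms^2
# (1 mm/s^2 = 1e-3 um/ms^2); user-facing interfaces use mm/s and mm/s^2.
# The state vector ordering is [x, vx, ax, y, vy, ay].

MM_S2_TO_UM_MS2 <- 1e-3

#' Tracker configuration
#'
#' Collects every tunable parameter of the Kalman tracking pipeline: the
#' frame interval, the motion model (constant acceleration or the
#' constant-velocity baseline), process and observation noise, the
#' Mahalanobis gate for frame-to-frame association, and the gates of the
#' three-frame initialisation.
#'
#' @param frame_rate acquisition frame rate in Hz; sets the frame interval
#'   `dt = 1000 / frame_rate` milliseconds.
#' @param model `"accel"` for the constant-acceleration motion model or
#'   `"linear"` for the constant-velocity baseline (acceleration terms of the
#'   transition and the state forced to zero).
#' @param sigma_a process-noise acceleration standard deviation in mm/s^2.
#'   Describes how much the true acceleration may drift between frames.
#' @param sigma_obs localisation (observation) noise standard deviation in
#'   micrometres.
#' @param gate_chi2 Mahalanobis-squared gate for track-detection association;
#'   default is the 99% quantile of a chi-squared with 2 degrees of freedom.
#' @param p0_diag optional length-6 diagonal of the initial state covariance
#'   in the `[x, vx, ax, y, vy, ay]` ordering (um, um/ms, um/ms^2 scales).
#'   Default propagates `sigma_obs` into derivative uncertainty:
#'   `[s^2, (2s/dt)^2, (4s/dt^2)^2]` per axis with `s = max(sigma_obs, 1)`.
#' @param v_max maximum plausible microbubble speed in mm/s; bounds the step
#'   length `v_max * dt` used to gate three-frame initialisation candidates.
#' @param cost_cap maximum normalised vector-difference cost accepted for an
#'   initialisation triplet (in \[0, 1\]; 0.5 rejects turns sharper than
#'   about 60 degrees between equal steps).
#' @param max_misses consecutive unmatched frames tolerated before a track is
#'   terminated (0 = terminate on first miss).
#' @param min_track_length minimum number of detections for a track to be
#'   reported.
#' @return an object of class `kalman_config`.
#' @examples
#' cfg <- kalman_config(frame_rate = 25)
#' cfg$dt   # 40 ms
#' @export
kalman_config <- function(frame_rate,
                          model = c("accel", "linear"),
                          sigma_a = 25,
                          sigma_obs = 10,
                          gate_chi2 = stats::qchisq(0.99, df = 2),
                          p0_diag = NULL,
                          v_max = 50,
                          cost_cap = 0.5,
                          max_misses = 0L,
                          min_track_length = 3L) {
  model <- match.arg(model)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("'frame_rate' must be a single positive number (Hz)")
  if (sigma_a < 0) stop("'sigma_a' must be non-negative")
  if (sigma_obs < 0) stop("'sigma_obs' must be non-negative")
  if (gate_chi2 <= 0) stop("'gate_chi2' must be positive")
  dt <- 1000 / frame_rate
  if (is.null(p0_diag)) {
    s <- max(sigma_obs, 1)
    p0_diag <- rep(c(s^2, (2 * s / dt)^2, (4 * s / dt^2)^2), 2L)
  }
  if (length(p0_diag) != 6L || any(p0_diag < 0))
    stop("'p0_diag' must be 6 non-negative variances")
  structure(list(
    frame_rate = frame_rate,
    dt = dt,
    model = model,
    sigma_a = sigma_a,
    sigma_a2 = (sigma_a * MM_S2_TO_UM_MS2)^2,  # (um/ms^2)^2
    sigma_obs = sigma_obs,
    gate_chi2 = gate_chi2,
    p0_diag = p0_diag,
    v_max = v_max,
    cost_cap = cost_cap,
    max_misses = as.integer(max_misses),
    min_track_length = as.integer(min_track_length)
  ), class = "kalman_config")
}

#' @export
print.kalman_config <- function(x, ...) {
  cat("Kalman tracker configuration\n")
  cat(sprintf("  model: %s   frame rate: %g Hz (dt = %g ms)\n",
              x$model, x$frame_rate, x$dt))
  cat(sprintf("  sigma_a: %g mm/s^2   sigma_obs: %g um   gate chi2: %.3f\n",
              x$sigma_a, x$sigma_obs, x$gate_chi2))
  cat(sprintf("  init: v_max %g mm/s, cost cap %g; lifecycle: max misses %d, min length %d\n",
              x$v_max, x$cost_cap, x$max_misses, x$min_track_length))
  invisible(x)
}

#' Motion state of one microbubble
#'
#' A six-dimensional Kalman state `[x, vx, ax, y, vy, ay]` (positions in um,
#' velocities in um/ms = mm/s, accelerations in um/ms^2) with its 6x6
#' estimate covariance and the frame index it refers to.
#'
#' @param S length-6 state vector in the `[x, vx, ax, y, vy, ay]` ordering.
#' @param P 6x6 covariance matrix (symmetric positive semi-definite).
#' @param frame integer frame index.
#' @return an object of class `motion_state`.
#' @export
motion_state <- function(S, P, frame) {
  S <- as.numeric(S)
  if (length(S) != 6L || any(!is.finite(S)))
    stop("state vector must be 6 finite numbers [x, vx, ax, y, vy, ay]")
  P <- as.matrix(P)
  if (!all(dim(P) == c(6L, 6L))) stop("P must be a 6x6 matrix")
  if (max(abs(P - t(P))) > 1e-9 * max(1, max(abs(P))))
    stop("P must be symmetric")
  structure(list(S = S, P = (P + t(P)) / 2, frame = as.integer(frame)),
            class = "motion_state")
}

# position / velocity / acceleration accessors (x then y component)
state_position <- function(state) state$S[c(1L, 4L)]
state_velocity <- function(state) state$S[c(2L, 5L)]
state_acceleration <- function(state) state$S[c(3L, 6L)]

#' State transition matrix for the per-axis block [[1, dt, dt^2/2], [0, 1, dt], [0, 0, 1]]
#'
#' @param dt frame interval in milliseconds (> 0).
#' @param model `"accel"` (full constant-acceleration transition) or
#'   `"linear"` (acceleration coupling zeroed, constant-velocity baseline).
#' @return 6x6 transition matrix in the `[x, vx, ax, y, vy, ay]` ordering.
#' @export
build_transition <- function(dt, model = "accel") {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive time interval")
  blk <- if (identical(model, "linear")) {
    matrix(c(1, dt, 0,
             0, 1, 0,
             0, 0, 0), 3L, 3L, byrow = TRUE)
  } else {
    matrix(c(1, dt, dt^2 / 2,
             0, 1, dt,
             0, 0, 1), 3L, 3L, byrow = TRUE)
  }
  F <- matrix(0, 6L, 6L)
  F[1:3, 1:3] <- blk
  F[4:6, 4:6] <- blk
  F
}

#' Process noise covariance of the discrete white-jerk model
#'
#' Per-axis block `G G' sigma_a2` with `G = [dt^2/2, dt, 1]'` (acceleration
#' row zeroed for the linear baseline, whose process noise is white
#' acceleration on the velocity states).
#'
#' @param dt frame interval (ms, > 0).
#' @param sigma_a2 acceleration-noise variance in (um/ms^2)^2 (>= 0).
#' @param model `"accel"` or `"linear"`.
#' @return symmetric positive semi-definite 6x6 covariance.
#' @export
build_process_noise <- function(dt, sigma_a2, model = "accel") {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive time interval")
  if (!is.numeric(sigma_a2) || length(sigma_a2) != 1L || sigma_a2 < 0)
    stop("'sigma_a2' must be a single non-negative variance")
  G <- if (identical(model, "linear")) c(dt^2 / 2, dt, 0) else c(dt^2 / 2, dt, 1)
  blk <- tcrossprod(G) * sigma_a2
  Q <- matrix(0, 6L, 6L)
  Q[1:3, 1:3] <- blk
  Q[4:6, 4:6] <- blk
  Q
}

# 2x6 observation matrix selecting (x, y)
observation_matrix <- function() {
  H <- matrix(0, 2L, 6L)
  H[1L, 1L] <- 1
  H[2L, 4L] <- 1
  H
}

#' Kalman prediction step
#'
#' Propagates a motion state one frame forward: `S' = F S`,
#' `P' = F P F' + Q`.
#'
#' @param state a `motion_state`.
#' @param cfg a `kalman_config`.
#' @return the predicted `motion_state` at `state$frame + 1`.
#' @export
predict_state <- function(state, cfg) {
  F <- build_transition(cfg$dt, cfg$model)
  Q <- build_process_noise(cfg$dt, cfg$sigma_a2, cfg$model)
  S <- as.numeric(F %*% state$S)
  P <- F %*% state$P %*% t(F) + Q
  motion_state(S, (P + t(P)) / 2, state$frame + 1L)
}

#' Gaussian-likelihood pairing cost between a predicted state and a detection
#'
#' The pairing cost is the reciprocal of the bivariate normal density of the
#' observed position under the predicted observation distribution
#' `N(mu, Sigma)` with `mu = H S_pred` and
#' `Sigma = H P_pred H' + R`, `R = sigma_obs^2 I`.
#'
#' @param predicted predicted `motion_state` at the detection's frame.
#' @param obs observed position, length-2 numeric (um).
#' @param cfg a `kalman_config`.
#' @return list of class `pairing_likelihood` with elements `mu` (2-vector),
#'   `Sigma` (2x2 innovation covariance), `mahal2` (squared Mahalanobis
#'   distance of `obs`), `density` and `cost = 1/density`.
#' @export
pairing_cost <- function(predicted, obs, cfg) {
  obs <- as.numeric(obs)
  if (length(obs) != 2L || any(!is.finite(obs)))
    stop("'obs' must be a finite 2-vector (um)")
  H <- observation_matrix()
  mu <- as.numeric(H %*% predicted$S)
  Sigma <- H %*% predicted$P %*% t(H) + diag(cfg$sigma_obs^2, 2L)
  Sigma <- (Sigma + t(Sigma)) / 2
  detS <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2] * Sigma[2, 1]
  if (!is.finite(detS) || detS <= 0)
    stop("innovation covariance is numerically singular; increase sigma_obs")
  d <- obs - mu
  Sinv <- matrix(c(Sigma[2, 2], -Sigma[1, 2], -Sigma[2, 1], Sigma[1, 1]),
                 2L, 2L) / detS
  mahal2 <- as.numeric(t(d) %*% Sinv %*% d)
  density <- exp(-mahal2 / 2) / (2 * pi * sqrt(detS))
  structure(list(mu = mu, Sigma = Sigma, mahal2 = mahal2,
                 density = density, cost = 1 / density),
            class = "pairing_likelihood")
}

#' Kalman correction step
#'
#' Standard update `K = P' H' (H P' H' + R)^-1`, `S+ = S' + K (z - H S')`,
#' `P+ = (I - K H) P'` against an observed position.
#'
#' @param predicted predicted `motion_state`.
#' @param obs observed position, length-2 numeric (um).
#' @param cfg a `kalman_config`.
#' @return the posterior `motion_state` at the same frame.
#' @export
kalman_update <- function(predicted, obs, cfg) {
  obs <- as.numeric(obs)
  if (length(obs) != 2L || any(!is.finite(obs)))
    stop("'obs' must be a finite 2-vector (um)")
  H <- observation_matrix()
  P <- predicted$P
  Sg <- H %*% P %*% t(H) + diag(cfg$sigma_obs^2, 2L)
  detS <- Sg[1, 1] * Sg[2, 2] - Sg[1, 2] * Sg[2, 1]
  if (!is.finite(detS) || detS <= 0)
    stop("innovation covariance is numerically singular")
  Sinv <- matrix(c(Sg[2, 2], -Sg[1, 2], -Sg[2, 1], Sg[1, 1]), 2L, 2L) / detS
  K <- P %*% t(H) %*% Sinv
  innov <- obs - as.numeric(H %*% predicted$S)
  S <- predicted$S + as.numeric(K %*% innov)
  IKH <- diag(6L) - K %*% H
  # Joseph form keeps P symmetric PSD through repeated cycles
  Pn <- IKH %*% P %*% t(IKH) + K %*% diag(cfg$sigma_obs^2, 2L) %*% t(K)
  if (identical(cfg$model, "linear")) S[c(3L, 6L)] <- 0
  motion_state(S, (Pn + t(Pn)) / 2, predicted$frame)
}
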