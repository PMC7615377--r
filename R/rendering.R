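# Acceleration-based nonlinear trajectory interpolation and map rendering.
#
# Between two linked localisations the microbubble path is modelled as the
# quadratic implied by the starting Kalman velocity and the unique
# acceleration that carries the bubble exactly onto the next localisation.
# Interpolated points are laid out uniformly in arc length so that density
# accumulation is independent of speed.

#' Segment acceleration consistent with both endpoints
#'
#' Returns the unique acceleration for which the quadratic path starting at
#' `p1` with velocity `v1` reaches `p2` after `dt_frame`:
#' `a = 2 (p2 - p1 - v1 dt) / dt^2`.
#'
#' @param p1,p2 segment endpoints (length-2, um).
#' @param v1 velocity at `p1` (length-2, um/ms = mm/s).
#' @param dt_frame time between the endpoints (ms, > 0).
#' @return length-2 acceleration (um/ms^2).
#' @export
estimate_segment_acceleration <- function(p1, p2, v1, dt_frame) {
  if (!is.numeric(dt_frame) || length(dt_frame) != 1L || dt_frame <= 0)
    stop("'dt_frame' must be a single positive time interval")
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); v1 <- as.numeric(v1)
  2 * (p2 - p1 - v1 * dt_frame) / dt_frame^2
}

#' Interpolate one track segment along its quadratic path
#'
#' Emits positions `p(t) = p1 + v1 t + a t^2 / 2` for `t` in `[0, dt_frame]`
#' at (approximately) uniform arc-length steps no longer than `spacing`,
#' with the segment endpoints included exactly.  The per-point speed is
#' `||v1 + a t||`.
#'
#' @param p1 start position (um).
#' @param v1 start velocity (um/ms).
#' @param a acceleration (um/ms^2), e.g. from
#'   [estimate_segment_acceleration()].
#' @param dt_frame segment duration (ms, > 0).
#' @param spacing maximum distance between consecutive points (um, > 0).
#' @return object of class `interp_segment`: matrix with columns `x`, `y`,
#'   `speed` (mm/s) and `t` (ms), plus attributes `v1` and `a`.
#' @export
interpolate_segment <- function(p1, v1, a, dt_frame, spacing) {
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive distance")
  if (!is.numeric(dt_frame) || length(dt_frame) != 1L || dt_frame <= 0)
    stop("'dt_frame' must be a single positive time interval")
  p1 <- as.numeric(p1); v1 <- as.numeric(v1); a <- as.numeric(a)
  pos <- function(t) cbind(p1[1] + v1[1] * t + 0.5 * a[1] * t^2,
                           p1[2] + v1[2] * t + 0.5 * a[2] * t^2)
  # fine polyline for the arc-length parameterisation
  chord <- sqrt(sum((as.numeric(pos(dt_frame)) - p1)^2))
  n_out <- max(1L, ceiling(chord / spacing))
  m <- max(129L, 8L * n_out)
  tf <- seq(0, dt_frame, length.out = m + 1L)
  pf <- pos(tf)
  seg <- sqrt(diff(pf[, 1])^2 + diff(pf[, 2])^2)
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  if (L < 1e-12) {
    t_out <- c(0, dt_frame)
  } else {
    K <- max(1L, ceiling(L / spacing))
    targets <- seq(0, L, length.out = K + 1L)
    t_out <- stats::approx(arc, tf, xout = targets, ties = "ordered")$y
    t_out[1L] <- 0
    t_out[length(t_out)] <- dt_frame
  }
  p_out <- pos(t_out)
  speed <- sqrt((v1[1] + a[1] * t_out)^2 + (v1[2] + a[2] * t_out)^2)
  out <- cbind(x = p_out[, 1], y = p_out[, 2], speed = speed, t = t_out)
  structure(out, class = c("interp_segment", class(out)), v1 = v1, a = a)
}

#' Spatial speed gradient along an interpolated segment
#'
#' For consecutive interpolated points the signed gradient is
#' `(speed_{i+1} - speed_i) / ||p_{i+1} - p_i||`, reported in 1/s (speed in
#' mm/s per distance in mm), attributed to the gap midpoint.  A per-time
#' variant (tangential acceleration, mm/s^2) is available.
#'
#' @param points matrix with columns `x`, `y`, `speed` and (for
#'   `per = "time"`) `t`, as returned by [interpolate_segment()].
#' @param per `"distance"` (default, 1/s) or `"time"` (mm/s^2).
#' @return data.frame with gap midpoints `x`, `y` and `gradient`; zero-length
#'   gaps are dropped.
#' @export
speed_gradient <- function(points, per = c("distance", "time")) {
  per <- match.arg(per)
  points <- as.matrix(unclass(points))
  if (nrow(points) < 2L) stop("need at least two interpolated points")
  dx <- diff(points[, "x"]); dy <- diff(points[, "y"])
  dist <- sqrt(dx^2 + dy^2)
  dv <- diff(points[, "speed"])
  if (per == "distance") {
    ok <- dist > 1e-12
    grad <- dv[ok] / dist[ok] * 1000   # (mm/s)/um -> 1/s
  } else {
    dt <- diff(points[, "t"])
    ok <- dt > 1e-12 & dist > 1e-12
    grad <- dv[ok] / dt[ok] * 1000     # (mm/s)/ms -> mm/s^2
  }
  i <- which(ok)
  data.frame(x = (points[i, "x"] + points[i + 1L, "x"]) / 2,
             y = (points[i, "y"] + points[i + 1L, "y"]) / 2,
             gradient = grad)
}

# Interpolate every consecutive-detection segment of every track.
# Returns a data.frame of points (x, y, speed, t, track_id, is_gap_mid ...)
# and, when gradients are requested, the per-gap gradient samples.
interpolate_tracks <- function(fit, spacing, per = "distance") {
  stopifnot(inherits(fit, "ulm_tracks"))
  dt <- fit$config$dt
  tr <- fit$tracks
  pts <- list(); grads <- list()
  for (id in unique(tr$track_id)) {
    h <- tr[tr$track_id == id, , drop = FALSE]
    if (nrow(h) < 2L) next
    for (s in seq_len(nrow(h) - 1L)) {
      gap <- h$frame[s + 1L] - h$frame[s]
      dtf <- gap * dt
      p1 <- c(h$x_um[s], h$y_um[s])
      p2 <- c(h$x_um[s + 1L], h$y_um[s + 1L])
      v1 <- c(h$vx_mm_s[s], h$vy_mm_s[s])   # um/ms numerically
      a <- estimate_segment_acceleration(p1, p2, v1, dtf)
      seg <- interpolate_segment(p1, v1, a, dtf, spacing)
      segm <- unclass(seg)
      drop_last <- s < nrow(h) - 1L  # avoid double-counting shared endpoints
      keep <- if (drop_last) seq_len(nrow(segm) - 1L) else seq_len(nrow(segm))
      pts[[length(pts) + 1L]] <-
        data.frame(x = segm[keep, "x"], y = segm[keep, "y"],
                   speed = segm[keep, "speed"], track_id = id)
      if (!is.null(per)) {
        g <- speed_gradient(seg, per = per)
        if (nrow(g)) {
          g$track_id <- id
          grads[[length(grads) + 1L]] <- g
        }
      }
    }
  }
  list(points = if (length(pts)) do.call(rbind, pts) else
         data.frame(x = numeric(), y = numeric(), speed = numeric(),
                    track_id = integer()),
       gradients = if (length(grads)) do.call(rbind, grads) else
         data.frame(x = numeric(), y = numeric(), gradient = numeric(),
                    track_id = integer()))
}

#' Accumulate a super-resolution map from tracked microbubbles
#'
#' Interpolates every track segment along its quadratic path and bins the
#' points on a regular grid.  `density` counts interpolated points per
#' pixel (with arc-length-uniform spacing this is speed-independent);
#' `speed` and `gradient` average the per-point speed (mm/s) or the per-gap
#' spatial speed gradient (1/s) over all samples falling in a pixel, with
#' empty pixels reported as `NA`.
#'
#' @param fit an `ulm_tracks` object from [mb_track()].
#' @param kind `"density"`, `"speed"`, or `"gradient"`.
#' @param pixel_size super-resolution pixel size (um).
#' @param extent optional list with `xlim`, `ylim` (um); default fits the
#'   interpolated points.
#' @param spacing interpolation point spacing (um); default `pixel_size / 2`.
#' @param gradient_per `"distance"` (1/s) or `"time"` (mm/s^2), for
#'   `kind = "gradient"`.
#' @return an object of class `ulm_map`: list with the value `grid`
#'   (rows = y, cols = x), per-pixel sample `counts`, `pixel_size`, `origin`
#'   (lower corner, um), and `kind`.
#' @export
accumulate_map <- function(fit, kind = c("density", "speed", "gradient"),
                           pixel_size = 10, extent = NULL,
                           spacing = pixel_size / 2,
                           gradient_per = c("distance", "time")) {
  kind <- match.arg(kind)
  gradient_per <- match.arg(gradient_per)
  if (pixel_size <= 0) stop("'pixel_size' must be positive")
  ip <- interpolate_tracks(fit, spacing,
                           per = if (kind == "gradient") gradient_per else NULL)
  samples <- if (kind == "gradient") {
    data.frame(x = ip$gradients$x, y = ip$gradients$y,
               value = ip$gradients$gradient)
  } else {
    data.frame(x = ip$points$x, y = ip$points$y, value = ip$points$speed)
  }
  if (is.null(extent)) {
    if (nrow(samples) == 0L) {
      extent <- list(xlim = c(0, pixel_size), ylim = c(0, pixel_size))
    } else {
      extent <- list(xlim = range(samples$x), ylim = range(samples$y))
    }
  }
  x0 <- extent$xlim[1]; y0 <- extent$ylim[1]
  nx <- max(1L, ceiling((extent$xlim[2] - x0) / pixel_size + 1e-9))
  ny <- max(1L, ceiling((extent$ylim[2] - y0) / pixel_size + 1e-9))
  counts <- matrix(0, ny, nx)
  sums <- matrix(0, ny, nx)
  if (nrow(samples) > 0L) {
    ix <- pmin(nx, pmax(1L, floor((samples$x - x0) / pixel_size) + 1L))
    iy <- pmin(ny, pmax(1L, floor((samples$y - y0) / pixel_size) + 1L))
    inb <- samples$x >= x0 & samples$x <= x0 + nx * pixel_size &
      samples$y >= y0 & samples$y <= y0 + ny * pixel_size
    for (q in which(inb)) {
      counts[iy[q], ix[q]] <- counts[iy[q], ix[q]] + 1
      sums[iy[q], ix[q]] <- sums[iy[q], ix[q]] + samples$value[q]
    }
  }
  grid <- if (kind == "density") counts else {
    g <- sums / counts
    g[counts == 0] <- NA_real_
    g
  }
  structure(list(grid = grid, counts = counts, pixel_size = pixel_size,
                 origin = c(x0, y0), kind = kind,
                 frame_rate = fit$config$frame_rate),
            class = "ulm_map")
}

#' @export
print.ulm_map <- function(x, ...) {
  cat(sprintf("Super-resolution %s map: %d x %d px at %g um/px\n",
              x$kind, ncol(x$grid), nrow(x$grid), x$pixel_size))
  filled <- mean(x$counts > 0)
  cat(sprintf("  origin (%.1f, %.1f) um; %.1f%% of pixels sampled\n",
              x$origin[1], x$origin[2], 100 * filled))
  v <- x$grid[is.finite(x$grid)]
  if (length(v))
    cat(sprintf("  values: min %.3g, median %.3g, max %.3g\n",
                min(v), stats::median(v), max(v)))
  invisible(x)
}

#' Plot a rendered map
#'
#' @param x an `ulm_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.ulm_map <- function(x, ...) {
  nx <- ncol(x$grid); ny <- nrow(x$grid)
  xs <- x$origin[1] + (seq_len(nx) - 0.5) * x$pixel_size
  ys <- x$origin[2] + (seq_len(ny) - 0.5) * x$pixel_size
  pal <- if (x$kind == "gradient") grDevices::hcl.colors(64L, "Blue-Red 3")
         else grDevices::hcl.colors(64L, "inferno")
  graphics::image(xs, ys, t(x$grid), col = pal, ylim = rev(range(ys)),
                  xlab = "x (um)", ylab = "y (um)",
                  main = paste("ULM", x$kind, "map"), useRaster = TRUE, ...)
  invisible(x)
}
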