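# Three-frame motion-state initialisation.
#
# Newly appeared microbubbles have no velocity estimate, so their state is
# seeded from a minimal-cost triplet of detections across three consecutive
# frames.  The triplet cost is the normalised difference of the two step
# vectors, which is small when the motion direction changes smoothly.

#' Normalised vector-difference cost of a three-frame triplet
#'
#' For step vectors `L12 = p2 - p1` and `L23 = p3 - p2`, the cost is
#' `||L23 - L12|| / (||L23|| + ||L12||)`, which lies in \[0, 1\]: 0 for
#' uniform straight motion, 1 for an exact reversal.
#'
#' Stationary triplets (both steps shorter than 1e-6 um) are assigned cost 0
#' rather than the undefined 0/0.
#'
#' @param p1,p2,p3 positions (length-2 numeric, um) in three consecutive
#'   frames.
#' @return scalar cost in \[0, 1\].
#' @export
triplet_cost <- function(p1, p2, p3) {
  L12 <- as.numeric(p3_check(p2) - p3_check(p1))
  L23 <- as.numeric(p3_check(p3) - p3_check(p2))
  n12 <- sqrt(sum(L12^2))
  n23 <- sqrt(sum(L23^2))
  if (n12 < 1e-6 && n23 < 1e-6) return(0)
  sqrt(sum((L23 - L12)^2)) / (n23 + n12)
}

p3_check <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 2L || any(!is.finite(p)))
    stop("positions must be finite 2-vectors (um)")
  p
}

#' Initial velocity and acceleration from a three-frame triplet
#'
#' The central-difference velocity is `(L12 + L23) / (2 dt)` and the
#' second-difference acceleration `(L23 - L12) / dt^2`, the exact values for
#' a constant-acceleration trajectory sampled at interval `dt`.
#'
#' @param p1,p2,p3 positions (um) in three consecutive frames.
#' @param dt frame interval (ms, > 0).
#' @return list with `v_init` (um/ms = mm/s) and `a_init` (um/ms^2),
#'   2-vectors.
#' @export
init_state <- function(p1, p2, p3, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("'dt' must be a single positive time interval")
  L12 <- p3_check(p2) - p3_check(p1)
  L23 <- p3_check(p3) - p3_check(p2)
  if (sqrt(sum(L12^2)) < 1e-6 && sqrt(sum(L23^2)) < 1e-6)
    return(list(v_init = c(0, 0), a_init = c(0, 0)))
  list(v_init = (L12 + L23) / (2 * dt),
       a_init = (L23 - L12) / dt^2)
}

# Candidate triplets within the step gate and cost cap.
# f1, f2, f3: n_i x 2 position matrices.  Returns data.frame(i, j, k, cost).
triplet_candidates <- function(f1, f2, f3, gate, cost_cap) {
  n1 <- nrow(f1); n2 <- nrow(f2); n3 <- nrow(f3)
  out <- vector("list", 64L)
  nout <- 0L
  gate2 <- gate^2
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      L12 <- f2[j, ] - f1[i, ]
      d12 <- sum(L12^2)
      if (d12 > gate2) next
      for (k in seq_len(n3)) {
        L23 <- f3[k, ] - f2[j, ]
        d23 <- sum(L23^2)
        if (d23 > gate2) next
        cost <- triplet_cost(f1[i, ], f2[j, ], f3[k, ])
        if (cost > cost_cap) next
        nout <- nout + 1L
        if (nout > length(out)) out <- c(out, vector("list", length(out)))
        out[[nout]] <- c(i, j, k, cost)
      }
    }
  }
  if (nout == 0L)
    return(data.frame(i = integer(), j = integer(), k = integer(),
                      cost = numeric()))
  m <- do.call(rbind, out[seq_len(nout)])
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             k = as.integer(m[, 3]), cost = m[, 4])
}

# Exact small-instance solver: maximise the number of conflict-free triplets,
# then minimise their total cost.  Dynamic programme over frame-2 detections
# with bitmasks of used frame-1 / frame-3 detections; intended for instances
# with at most ~6 detections per frame.
triplet_exact <- function(cand, n2) {
  if (nrow(cand) == 0L) return(integer())
  byj <- split(seq_len(nrow(cand)), factor(cand$j, levels = seq_len(n2)))
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(jidx, m1, m3) {
    if (jidx > n2) return(list(card = 0L, cost = 0, sel = integer()))
    key <- paste(jidx, m1, m3, sep = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(jidx + 1L, m1, m3)  # leave detection jidx unpaired
    for (r in byj[[jidx]]) {
      b1 <- bitwShiftL(1L, cand$i[r] - 1L)
      b3 <- bitwShiftL(1L, cand$k[r] - 1L)
      if (bitwAnd(m1, b1) != 0L || bitwAnd(m3, b3) != 0L) next
      sub <- rec(jidx + 1L, bitwOr(m1, b1), bitwOr(m3, b3))
      card <- sub$card + 1L
      cost <- sub$cost + cand$cost[r]
      if (card > best$card || (card == best$card && cost < best$cost - 1e-12))
        best <- list(card = card, cost = cost, sel = c(r, sub$sel))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 0L, 0L)$sel
}

# Greedy solver: accept candidates in ascending (cost, i, j, k) order,
# rejecting any that reuse a detection.
triplet_greedy <- function(cand, n1, n2, n3) {
  if (nrow(cand) == 0L) return(integer())
  ord <- order(cand$cost, cand$i, cand$j, cand$k)
  used1 <- logical(n1); used2 <- logical(n2); used3 <- logical(n3)
  sel <- integer()
  for (r in ord) {
    i <- cand$i[r]; j <- cand$j[r]; k <- cand$k[r]
    if (used1[i] || used2[j] || used3[k]) next
    used1[i] <- TRUE; used2[j] <- TRUE; used3[k] <- TRUE
    sel <- c(sel, r)
  }
  sel
}

#' Conflict-free triplet assignment across three consecutive frames
#'
#' Selects a set of detection triplets (one detection used at most once in
#' each frame) whose step lengths respect the gate and whose normalised
#' vector-difference costs respect the cap.  Small instances (at most
#' `exact_max` detections in every frame) are solved exactly -- maximum
#' number of triplets, then minimum total cost -- by a bitmask dynamic
#' programme; larger instances fall back to deterministic greedy selection
#' in ascending cost order.
#'
#' @param f1,f2,f3 position matrices (`n_i` x 2, um) for three consecutive
#'   frames; `NULL` or zero rows give an empty result.
#' @param gate maximum step length in um (> 0).
#' @param cost_cap maximum accepted triplet cost.
#' @param exact_max largest per-frame detection count solved exactly.
#' @return data.frame with columns `i`, `j`, `k` (row indices into `f1`,
#'   `f2`, `f3`) and `cost`, ordered by `i`.
#' @export
solve_triplet_assignment <- function(f1, f2, f3, gate, cost_cap = 0.5,
                                     exact_max = 6L) {
  empty <- data.frame(i = integer(), j = integer(), k = integer(),
                      cost = numeric())
  as_mat <- function(f) {
    if (is.null(f)) return(matrix(numeric(), 0L, 2L))
    f <- as.matrix(f)
    if (ncol(f) != 2L) stop("frame positions must have two columns")
    f
  }
  f1 <- as_mat(f1); f2 <- as_mat(f2); f3 <- as_mat(f3)
  if (nrow(f1) == 0L || nrow(f2) == 0L || nrow(f3) == 0L) return(empty)
  if (!is.numeric(gate) || gate <= 0) stop("'gate' must be positive")
  cand <- triplet_candidates(f1, f2, f3, gate, cost_cap)
  if (nrow(cand) == 0L) return(empty)
  sel <- if (max(nrow(f1), nrow(f2), nrow(f3)) <= exact_max)
    triplet_exact(cand, nrow(f2))
  else
    triplet_greedy(cand, nrow(f1), nrow(f2), nrow(f3))
  res <- cand[sel, , drop = FALSE]
  res <- res[order(res$i), , drop = FALSE]
  rownames(res) <- NULL
  res
}
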