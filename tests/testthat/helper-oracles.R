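# Independent oracles and small fixture builders used across the suite.

# Exact bipartite assignment oracle: dynamic programme over rows with a
# bitmask of used columns; maximises the number of matched pairs among
# allowed (finite-cost) pairs, then minimises the total cost.  Independent
# of the package's augmenting-path solver.
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(list(card = 0L, cost = 0))
  full <- bitwShiftL(1L, m) - 1L
  # value[state] for current row index: list(card, cost)
  best_card <- rep(-1L, full + 1L)
  best_cost <- rep(Inf, full + 1L)
  best_card[1L] <- 0L; best_cost[1L] <- 0
  for (i in seq_len(n)) {
    nb_card <- rep(-1L, full + 1L)
    nb_cost <- rep(Inf, full + 1L)
    for (s in 0:full) {
      if (best_card[s + 1L] < 0L) next
      # leave row i unmatched
      if (best_card[s + 1L] > nb_card[s + 1L] ||
          (best_card[s + 1L] == nb_card[s + 1L] &&
           best_cost[s + 1L] < nb_cost[s + 1L])) {
        nb_card[s + 1L] <- best_card[s + 1L]
        nb_cost[s + 1L] <- best_cost[s + 1L]
      }
      for (j in seq_len(m)) {
        b <- bitwShiftL(1L, j - 1L)
        if (bitwAnd(s, b) != 0L || !is.finite(cost[i, j])) next
        s2 <- bitwOr(s, b)
        c2 <- best_cost[s + 1L] + cost[i, j]
        k2 <- best_card[s + 1L] + 1L
        if (k2 > nb_card[s2 + 1L] ||
            (k2 == nb_card[s2 + 1L] && c2 < nb_cost[s2 + 1L])) {
          nb_card[s2 + 1L] <- k2
          nb_cost[s2 + 1L] <- c2
        }
      }
    }
    best_card <- nb_card; best_cost <- nb_cost
  }
  k <- max(best_card)
  list(card = k, cost = min(best_cost[best_card == k]))
}

# Exhaustive conflict-free triplet assignment oracle: recursion over all
# candidate subsets with conflict pruning; maximises triplet count, then
# minimises total cost.
oracle_triplets <- function(cand) {
  nr <- nrow(cand)
  best <- list(card = 0L, cost = 0)
  rec <- function(idx, used1, used2, used3, card, cost) {
    if (card > best$card ||
        (card == best$card && cost < best$cost - 1e-12)) {
      best <<- list(card = card, cost = cost)
    }
    if (idx > nr) return()
    # upper bound on remaining additions
    if (card + (nr - idx + 1L) < best$card) return()
    rec(idx + 1L, used1, used2, used3, card, cost)
    i <- cand$i[idx]; j <- cand$j[idx]; k <- cand$k[idx]
    if (!(i %in% used1) && !(j %in% used2) && !(k %in% used3)) {
      rec(idx + 1L, c(used1, i), c(used2, j), c(used3, k),
          card + 1L, cost + cand$cost[idx])
    }
  }
  rec(1L, integer(), integer(), integer(), 0L, 0)
  best
}

# Direct (loop-based) SSIM reference with the same Gaussian window,
# independent of the package's separable-convolution path.
oracle_ssim <- function(A, B, sigma = 1.5, size = 11L) {
  L <- max(A, B) - min(A, B)
  if (L == 0) return(1)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  half <- (size - 1L) %/% 2L
  g <- exp(-(-half:half)^2 / (2 * sigma^2)); g <- g / sum(g)
  W <- outer(g, g)
  n <- nrow(A); m <- ncol(A)
  refl <- function(i, k) pmin(k, pmax(1L, i))
  vals <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    ri <- refl(i + (-half:half), n)
    ci <- refl(j + (-half:half), m)
    a <- A[ri, ci]; b <- B[ri, ci]
    mua <- sum(W * a); mub <- sum(W * b)
    va <- sum(W * a * a) - mua^2
    vb <- sum(W * b * b) - mub^2
    cab <- sum(W * a * b) - mua * mub
    vals[i, j] <- ((2 * mua * mub + C1) * (2 * cab + C2)) /
      ((mua^2 + mub^2 + C1) * (va + vb + C2))
  }
  mean(vals)
}

# Noise-free constant-acceleration trajectory sampled at interval dt (ms).
ca_trajectory <- function(p0, v0, a, dt, n_frames) {
  t <- (seq_len(n_frames) - 1L) * dt
  cbind(x = p0[1] + v0[1] * t + 0.5 * a[1] * t^2,
        y = p0[2] + v0[2] * t + 0.5 * a[2] * t^2)
}

# Detection table for a set of trajectories (matrix list), 0-based frames.
detections_from_paths <- function(paths) {
  do.call(rbind, lapply(seq_along(paths), function(id) {
    p <- paths[[id]]
    data.frame(frame = seq_len(nrow(p)) - 1L, x_um = p[, 1], y_um = p[, 2],
               truth_id = id)
  }))
}

# Random gated cost matrix for assignment tests.
random_gated_cost <- function(n, m, p_forbid = 0.35) {
  cost <- matrix(stats::runif(n * m, 0.1, 10), n, m)
  cost[stats::runif(n * m) < p_forbid] <- Inf
  cost
}
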