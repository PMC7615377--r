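# Minimum-cost one-to-one assignment (Jonker-Volgenant style Hungarian
# algorithm with row/column potentials, O(n^3)).  Used for frame-to-frame
# track-detection association; forbidden (gated-out) pairs are encoded with
# a large finite sentinel so a feasible perfect matching always exists after
# dummy padding.

# Square-matrix Hungarian.  a: n x n finite cost matrix.  Returns the
# assigned column for each row (permutation of 1..n).
hungarian_square <- function(a) {
  n <- nrow(a)
  if (n == 0L) return(integer())
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- a[i0, free_j] - u[i0 + 1L] - v[free_j + 1L]
      upd <- cur < minv[free_j + 1L]
      if (any(upd)) {
        minv[free_j[upd] + 1L] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      jb <- free_j[which.min(minv[free_j + 1L])]
      delta <- minv[jb + 1L]
      uj <- which(used)
      u[p[uj] + 1L] <- u[p[uj] + 1L] + delta
      v[uj] <- v[uj] - delta
      minv[-uj] <- minv[-uj] - delta
      j0 <- jb
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  ans[p[-1L]] <- seq_len(n)
  ans
}

#' Gated bipartite assignment
#'
#' Solves the rectangular track-detection assignment: among one-to-one
#' matchings restricted to allowed (gated) pairs, maximises the number of
#' matches and, among those, minimises the total cost.  Implemented by
#' dummy-padding to a square problem and solving it with a shortest
#' augmenting path Hungarian algorithm; deterministic for a given input.
#'
#' @param cost `n x m` numeric cost matrix; `Inf` (or `NA`) marks a
#'   forbidden pair.
#' @return list with `pairs` (two-column matrix: row index, column index),
#'   `unmatched_rows`, `unmatched_cols`, and `total_cost`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost); m <- ncol(cost)
  cost[is.na(cost)] <- Inf
  empty <- list(pairs = matrix(integer(), 0L, 2L,
                               dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(n), unmatched_cols = seq_len(m),
                total_cost = 0)
  if (n == 0L || m == 0L) return(empty)
  finite <- cost[is.finite(cost)]
  if (length(finite) == 0L) return(empty)
  D <- max(finite) + 1            # cost of leaving one row/col unmatched
  BIG <- (n + m) * (abs(D) + 1) * 1e6  # forbidden-pair sentinel
  N <- n + m
  A <- matrix(BIG, N, N)
  A[seq_len(n), seq_len(m)] <- ifelse(is.finite(cost), cost, BIG)
  for (i in seq_len(n)) A[i, m + i] <- D          # row i unmatched
  for (j in seq_len(m)) A[n + j, j] <- D          # col j unmatched
  A[(n + 1):N, (m + 1):N] <- 0                    # dummy-dummy
  asg <- hungarian_square(A)
  rows <- seq_len(n)
  matched <- rows[asg[rows] <= m & is.finite(cost[cbind(rows, pmin(asg[rows], m))])]
  matched <- matched[cost[cbind(matched, asg[matched])] < BIG / 2]
  pairs <- cbind(row = matched, col = asg[matched])
  list(pairs = pairs,
       unmatched_rows = setdiff(rows, matched),
       unmatched_cols = setdiff(seq_len(m), asg[matched]),
       total_cost = if (nrow(pairs)) sum(cost[pairs]) else 0)
}
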