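# Potential-based Hungarian algorithm (Jonker-Volgenant style shortest
# augmenting paths, O(n^3)) for square cost minimization. Used for cluster
# matching across folds and for shared-dimension matching.

#' Solve a square linear assignment problem
#'
#' Minimizes `sum(cost[i, a(i)])` over permutations `a`. To maximize a
#' score matrix, pass its negative.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  abort_if(!is.matrix(cost) || nrow(cost) != ncol(cost),
           "cost must be a square matrix")
  abort_if(!all(is.finite(cost)), "cost must be finite")
  n <- nrow(cost)
  # index 1 is the virtual column 0 of the textbook formulation
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row currently assigned to column j-1 (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n) + 1L) {
    if (p[j] > 0L) assignment[p[j]] <- j - 1L
  }
  assignment
}
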