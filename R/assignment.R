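# Linear assignment (minimum-cost perfect matching on a square cost
# matrix) via the Jonker-Volgenant shortest-augmenting-path scheme with
# dual potentials, O(n^3). Used to extract a hard permutation from a
# similarity matrix; cross-checked against brute-force enumeration on
# small instances in the tests.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)              # p[j]: row matched to column j
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      cur <- cost[i0, ] - u[i0] - v[seq_len(n)]
      better <- !used[seq_len(n)] & (cur < minv)
      minv[better] <- cur[better]
      way[better] <- j0
      free <- which(!used[seq_len(n)])
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      uj <- which(used)
      u[p[uj]] <- u[p[uj]] + delta
      v[uj] <- v[uj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assign_col <- integer(n)
  assign_col[p[seq_len(n)]] <- seq_len(n)   # row -> column
  assign_col
}
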