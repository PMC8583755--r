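# Independent oracles, deliberately implemented by different routes than the
# package internals.

# Superposed RMSD via the Kearsley quaternion method (eigenvalue route,
# independent of the SVD-based implementation).
oracle_quaternion_rmsd <- function(x, y) {
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  d <- x - y
  s <- x + y
  M <- matrix(0, 4, 4)
  M[1, 1] <- sum(d^2)
  M[2, 2] <- sum(d[, 1]^2 + s[, 2]^2 + s[, 3]^2)
  M[3, 3] <- sum(s[, 1]^2 + d[, 2]^2 + s[, 3]^2)
  M[4, 4] <- sum(s[, 1]^2 + s[, 2]^2 + d[, 3]^2)
  M[1, 2] <- M[2, 1] <- sum(s[, 2] * d[, 3] - d[, 2] * s[, 3])
  M[1, 3] <- M[3, 1] <- sum(d[, 1] * s[, 3] - s[, 1] * d[, 3])
  M[1, 4] <- M[4, 1] <- sum(s[, 1] * d[, 2] - d[, 1] * s[, 2])
  M[2, 3] <- M[3, 2] <- sum(d[, 1] * d[, 2] - s[, 1] * s[, 2])
  M[2, 4] <- M[4, 2] <- sum(d[, 1] * d[, 3] - s[, 1] * s[, 3])
  M[3, 4] <- M[4, 3] <- sum(d[, 2] * d[, 3] - s[, 2] * s[, 3])
  lam <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(lam, 0) / nrow(x))
}

# Literal transcription of the greedy neighbour-count clustering, written
# with explicit loops and no shared code with the package.
oracle_greedy_cluster <- function(m, cutoff) {
  n <- nrow(m)
  pool <- seq_len(n)
  cluster <- integer(n)
  centers <- integer(0)
  k <- 0L
  while (length(pool) > 0) {
    best <- NA
    best_count <- -1
    for (i in pool) {
      count <- 0
      for (j in pool) if (m[i, j] <= cutoff) count <- count + 1
      if (count > best_count) {  # strict >: first (lowest) index wins ties
        best <- i
        best_count <- count
      }
    }
    members <- pool[m[best, pool] <= cutoff]
    k <- k + 1L
    cluster[members] <- k
    centers[k] <- best
    pool <- setdiff(pool, members)
  }
  list(cluster = cluster, centers = centers, n_clusters = k)
}

# Exhaustive pairwise hydrogen-bond count: distance strict <, deviation of
# D->H from D->A strict < angle cutoff.
oracle_hbond_count <- function(xyz, donors, hydrogens, acceptors_xyz,
                               dist_cutoff = 0.35, angle_cutoff = 30) {
  count <- 0
  for (k in seq_along(donors)) {
    d <- xyz[donors[k], ]
    h <- xyz[hydrogens[k], ]
    for (a in seq_len(nrow(acceptors_xyz))) {
      v <- acceptors_xyz[a, ] - d
      dist <- sqrt(sum(v^2))
      if (dist >= dist_cutoff || dist < 1e-9) next
      u <- (h - d) / sqrt(sum((h - d)^2))
      ang <- acos(max(-1, min(1, sum(v * u) / dist))) * 180 / pi
      if (ang < angle_cutoff) count <- count + 1
    }
  }
  count
}

# Random symmetric "RMSD-like" matrix with zero diagonal; values drawn from
# a coarse grid so ties in neighbour counts are common.
random_rmsd_matrix <- function(n, quantize = TRUE) {
  v <- if (quantize) sample(seq(0.05, 0.8, by = 0.05), n * (n - 1) / 2,
                            replace = TRUE) else runif(n * (n - 1) / 2, 0, 0.8)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}
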