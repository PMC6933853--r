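# Independent brute-force oracles. These deliberately avoid the package's
# C++ code paths: flood fill is a plain R breadth-first search, shortest
# paths use Floyd-Warshall over an explicit dense edge matrix.

# 26- or 6-neighbourhood offsets
oracle_offsets <- function(connectivity = 26) {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  off
}

# labels an array by BFS flood fill; 0 = at-or-below threshold
oracle_flood_fill <- function(values, threshold, connectivity = 26) {
  d <- dim(values)
  lab <- array(0L, dim = d)
  off <- oracle_offsets(connectivity)
  nextlab <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (lab[i, j, k] != 0L || values[i, j, k] <= threshold) next
    nextlab <- nextlab + 1L
    queue <- matrix(c(i, j, k), ncol = 3)
    lab[i, j, k] <- nextlab
    while (nrow(queue) > 0) {
      cur <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(off))) {
        p <- cur + off[o, ]
        if (any(p < 1) || any(p > d)) next
        if (lab[p[1], p[2], p[3]] == 0L &&
            values[p[1], p[2], p[3]] > threshold) {
          lab[p[1], p[2], p[3]] <- nextlab
          queue <- rbind(queue, p)
        }
      }
    }
  }
  lab
}

# exhaustive all-pairs minimum path weight over the voxels of a region,
# using the same cost definition as the package (mean-of-endpoint weights
# times Euclidean step length in voxels), via Floyd-Warshall
oracle_all_pairs_weight <- function(map, region_idx0, exponent_a = 2,
                                    connectivity = 26) {
  d <- dim(map$values)
  v <- as.vector(map$values)[region_idx0 + 1L]
  lo <- min(v); hi <- max(v)
  w_node <- if (hi > lo) ((hi - v) / (hi - lo))^exponent_a else rep(0, length(v))
  ijk <- cbind(region_idx0 %% d[1],
               (region_idx0 %/% d[1]) %% d[2],
               region_idx0 %/% (d[1] * d[2]))
  n <- length(region_idx0)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    dd <- abs(ijk[a, ] - ijk[b, ])
    adj <- if (connectivity == 26) all(dd <= 1) else
      (sum(dd) == 1)
    if (adj && any(dd > 0)) {
      step <- sqrt(sum(dd^2))
      D[a, b] <- 0.5 * (w_node[a] + w_node[b]) * step
    }
  }
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], `+`)
    D <- pmin(D, Dk)
  }
  D
}

# closed-form two-Gaussian density along the axis joining two unit
# Gaussians at distance d apart
two_gauss_axis <- function(x, d, sigma) {
  exp(-x^2 / (2 * sigma^2)) + exp(-(x - d)^2 / (2 * sigma^2))
}
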