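# Shared helpers: small grids, independently coded oracles, and a uniform
# straight orientation field. Oracles deliberately re-derive results with
# different code paths than the package implementation.

smallGrid <- function(dim = c(20L, 20L, 20L), vs = 1) {
  imageGrid(as.integer(dim), vs)
}

# random polyline streamlines inside a grid (world mm)
randomStreamlines <- function(n, grid, minPts = 2L, maxPts = 8L) {
  lo <- voxelToWorld(matrix(0, 1, 3), grid) - 0.49 * voxelSize(grid)
  hi <- voxelToWorld(matrix(grid@dim - 1L, 1, 3), grid) +
    0.49 * voxelSize(grid)
  lapply(seq_len(n), function(i) {
    k <- sample(minPts:maxPts, 1)
    sweep(sweep(matrix(runif(3 * k), ncol = 3), 2, as.numeric(hi - lo),
                "*"), 2, as.numeric(lo), "+")
  })
}

# density oracle: per (streamline, voxel) membership test over densely
# sampled points; each segment of each streamline is sampled at
# ceil(len / h) subdivisions (the documented visitation contract), and a
# voxel counts once per streamline if any sample falls in its half-open box
densityOracle <- function(streamlines, grid) {
  h <- min(voxelSize(grid)) / 2
  inv <- solve(grid@affine)
  counts <- array(0, grid@dim)
  for (s in streamlines) {
    pts <- s[1, , drop = FALSE]
    if (nrow(s) > 1) for (seg in seq_len(nrow(s) - 1)) {
      a <- s[seg, ]; b <- s[seg + 1, ]
      len <- sqrt(sum((b - a)^2))
      m <- max(1L, ceiling(len / h))
      tt <- seq_len(m) / m
      pts <- rbind(pts, outer(tt, b - a) + rep(a, each = m))
    }
    vox <- unique(t(apply(pts, 1, function(p) {
      c <- (inv %*% c(p, 1))[1:3]
      floor(c + 0.5)
    })), MARGIN = 1)
    for (r in seq_len(nrow(vox))) {
      v <- vox[r, ]
      if (all(v >= 0) && all(v < grid@dim))
        counts[v[1] + 1, v[2] + 1, v[3] + 1] <-
          counts[v[1] + 1, v[2] + 1, v[3] + 1] + 1
    }
  }
  counts
}

# uniform straight field: one +y lobe of amplitude 1 in every voxel
straightField <- function(grid) {
  nv <- prod(grid@dim)
  orientationField(grid, seq_len(nv),
                   matrix(rep(c(0, 1, 0), nv), ncol = 3, byrow = TRUE),
                   rep(1, nv))
}

# exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (midranks, zeros already removed by the caller)
enumSignedRankP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  allW <- grid %*% r
  pGe <- mean(allW >= W - 1e-9)
  pLe <- mean(allW <= W + 1e-9)
  min(1, 2 * min(pGe, pLe))
}

maskFromArray <- function(grid, arr) binaryMask(grid, array(arr, grid@dim))
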