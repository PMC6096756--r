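# Internal helpers shared across modules.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

rms <- function(x) sqrt(mean(x^2))

# Apply a 3x4 affine to an n x 3 point matrix.
applyAffinePoints <- function(A, pts) {
  stopifnot(all(dim(A) == c(3L, 4L)), ncol(pts) == 3L)
  t(A[, 1:3] %*% t(pts) + A[, 4])
}

# Invert a 3x4 affine.
invertAffine <- function(A) {
  L <- solve(A[, 1:3])
  cbind(L, -L %*% A[, 4])
}

# Compose 3x4 affines: returns the affine equivalent to applying B then A.
composeAffine <- function(A, B) {
  cbind(A[, 1:3] %*% B[, 1:3], A[, 1:3] %*% B[, 4] + A[, 4])
}

identityAffine <- function() cbind(diag(3), c(0, 0, 0))

# Trilinear interpolation of a 3D array at continuous voxel coordinates
# (1-based, array indexing). Points outside the grid return NA.
trilinear <- function(vol, pts) {
  d <- dim(vol)
  out <- rep(NA_real_, nrow(pts))
  i0 <- floor(pts)
  frac <- pts - i0
  ok <- i0[, 1] >= 1 & i0[, 1] <= d[1] - 1 &
        i0[, 2] >= 1 & i0[, 2] <= d[2] - 1 &
        i0[, 3] >= 1 & i0[, 3] <= d[3] - 1
  # points exactly on the upper faces
  hi <- pts[, 1] == d[1] | pts[, 2] == d[2] | pts[, 3] == d[3]
  onGrid <- !ok & hi &
    pts[, 1] >= 1 & pts[, 1] <= d[1] &
    pts[, 2] >= 1 & pts[, 2] <= d[2] &
    pts[, 3] >= 1 & pts[, 3] <= d[3]
  if (any(onGrid)) {
    i0[onGrid, ] <- pmin(i0[onGrid, , drop = FALSE],
                         matrix(rep(d - 1L, each = sum(onGrid)), ncol = 3))
    frac[onGrid, ] <- pts[onGrid, , drop = FALSE] - i0[onGrid, , drop = FALSE]
    ok <- ok | onGrid
  }
  if (!any(ok)) return(out)
  x0 <- i0[ok, 1]; y0 <- i0[ok, 2]; z0 <- i0[ok, 3]
  fx <- frac[ok, 1]; fy <- frac[ok, 2]; fz <- frac[ok, 3]
  idx <- function(dx, dy, dz) {
    cbind(x0 + dx, y0 + dy, z0 + dz)
  }
  v000 <- vol[idx(0, 0, 0)]; v100 <- vol[idx(1, 0, 0)]
  v010 <- vol[idx(0, 1, 0)]; v110 <- vol[idx(1, 1, 0)]
  v001 <- vol[idx(0, 0, 1)]; v101 <- vol[idx(1, 0, 1)]
  v011 <- vol[idx(0, 1, 1)]; v111 <- vol[idx(1, 1, 1)]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) +
    v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz +
    v111 * fx * fy * fz
  out
}

# Squared cross-distances between two point sets (n x 3, m x 3) computed in
# blocks to bound memory; returns, for each row of `a`, the index and
# distance of the nearest row of `b`.
nearestNeighbours <- function(a, b, block = 2048L) {
  n <- nrow(a)
  idx <- integer(n)
  dist <- numeric(n)
  b2 <- rowSums(b^2)
  for (start in seq(1L, n, by = block)) {
    end <- min(start + block - 1L, n)
    ab <- a[start:end, , drop = FALSE] %*% t(b)
    d2 <- outer(rowSums(a[start:end, , drop = FALSE]^2), b2, "+") - 2 * ab
    j <- max.col(-d2, ties.method = "first")
    idx[start:end] <- j
    dist[start:end] <- sqrt(pmax(0, d2[cbind(seq_len(end - start + 1L), j)]))
  }
  list(index = idx, distance = dist)
}
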