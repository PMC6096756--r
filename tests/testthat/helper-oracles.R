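# Shared fixtures and independent brute-force oracles.

# Small, fast phantom used across histology/tonotopy tests.
smallPhantom <- function(...) {
  phantomSpec(semiAxesUm = c(300, 240, 150), pixelSizeUm = 6, ...)
}

rotAffine <- function(axis, thetaDeg, scale = 1, shift = c(0, 0, 0)) {
  th <- thetaDeg * pi / 180
  R <- diag(3)
  ij <- setdiff(1:3, axis)
  R[ij[1], ij[1]] <- cos(th); R[ij[2], ij[2]] <- cos(th)
  R[ij[1], ij[2]] <- -sin(th); R[ij[2], ij[1]] <- sin(th)
  cbind(R * scale, shift)
}

surfaceFromPoints <- function(pts) {
  new("SurfaceModel", vertices = pts, faces = matrix(integer(0), 0, 3),
      openEnds = c(FALSE, FALSE), sectionOf = rep(0L, nrow(pts)))
}

affCompose <- centralgain:::composeAffine
affInvert <- centralgain:::invertAffine
affApply <- centralgain:::applyAffinePoints

# Exhaustive max-minus-min scan over every window of a sample vector.
oracleWindowScan <- function(x, idx) {
  hi <- -Inf; lo <- Inf
  for (i in idx) {
    if (x[i] > hi) hi <- x[i]
    if (x[i] < lo) lo <- x[i]
  }
  hi - lo
}

# Point-to-line distance oracle for the triangle construction: explicit
# two-point line form evaluated per bin.
oracleTriangle <- function(h) {
  h <- as.numeric(h)
  nz <- which(h > 0)
  left <- min(nz) - 1L; right <- max(nz) - 1L
  if (left == right) return(left)
  p <- which.max(h) - 1L
  e <- if ((right - p) >= (p - left)) right else left
  lo <- min(p, e); hi <- max(p, e)
  if (hi - lo < 2L) return(e)
  x1 <- p; y1 <- h[p + 1]; x2 <- e; y2 <- h[e + 1]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  cand <- (lo + 1L):(hi - 1L)
  d <- vapply(cand, function(i) {
    abs((y2 - y1) * i - (x2 - x1) * h[i + 1] + x2 * y1 - y2 * x1) / len
  }, numeric(1))
  cand[which.max(d)]
}

# Exhaustive Renyi-entropy threshold of order alpha: direct per-candidate
# evaluation of the two class entropies.
oracleRenyiAlpha <- function(h, alpha) {
  p <- as.numeric(h) / sum(h)
  nz <- which(p > 0)
  ent <- function(q) {
    q <- q[q > 0]
    if (!length(q)) return(-Inf)
    q <- q / sum(q)
    if (alpha == 1) -sum(q * log(q)) else log(sum(q^alpha)) / (1 - alpha)
  }
  cand <- min(nz):(max(nz) - 1L)
  tot <- vapply(cand, function(t)
    ent(p[1:t]) + ent(p[(t + 1):length(p)]), numeric(1))
  cand[which.max(tot)] - 1L
}

# A reproducible bimodal gray-level histogram (background + label modes).
bimodalHistogram <- function(seed = 42, n = 50000, mix = 0.08,
                             mu = c(60, 190), sdev = c(12, 18)) {
  set.seed(seed)
  lab <- runif(n) < mix
  v <- round(ifelse(lab, rnorm(n, mu[2], sdev[2]), rnorm(n, mu[1], sdev[1])))
  tabulate(pmin(255, pmax(0, v)) + 1L, nbins = 256L)
}
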