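# 3D reconstruction, registration, frequency mapping, binned densities.

test_that("stacked outlines lift to the correct z and match the analytic shell", {
  circ <- function(r, n = 40) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(r * cos(th), r * sin(th))
  }
  surf <- stackOutlines(rep(list(circ(100)), 4), spacingUm = 50)
  v <- vertices(surf)
  expect_equal(sort(unique(v[, 3])), c(0, 50, 100, 150))
  expect_equal(max(v[, 3]) - min(v[, 3]), 50 * 3)
  expect_error(stackOutlines(rep(list(circ(100)), 2)), "3")

  # pure-ellipsoid phantom: outline vertices lie on the analytic ellipsoid
  # shell to within the pixel quantization of the boundary trace
  spec <- smallPhantom(taper = c(0, 0, 0))
  sim <- generateVCNStack(spec, "sham", seed = 5)
  out <- roiOutlines(sim$stack, step = 1L)
  ax <- spec@semiAxesUm
  z0 <- -ax[3] + 25  # first section centre (50-um sections from -150)
  for (k in seq_along(out)) {
    z <- z0 + (k - 1) * 50
    # in-plane semi-axes of the cross-section at height z
    shrink <- sqrt(1 - (z / ax[3])^2)
    r <- sqrt((out[[k]][, 1] / (ax[1] * shrink))^2 +
              (out[[k]][, 2] / (ax[2] * shrink))^2)
    # boundary pixel centres sit just inside the shell
    distUm <- (1 - r) * min(ax[1], ax[2]) * shrink
    expect_true(all(distUm > -1e-6))
    expect_lt(max(distUm), 2 * spec@pixelSizeUm)
  }
})

test_that("hemisphere mirroring is an involution and leaves the right side unchanged", {
  set.seed(3)
  surf <- surfaceFromPoints(matrix(rnorm(60), 20, 3))
  expect_identical(mirrorHemisphere(surf, "right")@vertices, surf@vertices)
  twice <- mirrorHemisphere(mirrorHemisphere(surf, "left"), "left")
  expect_equal(twice@vertices, surf@vertices)
})

test_that("affine fit: template copy gives the identity at near-zero RMS", {
  spec <- smallPhantom()
  tpl <- templateFromSpec(spec)
  fit <- fitAffine(tpl@surface, tpl, tol = 1e-6)
  expect_lt(fit@rms, 1e-3)
  expect_lt(max(abs(affineMatrix(fit) - cbind(diag(3), c(0, 0, 0)))), 1e-3)
})

test_that("affine fit recovers a known transform: composition is the identity", {
  spec <- smallPhantom()
  tpl <- templateFromSpec(spec)
  A <- rotAffine(3, 12, scale = 1.05, shift = c(40, -30, 20))
  V <- affApply(affInvert(A), vertices(tpl@surface))
  fit <- fitAffine(surfaceFromPoints(V), tpl, tol = 1e-6)
  comp <- affCompose(affineMatrix(fit), affInvert(A))
  expect_lt(fit@rms, 1e-3)
  expect_lt(max(abs(comp - cbind(diag(3), c(0, 0, 0)))), 1e-3)
})

test_that("affine fit: vertex jitter appears in the reported RMS at its own scale", {
  spec <- smallPhantom()
  tpl <- templateFromSpec(spec)
  set.seed(12)
  V <- vertices(tpl@surface) + matrix(rnorm(3 * 2000, sd = 20), ncol = 3)
  fit <- fitAffine(surfaceFromPoints(V), tpl)
  expect_gt(fit@rms, 8)    # of the order of the 20-um jitter SD
  expect_lt(fit@rms, 40)
  expect_error(fitAffine(surfaceFromPoints(cbind(1:20, 21:40, 0)), tpl),
               "degenerate")
})

test_that("mirrored left phantom registers as well as the right-side original", {
  spec <- smallPhantom()
  tpl <- templateFromSpec(spec)
  sim <- generateVCNStack(spec, "sham", seed = 6)
  surf <- stackOutlines(roiOutlines(sim$stack), spacingUm = 50)
  fitR <- fitAffine(surf, tpl)
  left <- surf
  left@vertices[, 1] <- -left@vertices[, 1]   # a left-hemisphere tracing
  fitL <- fitAffine(mirrorHemisphere(left, "left"), tpl)
  expect_equal(fitL@rms, fitR@rms, tolerance = 1e-6)
})

test_that("pixel frequencies: ground-truth transform reproduces the field exactly", {
  spec <- smallPhantom()
  sim <- generateVCNStack(spec, "sham", seed = 7)
  tpl <- templateFromSpec(spec)
  pf <- mapPixelFrequencies(sim$stack, sim$truth$affineStackToTemplate, tpl)
  for (i in seq_along(pf)) {
    both <- !is.na(pf[[i]]) & !is.na(sim$truth$frequencyKHz[[i]])
    # the field is linear in log2, so trilinear interpolation is exact
    expect_equal(log2(pf[[i]][both]),
                 log2(sim$truth$frequencyKHz[[i]][both]), tolerance = 1e-9)
  }
})

test_that("a one-voxel translation bounds the frequency error by the field gradient", {
  spec <- smallPhantom()
  sim <- generateVCNStack(spec, "sham", seed = 7)
  tpl <- templateFromSpec(spec)
  shift <- cbind(diag(3), c(0, tpl@voxelSizeUm, 0))  # one voxel along y
  A <- affCompose(shift, sim$truth$affineStackToTemplate)
  pf <- mapPixelFrequencies(sim$stack, A, tpl)
  gradPerUm <- diff(log2(spec@freqRangeKHz)) / (2 * spec@semiAxesUm[2])
  bound <- gradPerUm * tpl@voxelSizeUm + 1e-9
  for (i in seq_along(pf)) {
    both <- !is.na(pf[[i]]) & !is.na(sim$truth$frequencyKHz[[i]])
    err <- abs(log2(pf[[i]][both]) -
                 log2(sim$truth$frequencyKHz[[i]][both]))
    expect_lte(max(err), bound)
  }
})

test_that("rotated phantom end-to-end: >= 95% of pixels within 1/8 octave", {
  # full-size phantom: 10 sections constrain the affine well enough for
  # sub-bin frequency accuracy
  A <- affCompose(rotAffine(3, 10), rotAffine(1, -7, shift = c(30, -20, 10)))
  spec <- phantomSpec(affine = A)
  tpl <- templateFromSpec(spec)
  sim <- generateVCNStack(spec, "sham", seed = 8)
  surf <- stackOutlines(roiOutlines(sim$stack), spacingUm = 50)
  fit <- fitAffine(surf, tpl)
  pf <- mapPixelFrequencies(sim$stack, fit, tpl)
  errs <- unlist(lapply(seq_along(pf), function(i) {
    both <- !is.na(pf[[i]]) & !is.na(sim$truth$frequencyKHz[[i]])
    abs(log2(pf[[i]][both]) - log2(sim$truth$frequencyKHz[[i]][both]))
  }))
  expect_gt(mean(errs <= 0.125), 0.95)
})

test_that("quarter-octave bins reproduce the printed centres and construction", {
  b <- quarterOctaveBins()
  expect_equal(round(b$centersKHz, 1),
               c(5.8, 6.9, 8.2, 9.8, 11.7, 13.9, 16.5, 19.6, 23.3, 27.7, 33.0))
  expect_equal(b$centersKHz[6], sqrt(6 * 32))
  expect_equal(unique(round(b$centersKHz[-1] / b$centersKHz[-11], 12)),
               round(2^0.25, 12))
  # scale covariance
  b2 <- quarterOctaveBins(12, 64)
  expect_equal(b2$centersKHz, 2 * b$centersKHz)
  # half-open edges at centre * 2^(+/- 1/8)
  expect_equal(b$edgesKHz[1], b$centersKHz[1] * 2^(-1 / 8))
  expect_equal(b$edgesKHz[12], b$centersKHz[11] * 2^(1 / 8))
  expect_error(quarterOctaveBins(10, 5), "fmin")
})

test_that("binned density: all-true label, pixel conservation, Poisson flatness, a step profile", {
  spec <- smallPhantom()
  sim <- generateVCNStack(spec, "sham", seed = 9, illumRange = c(1, 1))
  tpl <- templateFromSpec(spec)
  pf <- mapPixelFrequencies(sim$stack, sim$truth$affineStackToTemplate, tpl)
  allTrue <- lapply(pf, function(m) matrix(TRUE, nrow(m), ncol(m)))
  bins <- quarterOctaveBins()
  profAll <- densityByBin(pf, allTrue, bins)
  expect_true(all(profAll$density[profAll$total > 0] == 1))

  # conservation: per-bin totals sum to the number of assigned in-range pixels
  f <- unlist(pf)
  inRange <- !is.na(f) & f >= bins$edgesKHz[1] & f < bins$edgesKHz[12]
  expect_equal(sum(profAll$total), sum(inRange))

  # uniform density: per-bin densities flat within Poisson error
  prof <- densityByBin(pf, sim$truth$labelMask, bins)
  ok <- prof$total > 2000
  p0 <- sum(prof$labeled[ok]) / sum(prof$total[ok])
  z <- (prof$density[ok] - p0) / sqrt(p0 * (1 - p0) / prof$total[ok])
  # puncta are multi-pixel blobs, so counts are clumped; allow inflation
  expect_true(all(abs(z) < 4 * sqrt(13)))

  # density halved above the middle bin centre -> twofold step across it
  # (single-pixel puncta remove disc spillover across the boundary)
  stepSpec <- smallPhantom(
    densitySham = function(f) ifelse(f > 13.9, 1e-3, 2e-3),
    punctumRadiusUm = 1e-3)
  tpl2 <- templateFromSpec(stepSpec)
  sim2 <- generateVCNStack(stepSpec, "sham", seed = 10, illumRange = c(1, 1))
  pf2 <- mapPixelFrequencies(sim2$stack, sim2$truth$affineStackToTemplate,
                             tpl2)
  prof2 <- densityByBin(pf2, sim2$truth$labelMask, bins)
  low <- prof2$centerKHz <= 13.9
  ratio <- (sum(prof2$labeled[low]) / sum(prof2$total[low])) /
    (sum(prof2$labeled[!low]) / sum(prof2$total[!low]))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)
})
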