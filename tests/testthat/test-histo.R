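# Leveling, pooled histograms, auto-thresholding, label density.

mkStack <- function(images, rois = NULL, px = 4, spacing = 50) {
  n <- length(images)
  if (is.null(rois))
    rois <- lapply(images, function(m) matrix(TRUE, nrow(m), ncol(m)))
  tf <- rbind(c(px, 0, 0), c(0, px, 0), c(0, 0, 1))
  new("SectionStack", images = images, rois = rois,
      transforms = rep(list(tf), n), pixelSizeUm = px, spacingUm = spacing,
      sectionIndex = seq_len(n) - 1L)
}

test_that("leveling: equal means keep unit gains; the worked target/gain case", {
  s <- mkStack(list(matrix(80, 10, 10), matrix(80, 10, 10)))
  lev <- levelSections(s)
  expect_equal(lev$gains, c(1, 1))
  expect_equal(lev$target, 80)

  # means {50, 100}, maxima {100, 200} -> target 100, gains {2, 1}
  img1 <- matrix(0, 10, 10); img1[, 1:5] <- 100; img1[, 6:10] <- 0
  img2 <- img1 * 2
  s2 <- mkStack(list(img1, img2))
  lev2 <- levelSections(s2)
  expect_equal(lev2$target, 100)
  expect_equal(lev2$gains, c(2, 1))
  expect_true(all(vapply(sectionImages(lev2$stack), max, numeric(1)) <= 255))
})

test_that("leveling equalizes ROI means within 0.5 gray level and preserves rank order", {
  set.seed(31)
  imgs <- lapply(c(0.6, 1, 1.3), function(g)
    pmin(pmax(round(g * (60 + matrix(rnorm(900, sd = 15), 30, 30))), 0), 255))
  rois <- lapply(imgs, function(m) {
    r <- matrix(FALSE, 30, 30); r[5:25, 5:25] <- TRUE; r
  })
  s <- mkStack(imgs, rois)
  lev <- levelSections(s)
  means <- vapply(seq_len(3), function(i)
    mean(sectionImages(lev$stack)[[i]][rois[[i]]]), numeric(1))
  expect_lt(diff(range(means)), 0.5)
  # no rank inversions within a section
  for (i in 1:3) {
    before <- imgs[[i]][rois[[i]]]
    after <- sectionImages(lev$stack)[[i]][rois[[i]]]
    ord <- order(before)
    expect_true(all(diff(after[ord]) >= 0 | diff(before[ord]) == 0))
  }
  expect_error(levelSections(mkStack(list(matrix(0, 5, 5) + 0))), "zero ROI")
})

test_that("pooled histogram: point mass, additivity, total count", {
  s <- mkStack(list(matrix(37, 8, 8)))
  h <- pooledHistogram(s)
  expect_equal(sum(h), 64)
  expect_equal(unname(h[38]), 64L)

  set.seed(4)
  i1 <- matrix(sample(0:255, 100, TRUE), 10, 10)
  i2 <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_equal(pooledHistogram(mkStack(list(i1, i2))),
               pooledHistogram(mkStack(list(i1))) +
                 pooledHistogram(mkStack(list(i2))))
})

test_that("triangle threshold: separation, count-scale invariance, oracle equality", {
  h <- numeric(256); h[51] <- 1000; h[201] <- 10
  t0 <- triangleThreshold(h)
  expect_gt(t0, 50); expect_lt(t0, 200)
  expect_equal(triangleThreshold(h * 10), t0)

  ramp <- numeric(256); ramp[1:100] <- pmax(0, 100 - (0:99))
  expect_equal(triangleThreshold(ramp), oracleTriangle(ramp))

  for (s in 1:8) {
    h2 <- bimodalHistogram(seed = s, mix = runif(1, 0.02, 0.3))
    expect_equal(triangleThreshold(h2), oracleTriangle(h2))
  }
  one <- numeric(256); one[91] <- 5
  expect_equal(triangleThreshold(one), 90)
})

test_that("Renyi entropy threshold: per-alpha exhaustive-oracle equality and combination", {
  for (s in 1:8) {
    h <- bimodalHistogram(seed = 100 + s, mix = runif(1, 0.02, 0.3))
    p <- h / sum(h)
    for (a in c(0.5, 1, 2)) {
      expect_equal(centralgain:::renyiBestThreshold(p, a),
                   oracleRenyiAlpha(h, a))
    }
    t3 <- sort(vapply(c(0.5, 1, 2), function(a)
      oracleRenyiAlpha(h, a), integer(1)))
    tt <- renyiEntropyThreshold(h)
    expect_gte(tt, 0); expect_lte(tt, 255)
    # combined threshold lies in the hull of the three candidates
    # (weighted-average construction)
    expect_gte(tt, min(t3) - 1L)
    expect_lte(tt, max(t3))
  }
  # well-separated spikes: the threshold separates them for every alpha
  # (ties across the empty gap resolve to the first maximizing bin)
  h2 <- numeric(256); h2[41] <- 500; h2[221] <- 500
  for (a in c(0.5, 1, 2)) {
    ta <- oracleRenyiAlpha(h2, a)
    expect_gte(ta, 40); expect_lt(ta, 220)
  }
  expect_equal(renyiEntropyThreshold(h2), renyiEntropyThreshold(h2 * 7))
  one <- numeric(256); one[11] <- 3
  expect_equal(renyiEntropyThreshold(one), 10)
})

test_that("label density: boundary thresholds, monotonicity, ground-truth recovery", {
  set.seed(8)
  img <- matrix(sample(0:255, 400, TRUE), 20, 20)
  s <- mkStack(list(img))
  expect_equal(labelDensity(s, 0)$density, 1)
  expect_equal(labelDensity(s, 256)$density, 0)
  d <- vapply(seq(0, 256, by = 16), function(t)
    labelDensity(s, t)$density, numeric(1))
  expect_true(all(diff(d) <= 0))
  expect_error(labelDensity(s, 300), "threshold")

  # dark-label polarity
  expect_equal(labelDensity(s, 256, invert = TRUE)$density, 1)

  # phantom with known area fraction ~0.05 recovered within 20% relative
  spec <- smallPhantom(noiseSd = 3)
  sim <- generateVCNStack(spec, "sham", seed = 17)
  m <- measureLabelDensity(sim$stack, "triangle")
  expect_lt(abs(m$density - sim$truth$areaFraction) /
              sim$truth$areaFraction, 0.2)
})
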