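# ABR preprocessing, peak measurement, thresholds, ratios.

test_that("averaging: zeros stay zero and identical epochs average to themselves", {
  es <- new("EpochSet", stimulus = "click", frequencyKHz = NA_real_,
            levelDb = 70, sampleRate = 9500, onsetIndex = 20L,
            epochs = matrix(0, 1, 300))
  expect_equal(averageEpochs(es)@samples, rep(0, 300))

  set.seed(1)
  ep <- rnorm(300)
  es2 <- new("EpochSet", stimulus = "click", frequencyKHz = NA_real_,
             levelDb = 70, sampleRate = 9500, onsetIndex = 20L,
             epochs = rbind(ep, ep))
  one <- averageEpochs(new("EpochSet", stimulus = "click",
                           frequencyKHz = NA_real_, levelDb = 70,
                           sampleRate = 9500, onsetIndex = 20L,
                           epochs = rbind(ep)))
  expect_equal(averageEpochs(es2)@samples, one@samples)
})

test_that("band-pass attenuates 50 Hz by at least 20 dB relative to 1 kHz", {
  fs <- 9500
  t <- seq(0, 1, by = 1 / fs)
  x <- sin(2 * pi * 1000 * t) + sin(2 * pi * 50 * t)
  es <- new("EpochSet", stimulus = "click", frequencyKHz = NA_real_,
            levelDb = 70, sampleRate = fs, onsetIndex = 1L,
            epochs = rbind(x))
  y <- averageEpochs(es, band = c(300, 3000))@samples
  # project onto the two tones over an integer number of cycles
  n <- length(y)
  amp <- function(sig, f) {
    2 * abs(mean(sig * exp(-2i * pi * f * (seq_len(n) - 1) / fs)))
  }
  gain1k <- amp(y, 1000) / amp(x, 1000)
  gain50 <- amp(y, 50) / amp(x, 50)
  expect_gt(20 * log10(gain1k / gain50), 20)
})

test_that("band and epoch-count preconditions are enforced", {
  es <- new("EpochSet", stimulus = "click", frequencyKHz = NA_real_,
            levelDb = 70, sampleRate = 9500, onsetIndex = 20L,
            epochs = matrix(0, 2, 300))
  expect_error(averageEpochs(es, band = c(3000, 300)), "low < high")
  expect_error(averageEpochs(es, band = c(300, 5000)), "Nyquist")
})

test_that("window amplitude equals the exhaustive scan on every window", {
  wf <- abrWaveform(rep(2, 100), 9500, 10L)
  expect_equal(windowAmplitude(wf, 0, 5), 0)
  x <- rep(0, 100); x[30] <- -1; x[40] <- 2
  wf2 <- abrWaveform(x, 9500, 10L)
  expect_equal(windowAmplitude(wf2, 2, 4), 3)
  expect_error(windowAmplitude(wf2, 2, 500), "outside")

  set.seed(5)
  wf3 <- abrWaveform(rnorm(200), 9500, 15L)
  for (st in c(0, 2, 5, 10)) for (du in c(1, 4, 8)) {
    idx <- centralgain:::windowIndices(wf3, st, du)
    expect_equal(windowAmplitude(wf3, st, du),
                 oracleWindowScan(wf3@samples, idx))
  }
})

test_that("peak detection: noiseless latencies within one sample, amplitudes within 5% of analytic", {
  gt <- defaultABRTruth("sham")
  gt@noiseSdUv <- 0
  for (L in c(85, 65, 45)) {
    sim <- generateABR(gt, L, nEpochs = 1, seed = 1)
    wf <- averageEpochs(sim$epochSets[[1]], band = NULL)
    pk <- detectPeaks(wf)
    expect_true(all(pk$present))
    dtMs <- 1e3 / wf@sampleRate
    expect_true(all(abs(pk$latencyMs - abrTrueLatency(gt, L)) <= dtMs + 1e-9))
    truePT <- abrTruePeakToTrough(gt, L)
    expect_true(all(abs(pk$amplitudeUv - truePT) / truePT < 0.05))
    # latencies increase with peak number
    expect_true(all(diff(pk$latencyMs) > 0))
  }
})

test_that("peak detection: flat waveform yields four missing peaks", {
  wf <- abrWaveform(rep(0.5, 300), 9500, 20L)
  pk <- detectPeaks(wf)
  expect_true(all(!pk$present))
  expect_true(all(is.na(pk$amplitudeUv)))
})

test_that("time-shifting a waveform shifts latencies by exactly the shift", {
  gt <- defaultABRTruth("sham")
  gt@noiseSdUv <- 0
  sim <- generateABR(gt, 75, nEpochs = 1, seed = 1)
  wf <- averageEpochs(sim$epochSets[[1]], band = NULL)
  k <- 3L  # shift by 3 samples
  shifted <- abrWaveform(c(rep(0, k), wf@samples[1:(length(wf@samples) - k)]),
                         wf@sampleRate, wf@onsetIndex)
  d <- detectPeaks(shifted)$latencyMs - detectPeaks(wf)$latencyMs
  expect_equal(d, rep(k * 1e3 / wf@sampleRate, 4), tolerance = 1e-9)
})

test_that("threshold: flat responses are not reached, a step response localizes it", {
  mk <- function(level, amp) {
    x <- rep(0, 320)
    x[40:50] <- c(0, amp, 0, -amp, 0, amp, 0, -amp, 0, amp, 0)
    abrWaveform(x, 9500, 20L, levelDb = level)
  }
  flat <- lapply(c(20, 30, 40, 50), function(L) mk(L, 0))
  resFlat <- determineThreshold(flat)
  expect_false(resFlat$reached)
  expect_true(is.na(resFlat$threshold))
  expect_true(resFlat$degenerate)

  stepped <- lapply(c(20, 30, 40, 50, 60), function(L)
    mk(L, if (L >= 40) 5 else 0))
  res <- determineThreshold(stepped)
  expect_true(res$reached)
  expect_equal(res$threshold, 40)
})

test_that("threshold recovery: median estimate within one 5-dB step of the true threshold", {
  gt <- defaultABRTruth("sham")
  gt@thresholdDb <- 50
  est <- vapply(1:25, function(s) {
    sim <- generateABR(gt, seq(85, 20, by = -5), nEpochs = 300, seed = s)
    wfs <- lapply(sim$epochSets, averageEpochs)
    determineThreshold(wfs)$threshold
  }, numeric(1))
  expect_lte(abs(median(est) - 50), 5)
})

test_that("scale invariance: amplitudes scale, latencies/threshold/ratios do not", {
  gt <- defaultABRTruth("sham")
  sim <- generateABR(gt, seq(85, 25, by = -10), nEpochs = 100, seed = 13)
  wfs <- lapply(sim$epochSets, averageEpochs)
  scaled <- lapply(wfs, function(w) {
    w@samples <- w@samples * 3.7
    w
  })
  pk1 <- peakTable(wfs); pk2 <- peakTable(scaled)
  expect_equal(pk2$amplitudeUv, pk1$amplitudeUv * 3.7)
  expect_equal(pk2$latencyMs, pk1$latencyMs)
  expect_equal(determineThreshold(scaled)$threshold,
               determineThreshold(wfs)$threshold)
  expect_equal(amplitudeRatios(pk2)$p4p1, amplitudeRatios(pk1)$p4p1)
})

test_that("amplitude ratios: unit and half ratios, undefined without peak 1", {
  base <- data.frame(stimulus = "click", frequencyKHz = NA_real_,
                     levelDb = 70, peak = 1:4, present = TRUE,
                     latencyMs = 1:4, amplitudeUv = c(2, 2, 2, 2))
  r <- amplitudeRatios(base)
  expect_equal(unlist(r[, c("p2p1", "p3p1", "p4p1")]),
               c(p2p1 = 1, p3p1 = 1, p4p1 = 1))
  base$amplitudeUv <- c(2, 1.5, 1, 1)
  expect_equal(amplitudeRatios(base)$p4p1, 0.5)
  base$present[1] <- FALSE
  r3 <- amplitudeRatios(base)
  expect_false(r3$p1Defined)
  expect_true(is.na(r3$p2p1))
})

test_that("noise-exposed ratios exceed sham ratios at matched level", {
  shamT <- defaultABRTruth("sham")
  noiseT <- defaultABRTruth("noise")
  # analytic: ratios equal slope ratios wherever above threshold
  expect_gt(noiseT@peakSlopes[2] / noiseT@peakSlopes[1],
            shamT@peakSlopes[2] / shamT@peakSlopes[1])
  ratioAt <- function(gt, L, seed) {
    sim <- generateABR(gt, L, nEpochs = 200, seed = seed)
    amplitudeRatios(peakTable(list(averageEpochs(sim$epochSets[[1]]))))
  }
  rs <- ratioAt(shamT, 70, 31)
  rn <- ratioAt(noiseT, 80, 32)   # above the noise-arm click threshold
  expect_gt(rn$p2p1, rs$p2p1)
  expect_gt(rn$p4p1, rs$p4p1)
})

test_that("level-function slopes: exact line, zero slope, and preconditions", {
  suppressWarnings({   # lm warns on an exactly collinear fit
    expect_equal(levelFunctionSlope(c(1, 10, 100), c(10, 20, 30))[["slope"]],
                 0.1, tolerance = 1e-12)
    expect_equal(levelFunctionSlope(c(5, 5, 5, 5), c(10, 20, 30, 40),
                                    log = FALSE)[["slope"]], 0)
  })
  expect_error(levelFunctionSlope(c(1, 2), c(10, 20)), "3")
  # unbiasedness under noise
  set.seed(77)
  slopes <- replicate(100, {
    lev <- seq(30, 80, by = 10)
    y <- 10^(0.05 * lev + rnorm(length(lev), sd = 0.05))
    levelFunctionSlope(y, lev)[["slope"]]
  })
  expect_lt(abs(mean(slopes) - 0.05), 3 * sd(slopes) / 10)
})
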