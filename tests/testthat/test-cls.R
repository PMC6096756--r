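# Lick-suppression psychophysics: QC, criterion, d', thresholds.

mkSession <- function(pre, post, type, level = NULL, freq = 16) {
  n <- length(type)
  lev <- rep(NA_real_, n)
  if (!is.null(level)) lev[type == "warning"] <- level
  new("LickSession", frequencyKHz = freq, type = type, levelDb = lev,
      preBins = pre, postBins = post)
}

binsWithCount <- function(k) {
  v <- integer(35)
  if (k > 0) v[seq_len(k)] <- 1L
  v
}

test_that("subject QC applies the 20-bin and 10% safe-trial rules", {
  allLick <- mkSession(matrix(1L, 4, 35), matrix(1L, 4, 35),
                       rep("safe", 4))
  q <- qcSubject(list(allLick))
  expect_true(q$pass)
  expect_equal(q$perSession$meanPreCount, 35)
  expect_equal(q$perSession$safeDiffPct, 0)

  low <- mkSession(t(replicate(4, binsWithCount(19))), matrix(1L, 4, 35),
                   rep("safe", 4))
  expect_false(qcSubject(list(low))$pass)
  expect_false(qcSubject(list(low))$perSession$preCountOk)

  supp <- mkSession(t(replicate(4, binsWithCount(30))),
                    t(replicate(4, binsWithCount(26))), rep("safe", 4))
  q3 <- qcSubject(list(supp))
  expect_false(q3$pass)
  expect_equal(q3$perSession$safeDiffPct, 100 * 4 / 30, tolerance = 1e-9)
})

test_that("criterion selection matches the enumeration rule", {
  # uniform safe post-counts 0..34: FA at criterion 5 is 6/35 (closest)
  sel <- selectCriterion(0:34)
  expect_equal(sel$criterion, 5L)
  expect_equal(sel$faRate, 6 / 35)
  expect_false(sel$degenerate)

  # degenerate: all post-counts 35 -> FA 0 everywhere below 35
  selD <- selectCriterion(rep(35L, 20))
  expect_equal(selD$criterion, 34L)
  expect_true(selD$degenerate)

  expect_error(selectCriterion(1:5), "10")

  # invariance to trial order
  set.seed(2)
  counts <- rbinom(100, 35, 0.9)
  expect_identical(selectCriterion(counts), selectCriterion(rev(counts)))

  # realized FA near the target under a realistic baseline
  fa <- vapply(1:40, function(s) {
    set.seed(s)
    selectCriterion(rbinom(200, 35, 0.9))$faRate
  }, numeric(1))
  expect_true(median(fa) >= 0.10 && median(fa) <= 0.22)
})

test_that("d' geometry matches the normal-quantile oracle", {
  expect_equal(dprime(0.4, 0.4, 50, 50), 0)
  expect_equal(dprime(0.502, 0.16, 50, 50), 1.0, tolerance = 5e-3)
  expect_equal(dprime(0.84, 0.16, 50, 50),
               qnorm(0.84) - qnorm(0.16), tolerance = 1e-12)
  expect_equal(qnorm(0.84) - qnorm(0.16), 1.989, tolerance = 1e-3)
  # 0/1 correction
  expect_equal(dprime(1, 0, 25, 40),
               qnorm(1 - 1 / 50) - qnorm(1 / 80))
  # antisymmetry and monotonicity in the hit rate
  expect_equal(dprime(0.8, 0.2, 30, 30), -dprime(0.2, 0.8, 30, 30))
  d <- vapply(seq(0.2, 0.95, by = 0.05), dprime, numeric(1),
              faRate = 0.16, nHitTrials = 50, nFaTrials = 50)
  expect_true(all(diff(d) > 0))
})

test_that("threshold interpolation: midpoint, exact hit, refusal to extrapolate", {
  expect_equal(thresholdAtDprime(c(40, 50), c(0.5, 1.5))$threshold, 45)
  r <- thresholdAtDprime(c(50, 60, 70), c(0.2, 1.0, 2.0))
  expect_equal(r$threshold, 60)
  expect_equal(thresholdAtDprime(c(40, 50), c(0.2, 0.8))$status,
               "not_reached")
  ceilingRes <- thresholdAtDprime(c(40, 50), c(1.2, 2.0))
  expect_equal(ceilingRes$status, "ceiling")
  expect_equal(ceilingRes$threshold, 40)
})

test_that("raising all d' values never raises the threshold", {
  set.seed(9)
  for (i in 1:20) {
    lev <- seq(30, 80, by = 10)
    dp <- sort(runif(length(lev), -0.5, 3))
    r1 <- thresholdAtDprime(lev, dp)
    r2 <- thresholdAtDprime(lev, dp + 0.3)
    if (r1$status == "ok" && r2$status == "ok")
      expect_lte(r2$threshold, r1$threshold + 1e-9)
  }
})

test_that("session aggregation finds the latest stable run", {
  a <- aggregateThresholds(c(60, 41, 40, 42))
  expect_equal(a$status, "stable")
  expect_equal(a$threshold, 41)
  expect_equal(aggregateThresholds(c(40, 50, 60))$status, "unstable")
  b <- aggregateThresholds(c(44, 43, 41, 42))
  expect_equal(b$threshold, 42.5)   # last 4 of the stable run
  expect_equal(length(b$runSessions), 4L)
  # warning-trial bookkeeping
  cc <- aggregateThresholds(c(41, 40, 42), warningCounts = c(`60` = 25, `70` = 18))
  expect_false(cc$enoughWarnings)
  expect_error(aggregateThresholds(c(40, 41)), "3")
})

test_that("full pipeline recovers the analytic d'=1 level within 3 dB", {
  gt <- clsTruth(thresholdDb = 45, slopeDb = 4, hitMax = 0.95, faRate = 0.16)
  analytic <- clsAnalyticThreshold(gt)
  err <- vapply(1:30, function(s) {
    ses <- generateCLSSession(gt, seq(20, 80, 10), 50, seed = s)$session
    analyzeSession(ses)$threshold - analytic
  }, numeric(1))
  expect_lte(median(abs(err)), 3)
})

test_that("lick-session CSV round-trips", {
  ses <- generateCLSSession(clsTruth(), c(40, 60), 5, seed = 12)$session
  f <- tempfile(fileext = ".csv")
  writeLickSessionCSV(ses, f)
  back <- readLickSessionCSV(f, frequencyKHz = 16)
  expect_identical(back@postBins, ses@postBins)
  expect_identical(back@type, ses@type)
  expect_equal(back@levelDb, ses@levelDb)
  unlink(f)
})
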