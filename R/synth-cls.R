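# Synthetic conditioned lick-suppression sessions.

#' Construct CLS ground truth
#'
#' @param thresholdDb psychometric midpoint (dB SPL).
#' @param slopeDb psychometric spread (dB).
#' @param hitMax asymptotic suppression probability.
#' @param faRate floor suppression probability.
#' @param lickRate baseline per-bin lick probability.
#' @return a [CLSGroundTruth-class].
#' @export
clsTruth <- function(thresholdDb = 45, slopeDb = 4, hitMax = 0.95,
                     faRate = 0.16, lickRate = 0.9) {
  new("CLSGroundTruth", thresholdDb = thresholdDb, slopeDb = slopeDb,
      hitMax = hitMax, faRate = faRate, lickRate = lickRate)
}

# Probability that a warning trial at level L is suppressed.
clsSuppressionProb <- function(truth, levelDb) {
  truth@faRate + (truth@hitMax - truth@faRate) *
    pnorm((levelDb - truth@thresholdDb) / truth@slopeDb)
}

#' Generate a synthetic lick-suppression session
#'
#' Every trial carries 35 pre-stimulus and 35 post-stimulus 20-ms bins with
#' Bernoulli lick indicators at the baseline rate. On a warning trial at
#' level L, suppression occurs with probability
#' `faRate + (hitMax - faRate) * pnorm((L - threshold) / slope)`; a
#' suppressed trial has its post-stimulus lick probability multiplied by
#' zero (complete cessation), an unsuppressed one licks at the baseline
#' rate throughout. Safe trials always use the baseline rate.
#'
#' @param truth a [CLSGroundTruth-class].
#' @param levels warning-trial levels (dB SPL).
#' @param nWarningPerLevel warning trials per level (>= 1).
#' @param safeFraction fraction of all trials that are safe (default 0.75,
#'   i.e. warnings presented with ~25\% probability).
#' @param seed integer seed.
#' @param frequencyKHz tone frequency tested (metadata).
#' @return list with `session` (a [LickSession-class], trials in random
#'   presentation order) and `truth`.
#' @export
generateCLSSession <- function(truth, levels, nWarningPerLevel,
                               safeFraction = 0.75, seed,
                               frequencyKHz = 16) {
  stopifnot(is(truth, "CLSGroundTruth"), length(levels) >= 1)
  if (nWarningPerLevel < 1) stop("nWarningPerLevel must be >= 1")
  if (safeFraction < 0 || safeFraction >= 1)
    stop("safeFraction must lie in [0, 1)")
  nWarn <- length(levels) * nWarningPerLevel
  nSafe <- round(nWarn * safeFraction / (1 - safeFraction))
  withSeed(seed, {
    lev <- c(rep(levels, each = nWarningPerLevel), rep(NA_real_, nSafe))
    type <- c(rep("warning", nWarn), rep("safe", nSafe))
    ord <- sample.int(length(lev))
    lev <- lev[ord]; type <- type[ord]
    n <- length(lev)
    pre <- matrix(rbinom(n * 35L, 1L, truth@lickRate), nrow = n)
    postRate <- rep(truth@lickRate, n)
    warn <- type == "warning"
    supp <- rep(FALSE, n)
    supp[warn] <- runif(sum(warn)) < clsSuppressionProb(truth, lev[warn])
    postRate[supp] <- 0
    post <- matrix(rbinom(n * 35L, 1L, rep(postRate, 35L)), nrow = n)
    session <- new("LickSession", frequencyKHz = frequencyKHz, type = type,
                   levelDb = lev, preBins = pre, postBins = post)
    list(session = session, truth = truth)
  })
}

#' Analytic d' = target level of the CLS ground truth
#'
#' Closed-form detection threshold implied by the generator: the criterion
#' is chosen on the safe post-bin count distribution Binomial(35, lickRate)
#' exactly as [selectCriterion()] does; the hit rate at level L is
#' `p_supp(L) + (1 - p_supp(L)) * FA`, and the returned level solves
#' `qnorm(H(L)) - qnorm(FA) = target`.
#'
#' This is the ground-truth oracle against which recovered behavioral
#' thresholds are validated; the analysis chain never uses it.
#'
#' @param truth a [CLSGroundTruth-class].
#' @param target target d' (default 1.0).
#' @param targetFa false-alarm rate targeted by the criterion rule.
#' @return level in dB SPL.
#' @export
clsAnalyticThreshold <- function(truth, target = 1.0, targetFa = 0.16) {
  faByCrit <- pbinom(0:35, 35, truth@lickRate)
  crit <- which.min(abs(faByCrit - targetFa)) - 1L
  fa <- faByCrit[crit + 1L]
  dprimeAt <- function(L) {
    h <- clsSuppressionProb(truth, L) * (1 - fa) + fa
    qnorm(h) - qnorm(fa)
  }
  lo <- truth@thresholdDb - 20 * truth@slopeDb
  hi <- truth@thresholdDb + 20 * truth@slopeDb
  uniroot(function(L) dprimeAt(L) - target, c(lo, hi))$root
}
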