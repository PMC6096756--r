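# Acoustic startle: synthetic trials, quiet-period gating, growth functions.

#' Generate synthetic startle trials
#'
#' Each trial couples a 5-s baseline movement trace with a 100-ms response
#' trace. Trace RMS amplitudes are controlled exactly: the baseline trace
#' has RMS `baselineLevel` (over its final 1 s) and the response trace RMS
#' `a * baselineLevel`, where the relative amplitude `a` is the specified
#' per-level mean plus zero-mean Gaussian trial-to-trial noise. With
#' `noiseSd = 0` the carrier is deterministic, so measured ratios equal
#' the specified means exactly.
#'
#' @param meanResponseByLevel named numeric: mean relative startle
#'   amplitude per level (names are dB SPL); all values >= 0.
#' @param baselineLevel RMS of the baseline movement signal (sensor units).
#' @param noiseSd SD of the trial-to-trial relative-amplitude noise (>= 0).
#' @param nTrials trials per level.
#' @param seed integer seed.
#' @param baselineRate,responseRate trace sampling rates (Hz).
#' @return a [StartleTrialSet-class].
#' @export
generateStartleTrials <- function(meanResponseByLevel, baselineLevel = 1,
                                  noiseSd = 0.2, nTrials = 10, seed,
                                  baselineRate = 500, responseRate = 500) {
  if (any(meanResponseByLevel < 0)) stop("response means must be >= 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (is.null(names(meanResponseByLevel)))
    stop("meanResponseByLevel must be named by level (dB SPL)")
  nB <- round(5 * baselineRate)
  nR <- round(0.1 * responseRate)
  levels <- as.numeric(names(meanResponseByLevel))
  carrier <- function(n, amp) {
    if (noiseSd == 0) rep(amp, n)
    else {
      x <- rnorm(n)
      x / rms(x) * amp
    }
  }
  withSeed(seed, {
    lev <- rep(levels, each = nTrials)
    amps <- pmax(0, rep(meanResponseByLevel, each = nTrials) +
                      rnorm(length(lev), sd = noiseSd))
    base <- t(vapply(seq_along(lev),
                     function(i) carrier(nB, baselineLevel), numeric(nB)))
    # normalize the final 1-s window (the measurement window) to exact RMS
    lastSec <- (nB - baselineRate + 1):nB
    scl <- baselineLevel / apply(base[, lastSec, drop = FALSE], 1, rms)
    base <- base * scl
    resp <- t(vapply(seq_along(lev),
                     function(i) carrier(nR, amps[i] * baselineLevel),
                     numeric(nR)))
    new("StartleTrialSet", levelDb = lev, baseline = base, response = resp,
        baselineRate = baselineRate, responseRate = responseRate)
  })
}

#' Find the onset of a 5-s quiet period
#'
#' Scans a movement signal for the first time at which the trailing 5-s
#' window has RMS below the stillness threshold, i.e. the earliest moment
#' a startle stimulus could be presented.
#'
#' @param signal numeric movement samples.
#' @param sampleRate Hz; the signal must cover at least 5 s.
#' @param thresholdSd stillness threshold on the windowed RMS.
#' @param quietSec length of the required quiet window (default 5 s).
#' @return onset time in seconds, or `NA` when the animal is never still.
#' @export
quietGate <- function(signal, sampleRate, thresholdSd, quietSec = 5) {
  w <- round(quietSec * sampleRate)
  if (length(signal) < w) stop("signal must cover at least ", quietSec, " s")
  cs <- cumsum(c(0, signal^2))
  ends <- w:length(signal)
  winRms <- sqrt((cs[ends + 1] - cs[ends + 1 - w]) / w)
  hit <- which(winRms < thresholdSd)
  if (!length(hit)) return(NA_real_)
  ends[hit[1]] / sampleRate
}

#' Relative startle amplitude of one trial
#'
#' RMS of the 100-ms response trace divided by the RMS of the final 1 s of
#' the baseline trace (dimensionless).
#'
#' @param trials a [StartleTrialSet-class].
#' @param i trial index.
#' @return relative amplitude (scalar).
#' @export
startleAmplitude <- function(trials, i) {
  stopifnot(is(trials, "StartleTrialSet"))
  nB <- ncol(trials@baseline)
  lastSec <- (nB - round(trials@baselineRate) + 1):nB
  b <- rms(trials@baseline[i, lastSec])
  if (b == 0) stop("zero baseline RMS in trial ", i)
  rms(trials@response[i, ]) / b
}

#' Startle growth function
#'
#' Per-level mean and SEM of relative startle amplitudes, levels ascending.
#'
#' @param trials a [StartleTrialSet-class].
#' @return data.frame with `levelDb`, `n`, `mean`, `sem` (SEM is `NA` for
#'   singleton levels).
#' @export
growthFunction <- function(trials) {
  stopifnot(is(trials, "StartleTrialSet"))
  amps <- vapply(seq_along(trials@levelDb),
                 function(i) startleAmplitude(trials, i), numeric(1))
  levels <- sort(unique(trials@levelDb))
  out <- do.call(rbind, lapply(levels, function(L) {
    a <- amps[trials@levelDb == L]
    data.frame(levelDb = L, n = length(a), mean = mean(a),
               sem = if (length(a) > 1) sd(a) / sqrt(length(a)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
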