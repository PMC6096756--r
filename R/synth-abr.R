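# Synthetic ABR epochs: four biphasic wavelets on Gaussian noise.

# Biphasic (derivative-of-Gaussian) wavelet, unit positive peak at u = 0 and
# unit trough at u = 2 (u in units of sigma).
abrWavelet <- function(u) -(u - 1) * exp((1 - (u - 1)^2) / 2)

#' Default ABR ground-truth parameter sets
#'
#' Condition-specific parameters emulating the canonical noise-exposure
#' phenotype: elevated thresholds, strongly reduced peak-1 growth, and
#' relatively preserved later peaks, so that amplitude ratios p2:p1 ... p4:p1
#' come out larger in the noise condition (central gain).
#'
#' Tone thresholds follow a mouse-audiogram-shaped profile, with
#' noise-induced shifts largest at 16-24 kHz.
#'
#' @param condition `"sham"` or `"noise"`.
#' @param frequencyKHz tone frequency in kHz, or `NA` for a click.
#' @return an [ABRGroundTruth-class] object.
#' @examples
#' defaultABRTruth("noise", frequencyKHz = 16)
#' @export
defaultABRTruth <- function(condition = c("sham", "noise"),
                            frequencyKHz = NA_real_) {
  condition <- match.arg(condition)
  freqs <- c(6, 8, 12, 16, 24, 32)
  shamThr <- c(click = 30, setNames(c(35, 30, 25, 25, 30, 40), freqs))
  shift <- c(click = 20, setNames(c(5, 8, 15, 30, 30, 25), freqs))
  key <- if (is.na(frequencyKHz)) "click" else as.character(frequencyKHz)
  if (!key %in% names(shamThr))
    stop("no default threshold for frequency ", frequencyKHz, " kHz")
  thr <- shamThr[[key]] + if (condition == "noise") shift[[key]] else 0
  slopes <- if (condition == "sham") c(0.100, 0.075, 0.055, 0.065)
            else c(0.045, 0.051, 0.036, 0.053)
  new("ABRGroundTruth",
      condition = condition,
      thresholdDb = thr,
      peakSlopes = slopes,
      latencyInterceptMs = c(2.3, 3.3, 4.3, 5.3),
      latencySlopeMsPerDb = rep(-0.01, 4),
      sigmaMs = rep(0.2, 4),
      noiseSdUv = 3)
}

#' True peak-to-trough amplitudes of the synthetic ABR
#'
#' Closed-form peak-to-trough amplitude of each wavelet component:
#' `2 * max(0, slope_k * (L - threshold))`.
#'
#' @param truth an [ABRGroundTruth-class].
#' @param levelDb stimulus level (dB SPL).
#' @return numeric length 4 (microvolts).
#' @export
abrTruePeakToTrough <- function(truth, levelDb) {
  2 * pmax(0, truth@peakSlopes * (levelDb - truth@thresholdDb))
}

#' True positive-peak latencies of the synthetic ABR
#'
#' @param truth an [ABRGroundTruth-class].
#' @param levelDb stimulus level (dB SPL).
#' @return numeric length 4 (ms re stimulus onset).
#' @export
abrTrueLatency <- function(truth, levelDb) {
  truth@latencyInterceptMs + truth@latencySlopeMsPerDb * levelDb
}

#' Generate synthetic ABR epochs across levels
#'
#' Each epoch is the sum of four biphasic (derivative-of-Gaussian) wavelets
#' plus white Gaussian noise. Peak k at level L has peak-to-trough amplitude
#' `2 * max(0, slope_k * (L - threshold))` microvolts, positive-peak latency
#' `latencyIntercept_k + latencySlope_k * L` ms, and width `sigma_k` ms.
#'
#' @param truth an [ABRGroundTruth-class].
#' @param levels dB SPL levels to simulate (any order).
#' @param nEpochs number of stimulus repetitions per level (>= 1).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param stimulus `"click"` or `"tone"`.
#' @param frequencyKHz tone frequency (kHz), `NA` for clicks.
#' @param sampleRate sampling rate in Hz (default 9500).
#' @param preMs,postMs record extent before/after stimulus onset (ms). The
#'   default post-onset extent of 30 ms accommodates both the 2-10 ms
#'   response window and the 20-28 ms baseline window.
#' @return list with `epochSets` (one [EpochSet-class] per level, in the
#'   order of `levels`) and `truth` (the generator parameters, for
#'   validation only; analysis functions must not read it).
#' @examples
#' gt <- defaultABRTruth("sham")
#' sim <- generateABR(gt, levels = c(70, 50), nEpochs = 20, seed = 1)
#' sim$epochSets[[1]]
#' @export
generateABR <- function(truth, levels, nEpochs, seed,
                        stimulus = c("click", "tone"),
                        frequencyKHz = NA_real_,
                        sampleRate = 9500, preMs = 2, postMs = 30) {
  stimulus <- match.arg(stimulus)
  stopifnot(is(truth, "ABRGroundTruth"), length(levels) >= 1)
  if (nEpochs < 1) stop("nEpochs must be >= 1")
  # wavelet energy extends to roughly 3 / (2*pi*sigma) Hz; demand Nyquist
  # headroom of a factor 2 over that bandwidth
  bwHz <- 3 / (2 * pi * min(truth@sigmaMs) * 1e-3)
  if (sampleRate <= 2 * bwHz)
    stop("sampleRate must exceed twice the wavelet bandwidth (",
         round(2 * bwHz), " Hz)")
  nPre <- as.integer(round(preMs * 1e-3 * sampleRate))
  nPost <- as.integer(round(postMs * 1e-3 * sampleRate))
  n <- nPre + nPost
  onset <- nPre + 1L
  tMs <- (seq_len(n) - onset) / sampleRate * 1e3
  withSeed(seed, {
    sets <- lapply(levels, function(L) {
      amp <- truth@peakSlopes * pmax(0, L - truth@thresholdDb)  # 0-to-peak
      tau <- abrTrueLatency(truth, L)
      clean <- rep(0, n)
      for (k in 1:4) {
        if (amp[k] > 0)
          clean <- clean + amp[k] * abrWavelet((tMs - tau[k]) / truth@sigmaMs[k])
      }
      noise <- matrix(rnorm(nEpochs * n, sd = truth@noiseSdUv),
                      nrow = nEpochs)
      ep <- sweep(noise, 2, clean, "+")
      new("EpochSet", stimulus = stimulus, frequencyKHz = frequencyKHz,
          levelDb = L, sampleRate = sampleRate, onsetIndex = onset,
          epochs = ep)
    })
    list(epochSets = sets, truth = truth)
  })
}
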