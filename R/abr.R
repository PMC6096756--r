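# ABR preprocessing, peak measurement, thresholds, amplitude ratios.

#' Averaged, filtered ABR waveform
#'
#' @slot samples numeric vector (microvolts).
#' @slot sampleRate Hz.
#' @slot onsetIndex 1-based stimulus-onset sample.
#' @slot stimulus `"click"` or `"tone"`.
#' @slot frequencyKHz tone frequency (kHz; `NA` for clicks).
#' @slot levelDb presentation level (dB SPL).
#' @exportClass ABRWaveform
setClass("ABRWaveform",
  representation(
    samples = "numeric",
    sampleRate = "numeric",
    onsetIndex = "integer",
    stimulus = "character",
    frequencyKHz = "numeric",
    levelDb = "numeric"
  ),
  validity = function(object) {
    if (object@sampleRate <= 0) return("sampleRate must be > 0")
    if (object@onsetIndex < 1L || object@onsetIndex > length(object@samples))
      return("onsetIndex must lie within the record")
    TRUE
  }
)

setMethod("show", "ABRWaveform", function(object) {
  cat(sprintf("ABRWaveform: %s %s dB, %d samples @ %g Hz\n",
              if (object@stimulus == "click") "click"
              else sprintf("%g kHz", object@frequencyKHz),
              format(object@levelDb), length(object@samples),
              object@sampleRate))
})

#' Construct an [ABRWaveform-class] from raw samples
#'
#' @param samples numeric vector (microvolts).
#' @param sampleRate Hz.
#' @param onsetIndex stimulus-onset sample (1-based).
#' @param stimulus,frequencyKHz,levelDb stimulus metadata.
#' @return an `ABRWaveform`.
#' @export
abrWaveform <- function(samples, sampleRate, onsetIndex,
                        stimulus = "click", frequencyKHz = NA_real_,
                        levelDb = NA_real_) {
  new("ABRWaveform", samples = as.numeric(samples),
      sampleRate = sampleRate, onsetIndex = as.integer(onsetIndex),
      stimulus = stimulus, frequencyKHz = frequencyKHz, levelDb = levelDb)
}

#' Band-pass filter and average ABR epochs
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth band-pass
#' to every epoch, then averages pointwise across epochs. The default
#' 300-3000 Hz band is the standard ABR recording band.
#'
#' @param epochSet an [EpochSet-class].
#' @param band numeric length 2, `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < sampleRate / 2`. `NULL` skips filtering.
#' @return an [ABRWaveform-class].
#' @examples
#' sim <- generateABR(defaultABRTruth("sham"), 70, nEpochs = 50, seed = 1)
#' wf <- averageEpochs(sim$epochSets[[1]])
#' @export
averageEpochs <- function(epochSet, band = c(300, 3000)) {
  stopifnot(is(epochSet, "EpochSet"))
  ep <- epochSet@epochs
  if (nrow(ep) < 1L) stop("need at least one epoch")
  avg <- colMeans(ep)
  if (!is.null(band)) {
    if (length(band) != 2L || band[1] >= band[2])
      stop("band must be c(low, high) with low < high")
    nyq <- epochSet@sampleRate / 2
    if (band[1] <= 0 || band[2] >= nyq)
      stop("band must lie strictly inside (0, Nyquist)")
    bf <- signal::butter(4, band / nyq, type = "pass")
    # the zero-phase filter is linear, so filtering the pointwise mean is
    # identical to averaging per-epoch filtered records
    avg <- signal::filtfilt(bf, avg)
  }
  abrWaveform(avg, epochSet@sampleRate, epochSet@onsetIndex,
              epochSet@stimulus, epochSet@frequencyKHz, epochSet@levelDb)
}

# Sample indices of the half-open window [startMs, startMs + durMs) re onset.
windowIndices <- function(waveform, startMs, durMs) {
  fs <- waveform@sampleRate
  t0 <- waveform@onsetIndex + startMs * 1e-3 * fs
  t1 <- waveform@onsetIndex + (startMs + durMs) * 1e-3 * fs
  idx <- seq(ceiling(t0 - 1e-9), ceiling(t1 - 1e-9) - 1L)
  if (length(idx) < 1 || min(idx) < 1 || max(idx) > length(waveform@samples))
    stop("window [", startMs, ", ", startMs + durMs, ") ms lies outside the record")
  idx
}

#' Peak-to-peak amplitude within a time window
#'
#' Maximum minus minimum of the samples inside the half-open window
#' `[startMs, startMs + durMs)` re stimulus onset.
#'
#' @param waveform an [ABRWaveform-class].
#' @param startMs window start (ms re onset).
#' @param durMs window duration (ms).
#' @return amplitude in microvolts (scalar).
#' @export
windowAmplitude <- function(waveform, startMs, durMs) {
  stopifnot(is(waveform, "ABRWaveform"))
  x <- waveform@samples[windowIndices(waveform, startMs, durMs)]
  max(x) - min(x)
}

#' Default peak latency search windows (ms re onset)
#'
#' @return list of length-2 numeric vectors for peaks 1-4.
#' @export
defaultPeakWindows <- function() {
  list(p1 = c(0.8, 2.2), p2 = c(1.8, 3.2),
       p3 = c(2.8, 4.4), p4 = c(3.8, 5.8))
}

#' Detect ABR peaks 1-4
#'
#' For each peak, the largest local maximum inside its latency search
#' window is taken; its amplitude is the maximum minus the deepest trough
#' between it and the following peak's maximum (after peak 4: within a
#' fixed 1.2-ms tail). A window without a local maximum yields a missing
#' peak, not an error.
#'
#' @param waveform an [ABRWaveform-class] covering at least 10 ms post
#'   onset.
#' @param windowsMs list of 4 latency windows (ms re onset), see
#'   [defaultPeakWindows()].
#' @param troughTailMs trough search extent after the last peak (ms).
#' @return data.frame with columns `peak`, `present`, `latencyMs`,
#'   `amplitudeUv`.
#' @export
detectPeaks <- function(waveform, windowsMs = defaultPeakWindows(),
                        troughTailMs = 1.2) {
  stopifnot(is(waveform, "ABRWaveform"), length(windowsMs) == 4L)
  fs <- waveform@sampleRate
  x <- waveform@samples
  n <- length(x)
  postMs <- (n - waveform@onsetIndex) / fs * 1e3
  if (postMs < 10) stop("waveform must cover at least 10 ms post onset")

  peakIdx <- rep(NA_integer_, 4)
  for (k in 1:4) {
    w <- windowsMs[[k]]
    idx <- windowIndices(waveform, w[1], w[2] - w[1])
    idx <- idx[idx > 1 & idx < n]
    # successive peaks must advance in time even where the default search
    # windows overlap, so restrict to samples after the previous maximum
    prev <- peakIdx[seq_len(k - 1)]
    prev <- prev[!is.na(prev)]
    if (length(prev)) idx <- idx[idx > max(prev)]
    isMax <- x[idx] > x[idx - 1] & x[idx] >= x[idx + 1]
    cand <- idx[isMax]
    if (length(cand)) peakIdx[k] <- cand[which.max(x[cand])]
  }

  lat <- rep(NA_real_, 4)
  amp <- rep(NA_real_, 4)
  tail <- round(troughTailMs * 1e-3 * fs)
  for (k in 1:4) {
    if (is.na(peakIdx[k])) next
    lat[k] <- (peakIdx[k] - waveform@onsetIndex) / fs * 1e3
    nxt <- if (k < 4) peakIdx[(k + 1):4] else NA_integer_
    nxt <- nxt[!is.na(nxt)]
    stopIdx <- if (length(nxt)) nxt[1] - 1L else min(n, peakIdx[k] + tail)
    stopIdx <- min(stopIdx, n)
    rng <- seq(peakIdx[k], stopIdx)
    amp[k] <- x[peakIdx[k]] - min(x[rng])
  }
  data.frame(peak = 1:4, present = !is.na(peakIdx),
             latencyMs = lat, amplitudeUv = amp)
}

#' Build a tidy peak table over a set of averaged waveforms
#'
#' @param waveforms list of [ABRWaveform-class] objects (typically one per
#'   level of one stimulus).
#' @param ... passed to [detectPeaks()].
#' @return data.frame with one row per waveform x peak: `stimulus`,
#'   `frequencyKHz`, `levelDb`, `peak`, `present`, `latencyMs`,
#'   `amplitudeUv`.
#' @export
peakTable <- function(waveforms, ...) {
  do.call(rbind, lapply(waveforms, function(wf) {
    pk <- detectPeaks(wf, ...)
    cbind(data.frame(stimulus = wf@stimulus,
                     frequencyKHz = wf@frequencyKHz,
                     levelDb = wf@levelDb), pk)
  }))
}

#' Determine the ABR threshold by the 2-SD baseline criterion
#'
#' The criterion is the mean plus twice the standard deviation of the
#' baseline-window amplitudes pooled across all tested levels of the
#' stimulus. The threshold is the lowest tested level whose
#' response-window amplitude meets the criterion with every higher tested
#' level also meeting it; if the highest level fails, the threshold is
#' "not reached".
#'
#' @param waveforms list of [ABRWaveform-class] objects for one stimulus at
#'   different levels (any order; at least 2).
#' @param responseStartMs,responseDurMs response window (default 2-10 ms).
#' @param baselineStartMs,baselineDurMs baseline window (default 20-28 ms).
#' @return list with `threshold` (dB SPL, `NA` when not reached),
#'   `reached`, `criterion` (microvolts), `degenerate` (zero-variance
#'   zero-mean baseline), and `perLevel` (data.frame of level, response and
#'   baseline amplitudes).
#' @export
determineThreshold <- function(waveforms,
                               responseStartMs = 2, responseDurMs = 8,
                               baselineStartMs = 20, baselineDurMs = 8) {
  if (length(waveforms) < 2) stop("need waveforms at >= 2 levels")
  levels <- vapply(waveforms, function(w) w@levelDb, numeric(1))
  respAmp <- vapply(waveforms, windowAmplitude, numeric(1),
                    startMs = responseStartMs, durMs = responseDurMs)
  baseAmp <- vapply(waveforms, windowAmplitude, numeric(1),
                    startMs = baselineStartMs, durMs = baselineDurMs)
  ord <- order(levels)
  levels <- levels[ord]; respAmp <- respAmp[ord]; baseAmp <- baseAmp[ord]
  degenerate <- sd(baseAmp) == 0 && mean(baseAmp) == 0
  criterion <- mean(baseAmp) + 2 * sd(baseAmp)
  # "above" the criterion is strict: a response indistinguishable from the
  # baseline (zero-variance tie) must not count as a threshold passage
  pass <- respAmp > criterion
  # lowest level with this and every higher level passing
  okAbove <- rev(cumprod(rev(pass))) == 1
  thr <- if (any(okAbove)) levels[which(okAbove)[1]] else NA_real_
  list(threshold = thr, reached = !is.na(thr), criterion = criterion,
       degenerate = degenerate,
       perLevel = data.frame(levelDb = levels, responseUv = respAmp,
                             baselineUv = baseAmp))
}

#' Central-gain amplitude ratios p2:p1, p3:p1, p4:p1
#'
#' @param peaks a data.frame from [peakTable()].
#' @return data.frame with one row per (stimulus, frequency, level):
#'   columns `p2p1`, `p3p1`, `p4p1` and `p1Defined`. Ratios are `NA`
#'   (flagged by `p1Defined = FALSE`) where peak 1 is missing or zero.
#' @export
amplitudeRatios <- function(peaks) {
  fkey <- ifelse(is.na(peaks$frequencyKHz), "click", peaks$frequencyKHz)
  key <- interaction(peaks$stimulus, fkey, peaks$levelDb, drop = TRUE)
  out <- lapply(split(peaks, key), function(d) {
    amp <- rep(NA_real_, 4)
    amp[d$peak] <- ifelse(d$present, d$amplitudeUv, NA)
    ok <- !is.na(amp[1]) && amp[1] > 0
    data.frame(stimulus = d$stimulus[1], frequencyKHz = d$frequencyKHz[1],
               levelDb = d$levelDb[1],
               p2p1 = if (ok) amp[2] / amp[1] else NA_real_,
               p3p1 = if (ok) amp[3] / amp[1] else NA_real_,
               p4p1 = if (ok) amp[4] / amp[1] else NA_real_,
               p1Defined = ok)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$stimulus, res$frequencyKHz, res$levelDb), , drop = FALSE]
}

#' Slope of a level function
#'
#' Ordinary least-squares slope of (optionally log10-transformed) values
#' against level. Amplitudes are conventionally log-transformed; latencies
#' are fitted raw.
#'
#' @param values numeric response values (amplitudes or latencies).
#' @param levels dB SPL levels, same length.
#' @param log apply log10 to `values` first (default TRUE).
#' @return named numeric: `slope` (per dB) and `se`.
#' @export
levelFunctionSlope <- function(values, levels, log = TRUE) {
  keep <- is.finite(values) & is.finite(levels)
  if (log) keep <- keep & values > 0
  values <- values[keep]; levels <- levels[keep]
  if (length(values) < 3) stop("need at least 3 defined points")
  y <- if (log) log10(values) else values
  fit <- lm(y ~ levels)
  co <- summary(fit)$coefficients
  c(slope = unname(co["levels", "Estimate"]),
    se = unname(co["levels", "Std. Error"]))
}
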