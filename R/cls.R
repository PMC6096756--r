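# Conditioned lick-suppression analysis: QC, criterion, d', thresholds.

binCounts <- function(m) as.integer(rowSums(m))

#' Inclusion quality control for lick-suppression subjects
#'
#' Two inclusion rules: consistent licking (mean pre-stimulus bin count of
#' at least 20) and no suppression on safe trials (less than a 10\%
#' difference between total pre- and post-stimulus safe bin counts).
#' Report-only: nothing is discarded.
#'
#' @param sessions list of [LickSession-class] objects (>= 1).
#' @param minPreBins minimum acceptable mean pre-stimulus bin count.
#' @param maxSafeDiffPct maximum acceptable safe-trial pre/post difference
#'   in percent.
#' @return list with `pass`, and `perSession` data.frame (mean pre count,
#'   safe pre/post difference in percent, per-rule flags).
#' @export
qcSubject <- function(sessions, minPreBins = 20, maxSafeDiffPct = 10) {
  if (length(sessions) < 1) stop("need at least one session")
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    stopifnot(is(s, "LickSession"))
    meanPre <- mean(binCounts(s@preBins))
    safe <- s@type == "safe"
    if (any(safe)) {
      preTot <- sum(s@preBins[safe, , drop = FALSE])
      postTot <- sum(s@postBins[safe, , drop = FALSE])
      diffPct <- if (preTot > 0) 100 * (preTot - postTot) / preTot else NA
    } else diffPct <- NA_real_
    data.frame(session = i, meanPreCount = meanPre, safeDiffPct = diffPct,
               preCountOk = meanPre >= minPreBins,
               safeTrialsOk = is.na(diffPct) || abs(diffPct) < maxSafeDiffPct)
  })
  perSession <- do.call(rbind, rows)
  list(pass = all(perSession$preCountOk) && all(perSession$safeTrialsOk),
       perSession = perSession)
}

#' Select the response criterion from safe trials
#'
#' A response is a post-stimulus bin count less than or equal to the
#' criterion. The integer criterion whose safe-trial response (false
#' alarm) rate is closest to the target (16\%) is returned. Ties between
#' distinct false-alarm rates resolve toward the lower rate (conservative);
#' within a plateau of equal rates, the largest criterion is returned.
#'
#' @param safePostCounts integer post-stimulus bin counts of safe trials
#'   (>= 10 trials).
#' @param targetFa targeted false-alarm rate (default 0.16).
#' @return list with `criterion` (integer in [0, 35]), `faRate` (realized
#'   safe response rate), and `degenerate` (TRUE when no criterion yields a
#'   false-alarm rate inside (0, 0.5)).
#' @export
selectCriterion <- function(safePostCounts, targetFa = 0.16) {
  if (length(safePostCounts) < 10) stop("need at least 10 safe trials")
  crit <- 0:35
  fa <- vapply(crit, function(cc) mean(safePostCounts <= cc), numeric(1))
  d <- abs(fa - targetFa)
  best <- d <= min(d) + 1e-12
  faBest <- min(fa[best])
  cand <- crit[best & fa == faBest]
  chosen <- max(cand)
  list(criterion = as.integer(chosen), faRate = fa[chosen + 1L],
       degenerate = !any(fa > 0 & fa < 0.5))
}

#' Signal-detection sensitivity d'
#'
#' `d' = qnorm(H) - qnorm(FA)` with the standard 1/(2N) correction for
#' rates of exactly 0 or 1.
#'
#' @param hitRate,faRate observed rates in [0, 1].
#' @param nHitTrials,nFaTrials trial counts behind each rate (>= 1).
#' @return d' (scalar).
#' @examples
#' dprime(0.84, 0.16, 50, 200)
#' @export
dprime <- function(hitRate, faRate, nHitTrials, nFaTrials) {
  stopifnot(nHitTrials >= 1, nFaTrials >= 1)
  clamp <- function(p, n) {
    if (p <= 0) 1 / (2 * n) else if (p >= 1) 1 - 1 / (2 * n) else p
  }
  qnorm(clamp(hitRate, nHitTrials)) - qnorm(clamp(faRate, nFaTrials))
}

#' Detection threshold at a target d'
#'
#' Linear interpolation (in d' versus dB) between the highest level with
#' d' below the target and the next tested level. Extrapolation is
#' refused: if even the highest level stays below target the threshold is
#' not reached, and if every level is at or above target the lowest tested
#' level is returned with a ceiling flag.
#'
#' @param levels tested levels (dB SPL, >= 2).
#' @param dprimes d' at each level.
#' @param target target d' (default 1.0).
#' @return list with `threshold` (dB SPL or `NA`) and `status` (`"ok"`,
#'   `"not_reached"`, or `"ceiling"`).
#' @export
thresholdAtDprime <- function(levels, dprimes, target = 1.0) {
  stopifnot(length(levels) >= 2, length(levels) == length(dprimes),
            all(is.finite(dprimes)))
  ord <- order(levels)
  levels <- levels[ord]; dprimes <- dprimes[ord]
  if (all(dprimes < target))
    return(list(threshold = NA_real_, status = "not_reached"))
  if (all(dprimes >= target))
    return(list(threshold = levels[1], status = "ceiling"))
  if (dprimes[length(dprimes)] < target)
    return(list(threshold = NA_real_, status = "not_reached"))
  i <- max(which(dprimes < target))
  thr <- levels[i] + (target - dprimes[i]) *
    (levels[i + 1] - levels[i]) / (dprimes[i + 1] - dprimes[i])
  list(threshold = thr, status = "ok")
}

#' Aggregate session thresholds into a final threshold
#'
#' Finds the latest run of at least three consecutive sessions whose
#' thresholds span less than 5 dB and returns the mean of the last 3-4
#' sessions of that run. Optionally verifies that at least 20 warning
#' trials were collected at each level, pooled over the contributing
#' sessions.
#'
#' @param thresholds per-session thresholds in testing order (>= 3).
#' @param stabilityDb maximum span (max - min) of a stable run (default 5).
#' @param warningCounts optional named vector of pooled warning-trial
#'   counts per level.
#' @param minWarnings minimum pooled warning trials per level.
#' @return list with `threshold` (mean of the last 3-4 stable sessions, or
#'   `NA`), `status` (`"stable"` / `"unstable"`), `runSessions` (indices of
#'   the averaged sessions), and `enoughWarnings` (`NA` when
#'   `warningCounts` is not supplied).
#' @export
aggregateThresholds <- function(thresholds, stabilityDb = 5,
                                warningCounts = NULL, minWarnings = 20) {
  n <- length(thresholds)
  if (n < 3) stop("need at least 3 sessions")
  run <- NULL
  for (end in n:3) {
    start <- end
    while (start > 1 &&
           isTRUE(diff(range(thresholds[(start - 1):end])) < stabilityDb))
      start <- start - 1
    if (end - start + 1 >= 3) { run <- c(start, end); break }
  }
  enough <- if (is.null(warningCounts)) NA else all(warningCounts >= minWarnings)
  if (is.null(run))
    return(list(threshold = NA_real_, status = "unstable",
                runSessions = integer(0), enoughWarnings = enough))
  m <- min(4L, run[2] - run[1] + 1L)
  idx <- (run[2] - m + 1L):run[2]
  list(threshold = mean(thresholds[idx]), status = "stable",
       runSessions = idx, enoughWarnings = enough)
}

#' Full psychometric analysis of one lick-suppression session
#'
#' Runs criterion selection on the safe trials, computes per-level hit
#' rates and d' (false alarms taken per session), and interpolates the
#' threshold at the target d'.
#'
#' @param session a [LickSession-class].
#' @param targetFa targeted false-alarm rate for criterion selection.
#' @param targetDprime threshold criterion in d' units (default 1.0).
#' @return list with `psychometric` (data.frame: level, nTrials, hitRate,
#'   dprime), `criterion`, `faRate`, `threshold`, `status`.
#' @export
analyzeSession <- function(session, targetFa = 0.16, targetDprime = 1.0) {
  stopifnot(is(session, "LickSession"))
  post <- binCounts(session@postBins)
  safe <- session@type == "safe"
  cs <- selectCriterion(post[safe], targetFa = targetFa)
  nSafe <- sum(safe)
  levels <- sort(unique(session@levelDb[!safe]))
  psych <- do.call(rbind, lapply(levels, function(L) {
    at <- !safe & session@levelDb == L
    h <- mean(post[at] <= cs$criterion)
    data.frame(levelDb = L, nTrials = sum(at), hitRate = h,
               dprime = dprime(h, cs$faRate, sum(at), nSafe))
  }))
  thr <- thresholdAtDprime(psych$levelDb, psych$dprime, targetDprime)
  list(psychometric = psych, criterion = cs$criterion, faRate = cs$faRate,
       threshold = thr$threshold, status = thr$status)
}
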