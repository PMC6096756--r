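# Section leveling, pooled-histogram auto-thresholding, label density.

#' Level section intensities to a common ROI mean
#'
#' Multiplies every section by a scalar gain so that all ROI mean
#' intensities equal a common target. The target is the largest common
#' mean that neither clips any ROI pixel above 255 nor brightens any
#' section beyond the best-exposed section's native mean:
#' `min(max(ROI means), min_i 255 * mean_i / max_i)`. Only global
#' per-section scaling is applied, never local edits.
#'
#' @param stack a [SectionStack-class].
#' @return list with `stack` (leveled, intensities rounded back to the
#'   8-bit grid), `gains`, and `target` (the common ROI mean).
#' @export
levelSections <- function(stack) {
  stopifnot(is(stack, "SectionStack"))
  n <- length(stack@images)
  means <- numeric(n); maxs <- numeric(n)
  for (i in seq_len(n)) {
    v <- stack@images[[i]][stack@rois[[i]]]
    means[i] <- mean(v); maxs[i] <- max(v)
  }
  if (any(means == 0)) stop("section with zero ROI mean cannot be leveled")
  target <- min(max(means), min(255 * means / pmax(maxs, 1e-12)))
  gains <- target / means
  images <- lapply(seq_len(n), function(i)
    pmin(pmax(round(stack@images[[i]] * gains[i]), 0), 255))
  out <- stack
  out@images <- images
  list(stack = out, gains = gains, target = target)
}

#' Pooled intensity histogram over all ROI pixels
#'
#' @param stack a [SectionStack-class] (normally leveled first).
#' @return integer vector of 256 counts, names `"0"` ... `"255"`; the
#'   counts sum to the total ROI pixel count.
#' @export
pooledHistogram <- function(stack) {
  stopifnot(is(stack, "SectionStack"))
  h <- integer(256)
  for (i in seq_along(stack@images)) {
    v <- round(stack@images[[i]][stack@rois[[i]]])
    h <- h + tabulate(v + 1L, nbins = 256L)
  }
  names(h) <- 0:255
  h
}

#' Triangle auto-threshold
#'
#' Geometric construction: a line is drawn from the histogram peak to the
#' far end of the longer tail; the threshold is the bin maximizing the
#' perpendicular distance between the histogram and that line.
#'
#' @param histogram numeric vector of 256 bin counts (bins 0-255).
#' @return threshold gray level (integer in 0-255).
#' @export
triangleThreshold <- function(histogram) {
  h <- as.numeric(histogram)
  stopifnot(length(h) == 256L, all(h >= 0))
  nz <- which(h > 0)
  if (!length(nz)) stop("empty histogram")
  left <- min(nz) - 1L; right <- max(nz) - 1L
  if (left == right) return(left)
  p <- which.max(h) - 1L
  e <- if ((right - p) >= (p - left)) right else left
  lo <- min(p, e); hi <- max(p, e)
  if (hi - lo < 2L) return(e)
  i <- (lo + 1L):(hi - 1L)
  # |cross product| of (e - p, h[e] - h[p]) with (i - p, h[i] - h[p])
  d <- abs((e - p) * (h[i + 1L] - h[p + 1L]) -
           (i - p) * (h[e + 1L] - h[p + 1L]))
  i[which.max(d)]
}

# Renyi entropy of order alpha of the class distribution {p_i / P} over
# bins `idx`, with the Shannon limit at alpha = 1.
renyiClassEntropy <- function(p, idx, alpha) {
  P <- sum(p[idx])
  if (P <= 0) return(-Inf)
  q <- p[idx][p[idx] > 0] / P
  if (alpha == 1) -sum(q * log(q))
  else log(sum(q^alpha)) / (1 - alpha)
}

# Exhaustive maximization of background + foreground Renyi entropy.
renyiBestThreshold <- function(p, alpha) {
  nz <- which(p > 0)
  first <- min(nz); last <- max(nz)
  if (first == last) return(first - 1L)
  cand <- first:(last - 1L)
  tot <- vapply(cand, function(t)
    renyiClassEntropy(p, 1:t, alpha) +
      renyiClassEntropy(p, (t + 1L):length(p), alpha),
    numeric(1))
  cand[which.max(tot)] - 1L
}

#' Renyi-entropy auto-threshold
#'
#' Sahoo-Wilkins-Yeager construction: candidate thresholds maximize the
#' sum of background and foreground Renyi entropies at orders 1/2, 1 (the
#' Shannon/Kapur limit) and 2; the three candidates are combined with the
#' published weighting rule based on their spread and the cumulative
#' histogram.
#'
#' @param histogram numeric vector of 256 bin counts (bins 0-255).
#' @return threshold gray level (integer in 0-255).
#' @export
renyiEntropyThreshold <- function(histogram) {
  h <- as.numeric(histogram)
  stopifnot(length(h) == 256L, all(h >= 0))
  nz <- which(h > 0)
  if (!length(nz)) stop("empty histogram")
  if (length(nz) == 1L) return(nz - 1L)
  p <- h / sum(h)
  ts <- sort(c(renyiBestThreshold(p, 0.5),
               renyiBestThreshold(p, 1),
               renyiBestThreshold(p, 2)))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) beta <- c(1, 2, 1) else beta <- c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) beta <- c(3, 1, 0) else beta <- c(1, 2, 1)
  }
  P1 <- cumsum(p)
  omega <- P1[t3 + 1L] - P1[t1 + 1L]
  opt <- t1 * (P1[t1 + 1L] + 0.25 * omega * beta[1]) +
    0.25 * t2 * omega * beta[2] +
    t3 * (1 - P1[t3 + 1L] + 0.25 * omega * beta[3])
  as.integer(floor(opt))
}

#' Label density of a thresholded stack
#'
#' Fraction of ROI pixels at or above the threshold (bright-label
#' convention; `invert = TRUE` counts pixels at or below it for
#' dark-label material), pooled over all sections and per section.
#'
#' @param stack a [SectionStack-class] (normally leveled).
#' @param threshold gray level in [0, 256]; 256 is a sentinel above the
#'   8-bit maximum, yielding density 0.
#' @param invert dark-label polarity.
#' @return list with `density` (pooled fraction in [0, 1]), `threshold`,
#'   `invert`, and `perSection` densities.
#' @export
labelDensity <- function(stack, threshold, invert = FALSE) {
  stopifnot(is(stack, "SectionStack"))
  if (threshold < 0 || threshold > 256) stop("threshold must be in [0, 256]")
  lab <- 0; tot <- 0
  per <- numeric(length(stack@images))
  for (i in seq_along(stack@images)) {
    v <- stack@images[[i]][stack@rois[[i]]]
    if (!length(v)) stop("empty ROI in section ", i)
    k <- if (invert) sum(v <= threshold) else sum(v >= threshold)
    per[i] <- k / length(v)
    lab <- lab + k; tot <- tot + length(v)
  }
  list(density = lab / tot, threshold = threshold, invert = invert,
       perSection = per)
}

#' One-call densitometry pipeline
#'
#' Leveling, pooled histogram, auto-threshold (triangle or Renyi entropy),
#' and ROI label density — the full per-case measurement chain.
#'
#' @param stack a [SectionStack-class].
#' @param method `"renyi"` or `"triangle"`.
#' @param invert dark-label polarity (see [labelDensity()]).
#' @return list with `density`, `threshold`, `gains`, `perSection`.
#' @export
measureLabelDensity <- function(stack, method = c("renyi", "triangle"),
                                invert = FALSE) {
  method <- match.arg(method)
  lev <- levelSections(stack)
  h <- pooledHistogram(lev$stack)
  thr <- if (method == "triangle") triangleThreshold(h)
         else renyiEntropyThreshold(h)
  d <- labelDensity(lev$stack, thr, invert = invert)
  list(density = d$density, threshold = thr, gains = lev$gains,
       perSection = d$perSection)
}
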