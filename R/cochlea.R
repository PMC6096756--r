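# Optical-fractionator stereology and cochleogram quantities.

#' Generate a synthetic fractionator sample
#'
#' Places `trueN` cells uniformly in a virtual canal of `nSections`
#' sections, samples every 1/ssf-th section from a random start, and
#' counts cells falling inside a counting frame occupying the fraction
#' `asf` of each grid cell (random frame phase). The design is unbiased:
#' each cell is counted with probability `ssf * asf * hsf`.
#'
#' @param trueN true number of cells (>= 0).
#' @param ssf section sampling fraction in (0, 1]; 1/ssf must be a whole
#'   number of sections.
#' @param asf area sampling fraction in (0, 1].
#' @param hsf height sampling fraction in (0, 1].
#' @param seed integer seed.
#' @param nSections sections in the canal.
#' @param canalUm in-plane canal extent `c(width, height)` (micrometres).
#' @param gridUm sampling-grid cell edge (default 40).
#' @return list with `sample` (a [FractionatorSample-class]) and `truth`
#'   (list with `trueN` and the cell coordinates).
#' @export
generateFractionatorData <- function(trueN, ssf = 1 / 3, asf = 1, hsf = 1,
                                     seed, nSections = 30L,
                                     canalUm = c(400, 200), gridUm = 40) {
  if (trueN < 0) stop("trueN must be >= 0")
  f <- c(ssf, asf, hsf)
  if (any(f <= 0) || any(f > 1)) stop("fractions must lie in (0, 1]")
  period <- round(1 / ssf)
  if (abs(period - 1 / ssf) > 1e-9)
    stop("1/ssf must be a whole number of sections")
  withSeed(seed, {
    sec <- sample.int(nSections, trueN, replace = TRUE)
    x <- runif(trueN, 0, canalUm[1])
    y <- runif(trueN, 0, canalUm[2])
    start <- sample.int(period, 1)
    sampled <- seq(start, nSections, by = period)
    # counting frame: sub-rectangle with side fraction sqrt(asf) in both
    # in-plane directions, common random phase across the grid
    fr <- sqrt(asf)
    ox <- runif(1, 0, gridUm); oy <- runif(1, 0, gridUm)
    inFrame <- ((x + ox) %% gridUm) < fr * gridUm &
               ((y + oy) %% gridUm) < fr * gridUm
    inHeight <- if (hsf < 1) runif(trueN) < hsf else rep(TRUE, trueN)
    counted <- sec %in% sampled & inFrame & inHeight
    counts <- vapply(sampled, function(s)
      sum(counted & sec == s), integer(1))
    samp <- new("FractionatorSample", counts = counts,
                ssf = ssf, asf = asf, hsf = hsf)
    list(sample = samp,
         truth = list(trueN = trueN,
                      cells = data.frame(section = sec, x = x, y = y)))
  })
}

#' Optical-fractionator population estimate
#'
#' `N = sum(Q) / (ssf * asf * hsf)`: the summed tally scaled by the
#' inverse section, area and height sampling fractions.
#'
#' @param sample a [FractionatorSample-class].
#' @return estimated total count (scalar).
#' @examples
#' s <- new("FractionatorSample", counts = c(40L, 60L),
#'          ssf = 1/3, asf = 1/4, hsf = 1)
#' fractionatorEstimate(s)  # 1200
#' @export
fractionatorEstimate <- function(sample) {
  stopifnot(is(sample, "FractionatorSample"))
  sum(sample@counts) / (sample@ssf * sample@asf * sample@hsf)
}

#' Percent loss relative to a reference mean
#'
#' `100 * (1 - test / reference)`.
#'
#' @param meanReference reference (e.g. sham) group mean, > 0.
#' @param meanTest test (e.g. noise-exposed) group mean.
#' @return percent loss (positive when the test mean is smaller).
#' @examples
#' percentLoss(7311, 6262)  # ~14
#' @export
percentLoss <- function(meanReference, meanTest) {
  if (meanReference <= 0) stop("reference mean must be > 0")
  100 * (1 - meanTest / meanReference)
}

#' Ribbon synapses per inner hair cell
#'
#' Total presynaptic-ribbon puncta in an image stack divided by the number
#' of inner hair cells in the image, per cochlear frequency place.
#'
#' @param punctaCount total labeled puncta (>= 0).
#' @param ihcCount inner hair cells in the image.
#' @return puncta per IHC, or `NA` (with a warning) when no IHC is present.
#' @export
synapsesPerIHC <- function(punctaCount, ihcCount) {
  stopifnot(punctaCount >= 0, ihcCount >= 0)
  if (ihcCount == 0) {
    warning("no inner hair cells in image; ratio undefined")
    return(NA_real_)
  }
  punctaCount / ihcCount
}

#' Hair-cell survival relative to a reference mean
#'
#' `100 * test / reference` per frequency place and cell class. Values
#' above 100 are reported as-is with an attribute flag.
#'
#' @param testCounts hair-cell counts in the test cochlea.
#' @param referenceMeans matched reference-group mean counts (> 0).
#' @return percent survival, with attribute `above100` marking entries
#'   exceeding the reference.
#' @export
hairCellSurvival <- function(testCounts, referenceMeans) {
  if (any(referenceMeans <= 0)) stop("reference means must be > 0")
  out <- 100 * testCounts / referenceMeans
  attr(out, "above100") <- out > 100
  out
}
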