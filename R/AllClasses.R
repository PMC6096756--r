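#' @import methods
#' @importFrom stats approx coef cov dbinom lm median na.omit pbinom pnorm
#'   qnorm rbinom rnorm rpois runif sd t.test uniroot p.adjust setNames var
#' @importFrom utils head read.csv tail write.csv
#' @importFrom tools md5sum
NULL

# ---------------------------------------------------------------------------
# Ground-truth parameter classes (returned by every generator; downstream
# analysis functions never read them -- they exist for validation only)
# ---------------------------------------------------------------------------

#' Ground truth for the synthetic ABR generator
#'
#' Parameters of the level-dependent four-peak ABR model used by
#' [generateABR()]. Peak-to-trough amplitude of peak k at level L (dB SPL)
#' is \code{2 * max(0, peakSlopes[k] * (L - thresholdDb))} microvolts, and
#' the positive-peak latency is
#' \code{latencyInterceptMs[k] + latencySlopeMsPerDb[k] * L}.
#'
#' @slot condition character, `"sham"` or `"noise"`.
#' @slot thresholdDb true threshold (dB SPL); amplitudes are zero below it.
#' @slot peakSlopes amplitude-growth slope per peak (microvolt/dB), length 4.
#' @slot latencyInterceptMs latency intercept per peak (ms), length 4.
#' @slot latencySlopeMsPerDb latency slope per peak (ms/dB, negative so
#'   latency shortens with level), length 4.
#' @slot sigmaMs wavelet width per peak (ms), length 4.
#' @slot noiseSdUv additive Gaussian noise SD per single epoch (microvolt).
#' @exportClass ABRGroundTruth
setClass("ABRGroundTruth",
  representation(
    condition = "character",
    thresholdDb = "numeric",
    peakSlopes = "numeric",
    latencyInterceptMs = "numeric",
    latencySlopeMsPerDb = "numeric",
    sigmaMs = "numeric",
    noiseSdUv = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@peakSlopes) != 4L || any(object@peakSlopes < 0))
      msg <- c(msg, "peakSlopes must be 4 non-negative values")
    if (length(object@latencyInterceptMs) != 4L ||
        length(object@latencySlopeMsPerDb) != 4L ||
        length(object@sigmaMs) != 4L)
      msg <- c(msg, "latency and sigma parameters must have length 4")
    if (any(object@sigmaMs <= 0)) msg <- c(msg, "sigmaMs must be positive")
    if (object@noiseSdUv < 0) msg <- c(msg, "noiseSdUv must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Ground truth for the synthetic lick-suppression generator
#'
#' On a warning trial at level L the animal suppresses licking with
#' probability \code{faRate + (hitMax - faRate) * pnorm((L - thresholdDb) /
#' slopeDb)}; a suppressed trial has zero post-stimulus lick probability,
#' otherwise the baseline per-bin rate \code{lickRate} applies throughout.
#'
#' @slot thresholdDb psychometric midpoint (dB SPL).
#' @slot slopeDb psychometric spread (dB, the SD of the underlying normal).
#' @slot hitMax asymptotic suppression probability at high levels.
#' @slot faRate floor suppression probability (false-alarm construction).
#' @slot lickRate baseline per-20-ms-bin lick probability.
#' @exportClass CLSGroundTruth
setClass("CLSGroundTruth",
  representation(
    thresholdDb = "numeric",
    slopeDb = "numeric",
    hitMax = "numeric",
    faRate = "numeric",
    lickRate = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@slopeDb <= 0) msg <- c(msg, "slopeDb must be > 0")
    p <- c(object@hitMax, object@faRate, object@lickRate)
    if (any(p < 0 | p > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
    if (!(object@faRate < object@hitMax))
      msg <- c(msg, "faRate must be below hitMax")
    if (length(msg)) msg else TRUE
  }
)

#' Specification of the synthetic nucleus phantom
#'
#' Geometry and label statistics of the ellipsoidal stand-in for a cochlear
#' nucleus. The frequency field is linear in log2(kHz) along one template
#' axis; puncta are placed by an inhomogeneous Poisson process with
#' intensity \code{density(f)} per square micrometre.
#'
#' @slot semiAxesUm ellipsoid semi-axes (x, y, z) in micrometres.
#' @slot freqRangeKHz frequency at the two extremes of the frequency axis.
#' @slot freqAxis which template axis (1 = x, 2 = y, 3 = z) carries the
#'   tonotopic gradient.
#' @slot sectionThicknessUm section spacing/thickness (default 50).
#' @slot pixelSizeUm in-plane pixel size.
#' @slot punctumRadiusUm radius of a rendered punctum.
#' @slot punctumIntensity gray-level increment of a punctum over background.
#' @slot backgroundLevel mean background gray level.
#' @slot noiseSd additive Gaussian image noise SD (gray levels).
#' @slot densitySham punctum density for the sham condition: a single
#'   number (puncta per square micrometre) or a function of frequency (kHz).
#' @slot densityNoise same, for the noise-exposed condition.
#' @slot taper length 3: relative taper of the x semi-axis along the z
#'   and y axes, plus a quadratic bend of the x centre along z. Non-zero
#'   values break the affine self-symmetries of the ellipsoid so template
#'   registration has a unique solution; `c(0, 0, 0)` gives a pure
#'   ellipsoid.
#' @slot affine ground-truth 3x4 affine mapping phantom (subject) space to
#'   template space.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    semiAxesUm = "numeric",
    freqRangeKHz = "numeric",
    freqAxis = "integer",
    sectionThicknessUm = "numeric",
    pixelSizeUm = "numeric",
    punctumRadiusUm = "numeric",
    punctumIntensity = "numeric",
    backgroundLevel = "numeric",
    noiseSd = "numeric",
    densitySham = "ANY",
    densityNoise = "ANY",
    taper = "numeric",
    affine = "matrix"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@semiAxesUm) != 3L || any(object@semiAxesUm <= 0))
      msg <- c(msg, "semiAxesUm must be 3 positive values")
    if (object@sectionThicknessUm <= 0)
      msg <- c(msg, "sectionThicknessUm must be > 0")
    if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
    if (!object@freqAxis %in% 1:3) msg <- c(msg, "freqAxis must be 1, 2 or 3")
    if (!is.function(object@densitySham) && any(object@densitySham < 0))
      msg <- c(msg, "densitySham must be non-negative")
    if (!is.function(object@densityNoise) && any(object@densityNoise < 0))
      msg <- c(msg, "densityNoise must be non-negative")
    if (length(object@taper) != 3L || sum(abs(object@taper)) >= 0.8)
      msg <- c(msg, "taper must be 3 values with |t1| + |t2| + |t3| < 0.8")
    if (!all(dim(object@affine) == c(3L, 4L)))
      msg <- c(msg, "affine must be a 3x4 matrix")
    else if (abs(det(object@affine[, 1:3])) < 1e-12)
      msg <- c(msg, "affine linear part must be invertible")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# Data containers
# ---------------------------------------------------------------------------

#' Stimulus-tagged set of ABR epochs
#'
#' All epochs share one stimulus (click or tone), one presentation level,
#' one sampling rate, and one stimulus-onset sample.
#'
#' @slot stimulus `"click"` or `"tone"`.
#' @slot frequencyKHz tone frequency in kHz (`NA` for clicks).
#' @slot levelDb presentation level (dB SPL).
#' @slot sampleRate sampling rate (Hz).
#' @slot onsetIndex 1-based sample index of stimulus onset.
#' @slot epochs numeric matrix, one epoch per row (microvolts).
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    stimulus = "character",
    frequencyKHz = "numeric",
    levelDb = "numeric",
    sampleRate = "numeric",
    onsetIndex = "integer",
    epochs = "matrix"
  ),
  validity = function(object) {
    msg <- character()
    if (!object@stimulus %in% c("click", "tone"))
      msg <- c(msg, "stimulus must be 'click' or 'tone'")
    if (object@sampleRate <= 0) msg <- c(msg, "sampleRate must be > 0")
    if (nrow(object@epochs) < 1L) msg <- c(msg, "need at least one epoch")
    if (object@onsetIndex < 1L || object@onsetIndex > ncol(object@epochs))
      msg <- c(msg, "onsetIndex must lie within the record")
    if (length(msg)) msg else TRUE
  }
)

#' Conditioned lick-suppression session
#'
#' Trials with 35 pre-stimulus and 35 post-stimulus 20-ms lick-indicator
#' bins. Safe trials carry `NA` as their level.
#'
#' @slot frequencyKHz tone frequency tested in this session.
#' @slot type character vector, `"warning"` or `"safe"` per trial.
#' @slot levelDb numeric vector, dB SPL per trial (`NA` on safe trials).
#' @slot preBins integer 0/1 matrix, trials x 35.
#' @slot postBins integer 0/1 matrix, trials x 35.
#' @exportClass LickSession
setClass("LickSession",
  representation(
    frequencyKHz = "numeric",
    type = "character",
    levelDb = "numeric",
    preBins = "matrix",
    postBins = "matrix"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@type)
    if (!all(object@type %in% c("warning", "safe")))
      msg <- c(msg, "trial type must be 'warning' or 'safe'")
    if (ncol(object@preBins) != 35L || ncol(object@postBins) != 35L)
      msg <- c(msg, "exactly 35 pre and 35 post bins required")
    if (nrow(object@preBins) != n || nrow(object@postBins) != n ||
        length(object@levelDb) != n)
      msg <- c(msg, "trial fields must agree in length")
    if (any(!is.na(object@levelDb[object@type == "safe"])))
      msg <- c(msg, "safe trials must not carry a level")
    if (length(msg)) msg else TRUE
  }
)

#' Set of acoustic startle trials
#'
#' Each trial couples a 5-s baseline movement trace with a 100-ms response
#' trace recorded from stimulus onset.
#'
#' @slot levelDb startle-stimulus level per trial (dB SPL).
#' @slot baseline numeric matrix, trials x baseline samples.
#' @slot response numeric matrix, trials x response samples.
#' @slot baselineRate baseline-trace sampling rate (Hz).
#' @slot responseRate response-trace sampling rate (Hz).
#' @exportClass StartleTrialSet
setClass("StartleTrialSet",
  representation(
    levelDb = "numeric",
    baseline = "matrix",
    response = "matrix",
    baselineRate = "numeric",
    responseRate = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@levelDb)
    if (nrow(object@baseline) != n || nrow(object@response) != n)
      msg <- c(msg, "one baseline and one response trace per trial")
    durB <- ncol(object@baseline) / object@baselineRate
    durR <- ncol(object@response) / object@responseRate
    if (abs(durB - 5) > 1e-6)
      msg <- c(msg, "baseline traces must cover 5 s")
    if (abs(durR - 0.1) > 1e-6)
      msg <- c(msg, "response traces must cover 100 ms")
    if (length(msg)) msg else TRUE
  }
)

#' Serial-section image stack with ROI masks
#'
#' Grayscale 8-bit sections, a region-of-interest mask per section, and the
#' in-plane transform taking pixel coordinates (column, row, 1) to stack
#' coordinates in micrometres.
#'
#' @slot images list of numeric matrices with values in [0, 255].
#' @slot rois list of logical matrices, same dimensions as `images`.
#' @slot transforms list of 3x3 matrices (pixel -> stack-frame micrometres).
#' @slot pixelSizeUm in-plane pixel size (micrometres).
#' @slot spacingUm section spacing (micrometres).
#' @slot sectionIndex integer index of each section (0-based position along
#'   the cutting axis).
#' @exportClass SectionStack
setClass("SectionStack",
  representation(
    images = "list",
    rois = "list",
    transforms = "list",
    pixelSizeUm = "numeric",
    spacingUm = "numeric",
    sectionIndex = "integer"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@images)
    if (length(object@rois) != n || length(object@transforms) != n ||
        length(object@sectionIndex) != n)
      msg <- c(msg, "images, rois, transforms, sectionIndex must align")
    for (i in seq_len(n)) {
      img <- object@images[[i]]
      if (!is.matrix(img) || !is.matrix(object@rois[[i]]) ||
          !all(dim(img) == dim(object@rois[[i]]))) {
        msg <- c(msg, "ROI mask dimensions must match the image")
        break
      }
      if (min(img) < 0 || max(img) > 255) {
        msg <- c(msg, "intensities must lie in [0, 255]")
        break
      }
      if (!any(object@rois[[i]])) {
        msg <- c(msg, "every section needs a non-empty ROI")
        break
      }
    }
    if (object@pixelSizeUm <= 0) msg <- c(msg, "pixelSizeUm must be > 0")
    if (object@spacingUm <= 0) msg <- c(msg, "spacingUm must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' 3D surface (point cloud) of a reconstructed nucleus
#'
#' @slot vertices numeric matrix, n x 3, micrometres.
#' @slot faces integer matrix of vertex triplets, or a 0-row matrix for a
#'   pure point cloud.
#' @slot openEnds logical length 2: is the anterior (first) / posterior
#'   (last) end of the reconstruction open (unbounded)?
#' @slot sectionOf integer per vertex: index of the section it came from
#'   (0 when unknown).
#' @exportClass SurfaceModel
setClass("SurfaceModel",
  representation(
    vertices = "matrix",
    faces = "matrix",
    openEnds = "logical",
    sectionOf = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be n x 3")
    if (!all(is.finite(object@vertices)))
      msg <- c(msg, "vertex coordinates must be finite")
    if (nrow(object@faces) > 0 &&
        (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices)))
      msg <- c(msg, "faces reference invalid vertices")
    if (length(object@openEnds) != 2L)
      msg <- c(msg, "openEnds must have length 2")
    if (length(object@sectionOf) != nrow(object@vertices))
      msg <- c(msg, "sectionOf must have one entry per vertex")
    if (length(msg)) msg else TRUE
  }
)

#' Frequency-annotated template volume
#'
#' Voxelized scalar field of log2 frequency over the template nucleus, with
#' a validity mask and the template surface used for registration.
#'
#' @slot field 3D numeric array of log2(frequency / kHz).
#' @slot mask 3D logical array: voxels where the field is defined.
#' @slot originUm coordinates (micrometres) of the centre of voxel [1,1,1].
#' @slot voxelSizeUm isotropic voxel edge length (micrometres).
#' @slot surface [SurfaceModel] of the template boundary.
#' @exportClass FrequencyTemplate
setClass("FrequencyTemplate",
  representation(
    field = "array",
    mask = "array",
    originUm = "numeric",
    voxelSizeUm = "numeric",
    surface = "SurfaceModel"
  ),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@field) == dim(object@mask)))
      msg <- c(msg, "field and mask dimensions must agree")
    if (length(object@originUm) != 3L) msg <- c(msg, "originUm must be xyz")
    if (object@voxelSizeUm <= 0) msg <- c(msg, "voxelSizeUm must be > 0")
    if (any(!is.finite(object@field[object@mask])))
      msg <- c(msg, "field must be finite inside the mask")
    if (length(msg)) msg else TRUE
  }
)

#' Result of an affine template fit
#'
#' @slot matrix 3x4 affine (linear part | translation), micrometres.
#' @slot rms root-mean-square vertex-to-template distance (micrometres).
#' @slot iterations data.frame log with columns `iter` and `rms`.
#' @exportClass AffineFit
setClass("AffineFit",
  representation(
    matrix = "matrix",
    rms = "numeric",
    iterations = "data.frame"
  ),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@matrix) == c(3L, 4L)))
      msg <- c(msg, "affine must be 3x4")
    else if (abs(det(object@matrix[, 1:3])) < 1e-12)
      msg <- c(msg, "linear part must be invertible")
    if (object@rms < 0) msg <- c(msg, "rms must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Optical-fractionator sample
#'
#' Per-site neuron tallies plus the three sampling fractions of the
#' fractionator design.
#'
#' @slot counts integer vector of counted objects per sampling site.
#' @slot ssf section sampling fraction, in (0, 1].
#' @slot asf area sampling fraction (counting frame / grid cell), in (0, 1].
#' @slot hsf height sampling fraction, in (0, 1].
#' @exportClass FractionatorSample
setClass("FractionatorSample",
  representation(
    counts = "integer",
    ssf = "numeric",
    asf = "numeric",
    hsf = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
    f <- c(object@ssf, object@asf, object@hsf)
    if (any(f <= 0) || any(f > 1))
      msg <- c(msg, "sampling fractions must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "EpochSet", function(object) {
  stim <- if (object@stimulus == "click") "click"
          else sprintf("%g kHz tone", object@frequencyKHz)
  cat(sprintf(
    "EpochSet: %s at %g dB SPL\n  %d epochs x %d samples @ %g Hz (onset at sample %d)\n",
    stim, object@levelDb, nrow(object@epochs), ncol(object@epochs),
    object@sampleRate, object@onsetIndex))
})

setMethod("show", "LickSession", function(object) {
  nw <- sum(object@type == "warning")
  cat(sprintf(
    "LickSession: %g kHz, %d trials (%d warning, %d safe), levels %s dB\n",
    object@frequencyKHz, length(object@type), nw, length(object@type) - nw,
    paste(sort(unique(na.omit(object@levelDb))), collapse = ", ")))
})

setMethod("show", "StartleTrialSet", function(object) {
  cat(sprintf(
    "StartleTrialSet: %d trials at levels %s dB SPL\n",
    length(object@levelDb),
    paste(sort(unique(object@levelDb)), collapse = ", ")))
})

setMethod("show", "SectionStack", function(object) {
  d <- dim(object@images[[1]])
  cat(sprintf(
    "SectionStack: %d sections of %d x %d px (%g um/px, %g um spacing)\n",
    length(object@images), d[1], d[2], object@pixelSizeUm, object@spacingUm))
})

setMethod("show", "SurfaceModel", function(object) {
  cat(sprintf(
    "SurfaceModel: %d vertices%s; open ends: %s/%s\n",
    nrow(object@vertices),
    if (nrow(object@faces)) sprintf(", %d faces", nrow(object@faces))
    else " (point cloud)",
    object@openEnds[1], object@openEnds[2]))
})

setMethod("show", "AffineFit", function(object) {
  cat(sprintf("AffineFit: RMS %.3f um after %d iterations\n",
              object@rms, nrow(object@iterations)))
})

setMethod("show", "FractionatorSample", function(object) {
  cat(sprintf(
    "FractionatorSample: sum Q = %d over %d sites (ssf %.3g, asf %.3g, hsf %.3g)\n",
    sum(object@counts), length(object@counts),
    object@ssf, object@asf, object@hsf))
})

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' Epoch matrix of an [EpochSet]
#' @param x an `EpochSet`.
#' @return numeric matrix, one epoch per row.
#' @export
epochMatrix <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@epochs
}

#' Section images of a [SectionStack]
#' @param x a `SectionStack`.
#' @return list of numeric matrices.
#' @export
sectionImages <- function(x) {
  stopifnot(is(x, "SectionStack"))
  x@images
}

#' ROI masks of a [SectionStack]
#' @param x a `SectionStack`.
#' @return list of logical matrices.
#' @export
roiMasks <- function(x) {
  stopifnot(is(x, "SectionStack"))
  x@rois
}

#' Vertices of a [SurfaceModel]
#' @param x a `SurfaceModel`.
#' @return numeric n x 3 matrix (micrometres).
#' @export
vertices <- function(x) {
  stopifnot(is(x, "SurfaceModel"))
  x@vertices
}

#' Affine matrix of an [AffineFit]
#' @param x an `AffineFit`.
#' @return 3x4 numeric matrix.
#' @export
affineMatrix <- function(x) {
  stopifnot(is(x, "AffineFit"))
  x@matrix
}
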