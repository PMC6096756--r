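# Synthetic nucleus phantom: ellipsoid with tonotopic frequency field,
# punctate label, illumination jitter, and a known affine to the template.

#' Construct a phantom specification
#'
#' Defaults describe an ellipsoidal stand-in for a mouse ventral cochlear
#' nucleus: ~1 x 0.8 x 0.5 mm, 50-um sections, 4-um pixels, a log-frequency
#' gradient along the template y axis, and punctate label whose density is
#' halved in the noise condition (inhibitory-marker-like default).
#'
#' @param semiAxesUm ellipsoid semi-axes (x, y, z) in micrometres.
#' @param freqRangeKHz frequencies at the two extremes of the frequency
#'   axis (low to high).
#' @param freqAxis template axis carrying the tonotopic gradient (1-3).
#' @param sectionThicknessUm section spacing (default 50).
#' @param pixelSizeUm in-plane pixel size.
#' @param punctumRadiusUm rendered punctum radius.
#' @param punctumIntensity punctum gray-level increment over background.
#' @param backgroundLevel mean background gray level.
#' @param noiseSd image noise SD (gray levels).
#' @param densitySham sham punctum density: puncta/um^2, a scalar or a
#'   function of frequency in kHz.
#' @param densityNoise noise-condition density (default half of sham).
#' @param taper length 3: relative taper of the x extent along z and y,
#'   and a quadratic bend of the x centre along z. The default mild
#'   asymmetry makes the shape affinely rigid (a pure ellipsoid admits a
#'   continuum of affine self-maps, leaving surface registration
#'   under-determined); `c(0, 0, 0)` gives a pure ellipsoid.
#' @param affine ground-truth 3x4 affine from phantom (subject) space to
#'   template space.
#' @return a [PhantomSpec-class].
#' @export
phantomSpec <- function(semiAxesUm = c(500, 400, 250),
                        freqRangeKHz = c(3, 70),
                        freqAxis = 2L,
                        sectionThicknessUm = 50,
                        pixelSizeUm = 4,
                        punctumRadiusUm = 8,
                        punctumIntensity = 160,
                        backgroundLevel = 40,
                        noiseSd = 8,
                        densitySham = 2.5e-4,
                        densityNoise = NULL,
                        taper = c(0.22, 0.18, 0.15),
                        affine = identityAffine()) {
  if (is.null(densityNoise)) {
    densityNoise <- if (is.function(densitySham))
      (function(f) 0.5 * densitySham(f)) else 0.5 * densitySham
  }
  new("PhantomSpec", semiAxesUm = semiAxesUm,
      freqRangeKHz = freqRangeKHz, freqAxis = as.integer(freqAxis),
      sectionThicknessUm = sectionThicknessUm, pixelSizeUm = pixelSizeUm,
      punctumRadiusUm = punctumRadiusUm,
      punctumIntensity = punctumIntensity,
      backgroundLevel = backgroundLevel, noiseSd = noiseSd,
      densitySham = densitySham, densityNoise = densityNoise,
      taper = taper, affine = affine)
}

# Implicit shape function of the template body: inside where F(q) <= 1.
# A tapered, bent ellipsoid: the x semi-axis is modulated linearly along
# the z and y axes and the x centre is displaced quadratically along z.
# Together these remove every affine self-map of the ellipsoid (including
# the axis reflections), so template registration has a unique solution.
shapeF <- function(spec, q) {
  ax <- spec@semiAxesUm
  u <- q[, 3] / ax[3]
  v <- q[, 2] / ax[2]
  s <- pmax(0.2, 1 + spec@taper[1] * u + spec@taper[2] * v)
  xb <- q[, 1] - spec@taper[3] * ax[1] * u^2
  (xb / (ax[1] * s))^2 + v^2 + u^2
}

densityFun <- function(d) if (is.function(d)) d else function(f) rep(d, length(f))

# log2-frequency at template coordinate u along the frequency axis,
# linear from freqRangeKHz[1] at -semiAxis to freqRangeKHz[2] at +semiAxis.
templateLogFreq <- function(spec, u) {
  a <- spec@semiAxesUm[spec@freqAxis]
  lr <- log2(spec@freqRangeKHz)
  lr[1] + (u + a) / (2 * a) * (lr[2] - lr[1])
}

# Fibonacci-lattice sample of the template surface: unit-sphere directions
# scaled by the semi-axes, then projected radially onto the F = 1 shell.
shapeSurfacePoints <- function(spec, n = 2000L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  d <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  d <- sweep(d, 2, spec@semiAxesUm, "*")
  r <- vapply(seq_len(n), function(k) {
    uniroot(function(r) shapeF(spec, r * d[k, , drop = FALSE]) - 1,
            c(1e-6, 2))$root
  }, numeric(1))
  d * r
}

#' Build the frequency-annotated template of a phantom
#'
#' Voxelizes the template ellipsoid and its log2-frequency field, and
#' samples the template surface for registration.
#'
#' @param spec a [PhantomSpec-class].
#' @param voxelSizeUm isotropic voxel size of the field grid.
#' @param nSurface number of surface sample points.
#' @return a [FrequencyTemplate-class].
#' @export
templateFromSpec <- function(spec, voxelSizeUm = 20, nSurface = 2000L) {
  ax <- spec@semiAxesUm
  ext <- ax * c(1 + sum(abs(spec@taper)), 1, 1)
  lo <- -(ext + voxelSizeUm)
  dims <- as.integer(ceiling(2 * (ext + voxelSizeUm) / voxelSizeUm) + 1L)
  centres <- lapply(1:3, function(k)
    lo[k] + (seq_len(dims[k]) - 1) * voxelSizeUm)
  grid <- as.matrix(expand.grid(centres[[1]], centres[[2]], centres[[3]]))
  mask <- array(shapeF(spec, grid) <= 1, dims)
  u <- centres[[spec@freqAxis]]
  lf <- templateLogFreq(spec, u)
  field <- array(0, dims)
  field[] <- lf[slice.index(field, spec@freqAxis)]
  field[!mask] <- NA_real_
  surf <- new("SurfaceModel",
              vertices = shapeSurfacePoints(spec, nSurface),
              faces = matrix(integer(0), 0, 3),
              openEnds = c(FALSE, FALSE),
              sectionOf = rep(0L, nSurface))
  new("FrequencyTemplate", field = field, mask = mask,
      originUm = lo, voxelSizeUm = voxelSizeUm, surface = surf)
}

discOffsets <- function(radiusPx) {
  r <- ceiling(radiusPx)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= radiusPx^2, , drop = FALSE]
}

#' Generate a synthetic section stack from a phantom
#'
#' Cuts the phantom (the template ellipsoid carried into subject space by
#' the inverse of the ground-truth affine) into serial sections, renders
#' punctate label by an inhomogeneous Poisson process with intensity
#' `density(frequency)` per square micrometre, adds background, noise and
#' per-section multiplicative illumination jitter, and returns the stack
#' together with full ground truth.
#'
#' @param spec a [PhantomSpec-class].
#' @param condition `"sham"` or `"noise"` (selects the density profile).
#' @param seed integer seed.
#' @param illumRange range of the per-section uniform illumination factor;
#'   `c(1, 1)` disables jitter.
#' @return list with `stack` (a [SectionStack-class]), and `truth`: a list
#'   holding `frequencyKHz` (per-section matrices of ground-truth pixel
#'   frequency, `NA` outside the ROI), `labelMask` (per-section logical
#'   matrices of rendered punctum pixels), `areaFraction` (ground-truth
#'   labeled fraction of ROI pixels), `density` (the profile used),
#'   `illumination` (per-section factors), and `affineStackToTemplate`
#'   (3x4 ground-truth affine from stack coordinates to template space).
#' @export
generateVCNStack <- function(spec, condition = c("sham", "noise"), seed,
                             illumRange = c(0.75, 1.05)) {
  condition <- match.arg(condition)
  stopifnot(is(spec, "PhantomSpec"))
  dens <- densityFun(
    if (condition == "sham") spec@densitySham else spec@densityNoise)
  fchk <- seq(spec@freqRangeKHz[1], spec@freqRangeKHz[2], length.out = 64)
  if (any(dens(fchk) < 0)) stop("density profile must be non-negative")

  A <- spec@affine                      # subject -> template
  Ainv <- invertAffine(A)               # template -> subject
  ax <- spec@semiAxesUm
  xext <- ax[1] * (1 + sum(abs(spec@taper)))
  # subject-space bounding box from the template body's bounding corners
  corners <- as.matrix(expand.grid(c(-xext, xext), c(-ax[2], ax[2]),
                                   c(-ax[3], ax[3])))
  sbb <- applyAffinePoints(Ainv, corners)
  lo <- apply(sbb, 2, min); hi <- apply(sbb, 2, max)

  px <- spec@pixelSizeUm
  th <- spec@sectionThicknessUm
  zs <- seq(lo[3] + th / 2, hi[3], by = th)
  xs <- seq(lo[1] + px / 2, hi[1], by = px)
  ys <- seq(lo[2] + px / 2, hi[2], by = px)
  nr <- length(ys); nc <- length(xs)
  pix <- cbind(rep(xs, each = nr), rep(ys, times = nc))  # (x, y) per pixel
  offs <- discOffsets(spec@punctumRadiusUm / px)
  pxArea <- px^2

  withSeed(seed, {
    images <- list(); rois <- list(); transforms <- list()
    freqs <- list(); labels <- list(); illums <- numeric(0)
    zKept <- numeric(0)
    for (z in zs) {
      q <- applyAffinePoints(A, cbind(pix, z))     # template coords
      inside <- shapeF(spec, q) <= 1
      if (!any(inside)) next
      roi <- matrix(inside, nrow = nr, ncol = nc)
      f <- rep(NA_real_, nrow(q))
      f[inside] <- 2^templateLogFreq(spec, q[inside, spec@freqAxis])
      fmat <- matrix(f, nrow = nr, ncol = nc)

      lambda <- dens(f[inside]) * pxArea
      counts <- rpois(length(lambda), lambda)
      centres <- which(inside)[counts > 0]
      label <- matrix(FALSE, nr, nc)
      if (length(centres)) {
        cc <- ((centres - 1L) %/% nr) + 1L
        rr <- ((centres - 1L) %% nr) + 1L
        prr <- rep(rr, each = nrow(offs)) + offs$dr
        pcc <- rep(cc, each = nrow(offs)) + offs$dc
        okp <- prr >= 1 & prr <= nr & pcc >= 1 & pcc <= nc
        label[cbind(prr[okp], pcc[okp])] <- TRUE
      }
      illum <- runif(1, illumRange[1], illumRange[2])
      img <- matrix(spec@backgroundLevel, nr, nc)
      img[label] <- spec@backgroundLevel + spec@punctumIntensity
      img <- illum * img + rnorm(nr * nc, sd = spec@noiseSd)
      img <- pmin(pmax(round(img), 0), 255)

      images[[length(images) + 1L]] <- img
      rois[[length(rois) + 1L]] <- roi
      freqs[[length(freqs) + 1L]] <- fmat
      labels[[length(labels) + 1L]] <- label
      illums <- c(illums, illum)
      zKept <- c(zKept, z)
    }
    if (!length(images)) stop("no section intersects the phantom")
    # in-plane transform: pixel (col, row, 1) -> stack-frame micrometres,
    # with section k (0-based) at stack z = k * thickness
    tf <- rbind(c(px, 0, xs[1] - px), c(0, px, ys[1] - px), c(0, 0, 1))
    transforms <- rep(list(tf), length(images))
    stack <- new("SectionStack", images = images, rois = rois,
                 transforms = transforms, pixelSizeUm = px,
                 spacingUm = th,
                 sectionIndex = seq_along(images) - 1L)
    # stack z = 0 corresponds to subject z = zKept[1]
    toSubject <- cbind(diag(3), c(0, 0, zKept[1]))
    af <- sum(vapply(seq_along(labels), function(i)
      sum(labels[[i]] & rois[[i]]), numeric(1))) /
      sum(vapply(rois, sum, numeric(1)))
    list(stack = stack,
         truth = list(frequencyKHz = freqs, labelMask = labels,
                      areaFraction = af, density = dens,
                      illumination = illums,
                      affineStackToTemplate = composeAffine(A, toSubject)))
  })
}
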