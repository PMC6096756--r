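# 3D reconstruction, affine template registration, frequency mapping,
# quarter-octave density profiles.

#' Stack section outlines into a 3D surface point cloud
#'
#' Lifts in-plane outline points of section k to z = k * spacing. The
#' first and last sections are marked as open ends (the reconstruction is
#' not closed there), so registration can exclude them.
#'
#' @param outlines list (one per section, in order) of n x 2 matrices of
#'   in-plane coordinates in micrometres; at least 3 sections.
#' @param spacingUm section spacing (default 50).
#' @param openEnds logical length 2: anterior/posterior end open.
#' @return a [SurfaceModel-class] point cloud.
#' @export
stackOutlines <- function(outlines, spacingUm = 50,
                          openEnds = c(TRUE, TRUE)) {
  if (length(outlines) < 3) stop("need at least 3 sections")
  verts <- do.call(rbind, lapply(seq_along(outlines), function(k) {
    o <- outlines[[k]]
    stopifnot(ncol(o) == 2)
    cbind(o, (k - 1) * spacingUm)
  }))
  sec <- rep(seq_along(outlines),
             vapply(outlines, nrow, integer(1)))
  new("SurfaceModel", vertices = verts,
      faces = matrix(integer(0), 0, 3),
      openEnds = openEnds, sectionOf = as.integer(sec))
}

#' Extract ROI boundary outlines from a section stack
#'
#' Boundary pixels of each ROI mask (ROI pixels with at least one
#' non-ROI 4-neighbour), mapped to stack micrometres through the
#' section's in-plane transform.
#'
#' @param stack a [SectionStack-class].
#' @param step keep every `step`-th boundary point (decimation).
#' @return list of n x 2 coordinate matrices, one per section.
#' @export
roiOutlines <- function(stack, step = 4L) {
  stopifnot(is(stack, "SectionStack"))
  lapply(seq_along(stack@rois), function(i) {
    roi <- stack@rois[[i]]
    nr <- nrow(roi); nc <- ncol(roi)
    pad <- matrix(FALSE, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- roi
    core <- pad[2:(nr + 1), 2:(nc + 1)] &
      pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
      pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
    b <- which(roi & !core, arr.ind = TRUE)
    b <- b[seq(1, nrow(b), by = step), , drop = FALSE]
    tf <- stack@transforms[[i]]
    xy <- t(tf %*% rbind(b[, "col"], b[, "row"], 1))[, 1:2, drop = FALSE]
    colnames(xy) <- c("x", "y")
    xy
  })
}

#' Mirror a left-hemisphere surface across the midline
#'
#' Left-side reconstructions are reflected over the sagittal plane (x = 0)
#' to match the right-handed template orientation; right-side surfaces are
#' returned unchanged.
#'
#' @param surface a [SurfaceModel-class].
#' @param side `"left"` or `"right"`.
#' @return a [SurfaceModel-class].
#' @export
mirrorHemisphere <- function(surface, side = c("right", "left")) {
  side <- match.arg(side)
  if (side == "right") return(surface)
  out <- surface
  out@vertices[, 1] <- -out@vertices[, 1]
  out
}

#' Fit a surface to the template by iterative affine registration
#'
#' Iterative-closest-point loop with a closed-form least-squares affine
#' update: each vertex is matched to its nearest template-surface point,
#' the 12-parameter affine minimizing the summed squared match distance is
#' solved in closed form, and the loop stops when the RMS vertex-template
#' distance improves by less than `tol` (micrometres) over `patience`
#' consecutive iterations, or at `maxIter`. Vertices on sections flagged
#' as open ends are excluded from matching and from the reported RMS.
#' Initialization matches centroids and per-axis spreads.
#'
#' @param surface a [SurfaceModel-class] (>= 12 vertices).
#' @param template a [FrequencyTemplate-class] or [SurfaceModel-class]
#'   providing the template surface.
#' @param tol minimum RMS improvement counted as progress (default 0.1).
#' @param maxIter iteration cap (default 100).
#' @param patience iterations without progress before stopping (default 5).
#' @return an [AffineFit-class]; `affineMatrix()` maps surface coordinates
#'   into template space.
#' @export
fitAffine <- function(surface, template, tol = 0.1, maxIter = 100L,
                      patience = 5L) {
  stopifnot(is(surface, "SurfaceModel"))
  tsurf <- if (is(template, "FrequencyTemplate")) template@surface
           else template
  stopifnot(is(tsurf, "SurfaceModel"))
  V <- surface@vertices
  keep <- rep(TRUE, nrow(V))
  if (any(surface@openEnds) && any(surface@sectionOf > 0L)) {
    secs <- range(surface@sectionOf[surface@sectionOf > 0L])
    if (surface@openEnds[1]) keep[surface@sectionOf == secs[1]] <- FALSE
    if (surface@openEnds[2]) keep[surface@sectionOf == secs[2]] <- FALSE
  }
  V <- V[keep, , drop = FALSE]
  if (nrow(V) < 12) stop("need at least 12 vertices (12 affine DOF)")
  if (any(apply(V, 2, sd) < 1e-9) ||
      abs(det(stats::cov(V))) < 1e-12)
    stop("degenerate (coplanar) vertex set")
  Tpts <- tsurf@vertices

  # PCA initialization: align principal axes and spreads. The principal
  # frame leaves a sign ambiguity per axis; the four proper-rotation sign
  # combinations are screened with a short ICP run each and the best is
  # refined to convergence.
  muV <- colMeans(V); muT <- colMeans(Tpts)
  eV <- eigen(stats::cov(V), symmetric = TRUE)
  eT <- eigen(stats::cov(Tpts), symmetric = TRUE)
  s <- sqrt(eT$values / eV$values)
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  inits <- lapply(signs, function(sg) {
    L <- eT$vectors %*% diag(s * sg) %*% t(eV$vectors)
    cbind(L, muT - L %*% muV)
  })

  run <- function(A, iters) {
    best <- A
    bestRms <- Inf
    sinceImprove <- 0L
    log <- data.frame(iter = integer(0), rms = numeric(0))
    for (it in seq_len(iters)) {
      moved <- applyAffinePoints(A, V)
      nn <- nearestNeighbours(moved, Tpts)
      r <- sqrt(mean(nn$distance^2))
      log <- rbind(log, data.frame(iter = it, rms = r))
      sinceImprove <- if (r < bestRms - tol) 0L else sinceImprove + 1L
      if (r < bestRms) {
        bestRms <- r
        best <- A
      }
      if (sinceImprove >= patience) break
      # closed-form affine update: V (homogeneous) -> matched points
      X <- cbind(V, 1)
      Y <- Tpts[nn$index, , drop = FALSE]
      B <- solve(crossprod(X), crossprod(X, Y))   # 4 x 3
      A <- t(B)
    }
    list(A = best, rms = bestRms, log = log)
  }

  screened <- lapply(inits, run, iters = min(15L, maxIter))
  seed <- screened[[which.min(vapply(screened, `[[`, numeric(1), "rms"))]]
  fin <- run(seed$A, maxIter)
  new("AffineFit", matrix = fin$A, rms = fin$rms, iterations = fin$log)
}

#' Map ROI pixels to template frequencies
#'
#' Concatenates each section's in-plane transform with the fitted 3D
#' affine to carry every ROI pixel centre into template space, then looks
#' up the frequency field by trilinear interpolation. Pixels landing
#' outside the valid-frequency mask are flagged unassigned (`NA`).
#'
#' @param stack a [SectionStack-class].
#' @param fit an [AffineFit-class] (stack coordinates to template space),
#'   or a bare 3x4 affine matrix.
#' @param template a [FrequencyTemplate-class].
#' @return list of per-section numeric matrices of frequency in kHz (`NA`
#'   outside the ROI or outside the valid-frequency mask).
#' @export
mapPixelFrequencies <- function(stack, fit, template) {
  stopifnot(is(stack, "SectionStack"), is(template, "FrequencyTemplate"))
  A <- if (is(fit, "AffineFit")) fit@matrix else fit
  if (abs(det(A[, 1:3])) < 1e-12) stop("non-invertible affine")
  fld <- template@field
  lapply(seq_along(stack@rois), function(i) {
    roi <- stack@rois[[i]]
    nr <- nrow(roi); nc <- ncol(roi)
    idx <- which(roi)
    rr <- ((idx - 1L) %% nr) + 1L
    cc <- ((idx - 1L) %/% nr) + 1L
    tf <- stack@transforms[[i]]
    if (abs(det(tf)) < 1e-12) stop("non-invertible in-plane transform")
    xy <- t(tf %*% rbind(cc, rr, 1))
    pts <- cbind(xy[, 1], xy[, 2],
                 stack@sectionIndex[i] * stack@spacingUm)
    q <- applyAffinePoints(A, pts)
    vox <- sweep(sweep(q, 2, template@originUm), 2,
                 rep(template@voxelSizeUm, 3), "/") + 1
    lf <- trilinear(fld, vox)
    out <- matrix(NA_real_, nr, nc)
    out[idx] <- 2^lf
    out
  })
}

#' Quarter-octave frequency bins
#'
#' Eleven bin centres at quarter-octave steps, symmetric in log2 about the
#' geometric mean of `fminKHz` and `fmaxKHz`; edges at centre times
#' 2^(+/- 1/8), half-open upward. The defaults reproduce the audiometric
#' 6-32 kHz binning with centres 5.8, 6.9, 8.2, 9.8, 11.7, 13.9, 16.5,
#' 19.6, 23.3, 27.7 and 33.0 kHz.
#'
#' @param fminKHz,fmaxKHz spanned frequency range (0 < fmin < fmax).
#' @param nBins number of centres (default 11).
#' @return list with `centersKHz` and `edgesKHz` (length `nBins + 1`).
#' @examples
#' round(quarterOctaveBins()$centersKHz, 1)
#' @export
quarterOctaveBins <- function(fminKHz = 6, fmaxKHz = 32, nBins = 11L) {
  if (!(fminKHz > 0 && fminKHz < fmaxKHz))
    stop("need 0 < fminKHz < fmaxKHz")
  mid <- sqrt(fminKHz * fmaxKHz)
  k <- seq_len(nBins) - (nBins + 1) / 2
  centers <- mid * 2^(k / 4)
  edges <- c(centers * 2^(-1 / 8), centers[nBins] * 2^(1 / 8))
  list(centersKHz = centers, edgesKHz = edges)
}

#' Label density per quarter-octave frequency bin
#'
#' Counts labeled (thresholded) and total ROI pixels within each frequency
#' bin and forms per-bin densities. Pixels with no assigned frequency are
#' excluded from both numerator and denominator; empty bins are flagged
#' with `NA` density rather than zero. Per-bin totals over the spanned
#' range sum exactly to the number of assigned in-range pixels.
#'
#' @param pixelFreqs per-section frequency matrices from
#'   [mapPixelFrequencies()] (kHz, `NA` where unassigned).
#' @param labelMasks per-section logical matrices of thresholded pixels.
#' @param bins bin definition from [quarterOctaveBins()].
#' @return data.frame with `centerKHz`, `labeled`, `total`, `density`.
#' @export
densityByBin <- function(pixelFreqs, labelMasks, bins = quarterOctaveBins()) {
  stopifnot(length(pixelFreqs) == length(labelMasks))
  nb <- length(bins$centersKHz)
  labeled <- integer(nb); total <- integer(nb)
  for (i in seq_along(pixelFreqs)) {
    f <- pixelFreqs[[i]]
    lab <- labelMasks[[i]]
    stopifnot(all(dim(f) == dim(lab)))
    ok <- !is.na(f)
    b <- findInterval(f[ok], bins$edgesKHz, rightmost.closed = FALSE)
    inRange <- b >= 1 & b <= nb
    bi <- b[inRange]
    total <- total + tabulate(bi, nbins = nb)
    labeled <- labeled + tabulate(bi[lab[ok][inRange]], nbins = nb)
  }
  data.frame(centerKHz = bins$centersKHz, labeled = labeled, total = total,
             density = ifelse(total > 0, labeled / total, NA_real_))
}
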