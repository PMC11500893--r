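#' Define the volume of interest on an image
#'
#' In `ground_truth` mode the lesion-template support is resampled onto the
#' image grid: every image voxel covered at least 50% by support cells
#' (exact axis-separable box-overlap computation) enters the VOI. This
#' removes the manual-contouring variability of interactive segmentation by
#' construction. `threshold` mode keeps voxels with SUV at or above the
#' given threshold.
#'
#' @param template a [LesionTemplate-class] (ground_truth mode) or `NULL`.
#' @param image the [SUVImage-class] the mask must align with.
#' @param mode `"ground_truth"` or `"threshold"`.
#' @param threshold SUV cut (threshold mode).
#' @param minOccupancy occupancy fraction for ground-truth resampling
#'   (default 0.5).
#' @return a [VOIMask-class] aligned to `image`.
#' @examples
#' \donttest{
#' les <- lesionPreset("L1")
#' plan <- planTrajectory(les, acquisitionTime = 1730)
#' ses <- phantomSession(backgroundActivityMbq = 87.2,
#'                       acquisitionTimeS = 1730)
#' img <- acquire(paintGroundTruth(les, plan, ses),
#'                imagingSettings()[["A"]], seed = 1)
#' voi <- makeVOI(les, img)
#' volumeMl(voi)
#' }
#' @export
makeVOI <- function(template = NULL, image,
                    mode = c("ground_truth", "threshold"),
                    threshold = NULL, minOccupancy = 0.5) {
  mode <- match.arg(mode)
  stopifnot(is(image, "SUVImage") || is(image, "ImageVolume"))
  dImg <- dim(image@values)

  if (mode == "threshold") {
    if (is.null(threshold)) stopf("'threshold' required in threshold mode")
    m <- image@values >= threshold
    if (!any(m))
      stopf("empty VOI: threshold %.3g above the image maximum %.3g",
            threshold, max(image@values))
    return(new("VOIMask", mask = m, spacing = image@spacing,
               origin = image@origin))
  }

  stopifnot(is(template, "LesionTemplate"))
  sup <- template@values > 0
  h <- template@gridSpacing
  nT <- dim(sup)
  # axis-separable overlap length between template cells and image voxels;
  # both grids are centred on the painting-cube centre
  ov <- vector("list", 3L)
  for (d in 1:3) {
    cT <- axisCentres(nT[d], h)
    cI <- axisCentres(dImg[d], image@spacing[d])
    # overlap(i, t) = max(0, min(hi_i, hi_t) - max(lo_i, lo_t))
    hiM <- outer(cI + image@spacing[d] / 2, cT + h / 2, pmin)
    loM <- outer(cI - image@spacing[d] / 2, cT - h / 2, pmax)
    ov[[d]] <- pmax(hiM - loM, 0)
  }
  # covered volume per voxel: mode-products of the support tensor
  s <- array(as.numeric(sup), nT)
  # contract dim1: (nI1 x nT1) %*% (nT1 x nT2*nT3)
  t1 <- ov[[1]] %*% matrix(s, nrow = nT[1])          # nI1 x (nT2*nT3)
  a1 <- array(t1, c(dImg[1], nT[2], nT[3]))
  a1p <- aperm(a1, c(2, 1, 3))
  t2 <- ov[[2]] %*% matrix(a1p, nrow = nT[2])        # nI2 x (nI1*nT3)
  a2 <- aperm(array(t2, c(dImg[2], dImg[1], nT[3])), c(2, 1, 3))
  a2p <- aperm(a2, c(3, 1, 2))
  t3 <- ov[[3]] %*% matrix(a2p, nrow = nT[3])        # nI3 x (nI1*nI2)
  cov <- aperm(array(t3, c(dImg[3], dImg[1], dImg[2])), c(2, 3, 1))
  occ <- cov / prod(image@spacing)
  m <- occ >= minOccupancy
  if (!any(m))
    stopf("empty VOI: no image voxel reaches %.0f%% template occupancy",
          100 * minOccupancy)
  new("VOIMask", mask = m, spacing = image@spacing, origin = image@origin)
}

#' Trilinear interpolation of a 3-D array at fractional voxel indices
#' @noRd
trilinear <- function(a, fi, fj, fk) {
  d <- dim(a)
  fi <- pmin(pmax(fi, 1), d[1]); fj <- pmin(pmax(fj, 1), d[2])
  fk <- pmin(pmax(fk, 1), d[3])
  i0 <- pmin(floor(fi), d[1] - 1L); j0 <- pmin(floor(fj), d[2] - 1L)
  k0 <- pmin(floor(fk), d[3] - 1L)
  ti <- fi - i0; tj <- fj - j0; tk <- fk - k0
  g <- function(di, dj, dk) a[cbind(i0 + di, j0 + dj, k0 + dk)]
  (1 - ti) * (1 - tj) * (1 - tk) * g(0, 0, 0) +
    ti * (1 - tj) * (1 - tk) * g(1, 0, 0) +
    (1 - ti) * tj * (1 - tk) * g(0, 1, 0) +
    ti * tj * (1 - tk) * g(1, 1, 0) +
    (1 - ti) * (1 - tj) * tk * g(0, 0, 1) +
    ti * (1 - tj) * tk * g(1, 0, 1) +
    (1 - ti) * tj * tk * g(0, 1, 1) +
    ti * tj * tk * g(1, 1, 1)
}

#' Spatially resample an SUV image (and optionally its VOI)
#'
#' Intensities are interpolated trilinearly onto an isotropic (or given
#' anisotropic) grid covering the same field of view and centred on the same
#' origin convention; a companion mask is resampled nearest-neighbour.
#'
#' @param image an [SUVImage-class].
#' @param newSpacing target voxel size in mm (scalar or mm triple).
#' @param voi optional [VOIMask-class] aligned with `image`.
#' @return the resampled [SUVImage-class], or a list `list(image, voi)` when
#'   a VOI is supplied.
#' @examples
#' img <- new("SUVImage", values = array(runif(8^3), c(8, 8, 8)),
#'            spacing = rep(2, 3), origin = rep(-7, 3),
#'            settingCode = "A", lesionName = "demo")
#' img2 <- resampleImage(img, 2.5)
#' @export
resampleImage <- function(image, newSpacing, voi = NULL) {
  stopifnot(is(image, "ImageVolume"))
  newSpacing <- rep_len(newSpacing, 3L)
  if (any(newSpacing <= 0)) stopf("'newSpacing' must be positive")
  dOld <- dim(image@values)
  ext <- dOld * image@spacing
  nNew <- pmax(1L, as.integer(round(ext / newSpacing)))
  # fractional old-grid indices of the new voxel centres (grids centred)
  fidx <- lapply(1:3, function(d) {
    cN <- axisCentres(nNew[d], newSpacing[d])
    (cN - axisCentres(dOld[d], image@spacing[d])[1]) / image@spacing[d] + 1
  })
  fi <- fidx[[1]][slice.index(array(0, nNew), 1)]
  fj <- fidx[[2]][slice.index(array(0, nNew), 2)]
  fk <- fidx[[3]][slice.index(array(0, nNew), 3)]
  vals <- array(trilinear(image@values, fi, fj, fk), nNew)
  out <- new("SUVImage",
             values = vals, spacing = newSpacing,
             origin = vapply(1:3, function(d)
               axisCentres(nNew[d], newSpacing[d])[1], numeric(1)),
             settingCode = if (is(image, "SUVImage")) image@settingCode else "?",
             lesionName = if (is(image, "SUVImage")) image@lesionName else "?")
  if (is.null(voi)) return(out)
  stopifnot(is(voi, "VOIMask"))
  ni <- pmin(pmax(round(fi), 1), dOld[1])
  nj <- pmin(pmax(round(fj), 1), dOld[2])
  nk <- pmin(pmax(round(fk), 1), dOld[3])
  m <- array(voi@mask[cbind(ni, nj, nk)], nNew)
  if (!any(m)) stopf("VOI vanished under resampling to %.3g mm",
                     max(newSpacing))
  list(image = out,
       voi = new("VOIMask", mask = m, spacing = newSpacing,
                 origin = out@origin))
}

#' Grey-level discretization with a fixed bin size (absolute method)
#'
#' Maps each in-VOI SUV to level `floor(I / B) + 1`: level 1 covers
#' `[0, B)`, level 2 `[B, 2B)`, and so on. The printed bin-mapping formula
#' leaves the rounding operator implicit; the floor-plus-one convention used
#' by the LIFEx/IBSI processing chain is adopted so that `I = 0` falls in
#' the lowest bin.
#'
#' @param image an [SUVImage-class].
#' @param voi a [VOIMask-class] aligned with it.
#' @param B bin width in SUV (default 0.3125).
#' @return a [GreyLevelVolume-class] over the VOI bounding box.
#' @examples
#' img <- new("SUVImage", values = array(runif(27, 0, 4), c(3, 3, 3)),
#'            spacing = rep(3, 3), origin = rep(-3, 3),
#'            settingCode = "A", lesionName = "demo")
#' voi <- new("VOIMask", mask = array(TRUE, c(3, 3, 3)),
#'            spacing = rep(3, 3), origin = rep(-3, 3))
#' nLevels(discretizeFBS(img, voi))
#' @export
discretizeFBS <- function(image, voi, B = 0.3125) {
  stopifnot(is(image, "ImageVolume"), is(voi, "VOIMask"))
  if (B <= 0) stopf("'B' must be a positive SUV bin width")
  checkAligned(image, voi)
  vals <- voiCrop(image@values, voi@mask)
  inv <- !is.na(vals)
  if (any(vals[inv] < 0)) {
    warnf("negative SUV values clamped to 0 before FBS discretization")
    vals[inv & vals < 0] <- 0
  }
  lev <- array(NA_integer_, dim(vals))
  lev[inv] <- as.integer(floor(vals[inv] / B)) + 1L
  new("GreyLevelVolume",
      levels = lev, nLevels = max(lev, na.rm = TRUE),
      method = "FBS", binWidth = B, binCount = NA_integer_,
      intensityRange = range(vals, na.rm = TRUE), spacing = voi@spacing)
}

#' Grey-level discretization with a fixed bin number (relative method)
#'
#' Maps in-VOI SUVs onto `D` levels spanning the VOI intensity range:
#' `floor(D * (I - Imin) / (Imax - Imin)) + 1` for `I < Imax`, and level `D`
#' at `I = Imax` (the top edge belongs to the last bin). A constant VOI is
#' degenerate: every voxel gets level 1 with a warning.
#'
#' @param image an [SUVImage-class].
#' @param voi a [VOIMask-class].
#' @param D number of bins (default 64), `>= 2`.
#' @return a [GreyLevelVolume-class].
#' @export
discretizeFBN <- function(image, voi, D = 64L) {
  stopifnot(is(image, "ImageVolume"), is(voi, "VOIMask"))
  D <- as.integer(D)
  if (is.na(D) || D < 2L) stopf("'D' must be an integer >= 2")
  checkAligned(image, voi)
  vals <- voiCrop(image@values, voi@mask)
  inv <- !is.na(vals)
  iMin <- min(vals[inv]); iMax <- max(vals[inv])
  lev <- array(NA_integer_, dim(vals))
  if (iMax == iMin) {
    warnf("constant VOI: relative discretization is degenerate (all level 1)")
    lev[inv] <- 1L
    nL <- 1L
  } else {
    lev[inv] <- pmin(
      as.integer(floor(D * (vals[inv] - iMin) / (iMax - iMin))) + 1L, D)
    nL <- max(lev, na.rm = TRUE)
  }
  new("GreyLevelVolume",
      levels = lev, nLevels = nL,
      method = "FBN", binWidth = NA_real_, binCount = D,
      intensityRange = c(iMin, iMax), spacing = voi@spacing)
}

#' @noRd
checkAligned <- function(image, voi) {
  if (!identical(dim(image@values), dim(voi@mask)) ||
      max(abs(image@spacing - voi@spacing)) > 1e-6)
    stopf("image and VOI grids are not aligned")
  invisible(TRUE)
}

#' Crop image values to the VOI bounding box, NA outside the mask
#' @noRd
voiCrop <- function(values, mask) {
  idx <- which(mask, arr.ind = TRUE)
  rng <- lapply(1:3, function(d) seq(min(idx[, d]), max(idx[, d])))
  v <- values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  m <- mask[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  v[!m] <- NA_real_
  dim(v) <- vapply(rng, length, integer(1))
  v
}
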