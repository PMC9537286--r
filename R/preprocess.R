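#' Pre-processing configuration for feature extraction
#'
#' Bundles the image pre-processing parameters: 1 mm isotropic resampling,
#' the [-150, 180] HU re-segmentation window that removes air cavities and
#' bone, the Laplacian-of-Gaussian kernel widths, and the fixed bin number
#' used to discretise intensities for histogram and texture features.
#'
#' @param targetSpacing numeric(3) or scalar, resampling target in mm.
#' @param huWindow numeric(2), closed HU re-segmentation interval.
#' @param logSigmas numeric, LoG kernel widths in mm.
#' @param nBins integer >= 2, fixed bin number for discretisation.
#' @return list of class "PreprocessConfig".
#' @export
preprocessConfig <- function(targetSpacing = 1.0,
                             huWindow = c(-150, 180),
                             logSigmas = c(1, 2, 3, 4, 5),
                             nBins = 32L) {
  if (length(targetSpacing) == 1L) targetSpacing <- rep(targetSpacing, 3L)
  stopifnot(all(targetSpacing > 0), length(huWindow) == 2L,
            huWindow[1] < huWindow[2], all(logSigmas > 0), nBins >= 2L)
  structure(list(targetSpacing = targetSpacing, huWindow = huWindow,
                 logSigmas = logSigmas, nBins = as.integer(nBins)),
            class = "PreprocessConfig")
}

#' Resample a volume and mask to an isotropic grid
#'
#' Intensities are interpolated with tricubic (Catmull-Rom) splines, the
#' mask with trilinear interpolation thresholded at 0.5.  The output grid
#' shares the input's physical frame (same origin, extent covered).
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param mask the paired \linkS4class{RoiMask}.
#' @param target numeric(3) or scalar target spacing in mm.
#' @return list(volume, mask), both on the new grid.
#' @export
resampleIsotropic <- function(vol, mask, target = 1.0) {
  if (length(target) == 1L) target <- rep(target, 3L)
  stopifnot(all(target > 0),
            identical(dim(voxelArray(vol)), dim(morphMask(mask))))
  dIn <- dim(voxelArray(vol))
  spIn <- voxelSpacing(vol)
  # grid-centre alignment: the output grid covers the same physical
  # extent with its centre matched to the input's (also avoids sampling
  # exactly on voxel-face midpoints at integer spacing ratios)
  dOut <- pmax(1L, as.integer(ceiling(dIn * spIn / target)))
  tPhys <- ((dIn - 1) * spIn - (dOut - 1) * target) / 2
  scale <- target / spIn
  M <- diag(scale)
  tvec <- tPhys / spIn
  arr <- .affineResample(as.numeric(voxelArray(vol)), as.integer(dIn),
                         as.integer(dOut), M, tvec, "cubic")
  dim(arr) <- dOut
  msk <- .affineResample(as.numeric(morphMask(mask)), as.integer(dIn),
                         as.integer(dOut), M, tvec, "linear")
  dim(msk) <- dOut
  mskL <- msk >= 0.5
  if (!any(mskL)) stop("degenerate ROI: mask empty after resampling")
  newOrigin <- volumeOrigin(vol) + tPhys
  list(volume = ImageVolume(arr, target, newOrigin),
       mask = RoiMask(mskL, target, newOrigin))
}

#' Re-segment the ROI by a Hounsfield-unit window
#'
#' Removes voxels whose intensity falls outside the closed window (air
#' cavities and bone inside the delineation) from the intensity mask while
#' leaving the morphological mask untouched, so shape features still see
#' the full delineation.
#'
#' @param vol an \linkS4class{ImageVolume} (resampled).
#' @param mask the paired \linkS4class{RoiMask}.
#' @param window numeric(2), closed HU interval retained (default
#'   \code{c(-150, 180)}).
#' @return a \linkS4class{RoiMask} with the updated intensity mask.
#' @export
resegmentIntensity <- function(vol, mask, window = c(-150, 180)) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  v <- voxelArray(vol)
  keep <- morphMask(mask) & v >= window[1] & v <= window[2]
  if (!any(keep)) stop("degenerate ROI: intensity mask empty after ",
                       "re-segmentation")
  RoiMask(morphMask(mask), voxelSpacing(mask), volumeOrigin(mask),
          intensity = keep)
}

gaussKernel1d <- function(sigmaVox, order = 0L) {
  r <- max(1L, as.integer(ceiling(4 * sigmaVox)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigmaVox^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  # sampled second derivative of the (normalised) Gaussian; DC removed so
  # a constant image maps to exactly zero
  g2 <- (x^2 - sigmaVox^2) / sigmaVox^4 * g
  g2 - mean(g2)
}

logFilterSingle <- function(arr, spacing, sigmaMm) {
  d <- as.integer(dim(arr))
  g <- lapply(1:3, function(a) gaussKernel1d(sigmaMm / spacing[a], 0L))
  g2 <- lapply(1:3, function(a) gaussKernel1d(sigmaMm / spacing[a], 2L))
  x <- as.numeric(arr)
  # share Gaussian passes across the three second-derivative terms
  sx <- .conv1dAxis(x, d, g[[1]], 0L)
  sxy <- .conv1dAxis(sx, d, g[[2]], 1L)
  termZ <- .conv1dAxis(sxy, d, g2[[3]], 2L)
  sxz <- .conv1dAxis(sx, d, g[[3]], 2L)
  termY <- .conv1dAxis(sxz, d, g2[[2]], 1L)
  syz <- .conv1dAxis(.conv1dAxis(x, d, g[[2]], 1L), d, g[[3]], 2L)
  termX <- .conv1dAxis(syz, d, g2[[1]], 0L)
  array(termX + termY + termZ, d)
}

#' Mean Laplacian-of-Gaussian response image
#'
#' Applies LoG filters with the configured kernel widths (mm) individually
#' to the base image and returns the voxelwise arithmetic mean of the
#' responses.  Filtering is separable with mirror boundary padding; sigma
#' in mm is converted to voxels through the spacing.
#'
#' @param vol an \linkS4class{ImageVolume} (isotropic recommended).
#' @param sigmas numeric, kernel widths in mm (default 1:5).
#' @return an \linkS4class{ImageVolume} holding the mean response.
#' @export
logFilterBank <- function(vol, sigmas = c(1, 2, 3, 4, 5)) {
  sp <- voxelSpacing(vol)
  if (any(sigmas < min(sp) / 2))
    stop("LoG sigma smaller than half a voxel: increase sigma or resample")
  arr <- voxelArray(vol)
  acc <- array(0, dim(arr))
  for (s in sigmas) acc <- acc + logFilterSingle(arr, sp, s)
  ImageVolume(acc / length(sigmas), sp, volumeOrigin(vol))
}

#' Fixed-bin-number intensity discretisation
#'
#' Maps in-mask intensities onto integer bins 1..nBins over the in-mask
#' min-max range.  A constant region collapses to a single grey level.
#' Voxels outside the intensity mask are NA.
#'
#' @param vol an \linkS4class{ImageVolume}.
#' @param mask a \linkS4class{RoiMask}; its intensity mask is used.
#' @param nBins integer >= 2.
#' @return integer 3D array with NA outside the mask.
#' @export
discretiseIntensities <- function(vol, mask, nBins = 32L) {
  stopifnot(nBins >= 2L)
  m <- intensityMask(mask)
  if (!any(m)) stop("empty intensity mask")
  v <- voxelArray(vol)
  x <- v[m]
  lo <- min(x); hi <- max(x)
  out <- array(NA_integer_, dim(v))
  if (hi == lo) {
    out[m] <- 1L
  } else {
    b <- pmin(as.integer(floor((x - lo) / (hi - lo) * nBins)) + 1L,
              as.integer(nBins))
    out[m] <- b
  }
  out
}
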