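# Augmentation-based feature stability: image rotations and segmentation
# volume changes, one-way random-effects ICC, and the CI-lower-bound filter.

#' The image augmentation scheme used for stability analysis
#'
#' In-plane rotations about the cranio-caudal axis crossed with relative
#' volume changes of the segmentation: 5 x 4 = 20 variants per patient.
#'
#' @param rotationsDeg rotations in degrees.
#' @param volumeChanges relative volume changes (fractions).
#' @param tolerance relative tolerance on the achieved volume change.
#' @return list of class "AugmentationScheme".
#' @export
augmentationScheme <- function(rotationsDeg = c(-4, -2, 0, 2, 4),
                               volumeChanges = c(-0.2, -0.1, 0.1, 0.2),
                               tolerance = 0.01) {
  structure(list(rotationsDeg = rotationsDeg,
                 volumeChanges = volumeChanges, tolerance = tolerance),
            class = "AugmentationScheme")
}

rotateVolumeZ <- function(arr, angleDeg, method) {
  d <- dim(arr)
  if (angleDeg == 0) return(arr)
  th <- angleDeg * pi / 180
  # inverse mapping: input coords of each output voxel, rotation about the
  # grid centre in the x-y plane
  Rm <- matrix(c(cos(th), -sin(th), 0,
                 sin(th), cos(th), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  ctr <- (d - 1) / 2
  tvec <- as.numeric(ctr - Rm %*% ctr)
  out <- .affineResample(as.numeric(arr), as.integer(d), as.integer(d),
                         Rm, tvec, method)
  array(out, d)
}

signedDistance <- function(m, spacing) {
  dOut <- .edtSquared(as.integer(m), as.integer(dim(m)), spacing)
  dIn <- .edtSquared(as.integer(!m), as.integer(dim(m)), spacing)
  array(sqrt(dOut) - sqrt(dIn), dim(m))   # >0 outside, <0 inside
}

resizeMask <- function(m, spacing, relChange, tolerance = 0.01) {
  n0 <- sum(m)
  target <- as.integer(round(n0 * (1 + relChange)))
  if (target < 1L || target > length(m)) return(NULL)
  sd0 <- signedDistance(m, spacing)
  # thresholding the signed EDT == keeping the `target` voxels with the
  # smallest signed distance; ties within the critical distance shell are
  # broken deterministically by array order so the achieved volume is
  # exact (well within the tolerance)
  keep <- order(as.numeric(sd0))[seq_len(target)]
  cand <- array(FALSE, dim(m))
  cand[keep] <- TRUE
  if (abs(sum(cand) / (n0 * (1 + relChange)) - 1) > tolerance) return(NULL)
  cand
}

#' Generate augmentation variants of a volume/mask pair
#'
#' One variant per (rotation, volume change) pair.  The image is rotated
#' with cubic interpolation, the mask with linear interpolation thresholded
#' at 0.5; the volume change is achieved by thresholding the signed
#' Euclidean distance transform of the mask at an offset found by
#' bisection.  Unreachable targets are dropped with a warning.
#'
#' @param vol an \linkS4class{ImageVolume} (pre-processed).
#' @param mask the paired \linkS4class{RoiMask}.
#' @param scheme an \code{\link{augmentationScheme}}.
#' @return named list of list(volume, mask, rotation, volumeChange).
#' @export
augmentImage <- function(vol, mask, scheme = augmentationScheme()) {
  sp <- voxelSpacing(vol)
  arr <- voxelArray(vol)
  m0 <- morphMask(mask)
  out <- list()
  for (rot in scheme$rotationsDeg) {
    if (rot == 0) {
      arrR <- arr
      mR <- m0
    } else {
      arrR <- rotateVolumeZ(arr, rot, "cubic")
      mR <- rotateVolumeZ(array(as.numeric(m0), dim(m0)), rot,
                          "linear") >= 0.5
    }
    for (vc in scheme$volumeChanges) {
      mV <- resizeMask(mR, sp, vc, scheme$tolerance)
      key <- sprintf("rot%+g_vol%+g", rot, vc * 100)
      if (is.null(mV)) {
        warning("volume change ", vc, " unreachable at rotation ", rot,
                "; variant dropped")
        next
      }
      out[[key]] <- list(volume = ImageVolume(arrR, sp, volumeOrigin(vol)),
                         mask = RoiMask(mV, sp, volumeOrigin(vol)),
                         rotation = rot, volumeChange = vc)
    }
  }
  out
}

#' One-way random-effects intraclass correlation ICC(1,1)
#'
#' From the one-way ANOVA decomposition of a subjects x conditions table:
#' ICC = (MSB - MSW) / (MSB + (k-1) MSW), with a 95\% confidence interval
#' from the F-distribution bounds.  Estimates are clipped to [-1, 1].  A
#' table with zero total variance is defined as ICC 1 with degenerate CI.
#'
#' @param values numeric matrix, subjects in rows, conditions in columns,
#'   no missing cells.
#' @param conf confidence level (default 0.95).
#' @return list(icc, ci_low, ci_high, degenerate).
#' @export
iccOneWay <- function(values, conf = 0.95) {
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 conditions")
  if (anyNA(values)) stop("missing cells are not allowed")
  gm <- mean(values)
  rm <- rowMeans(values)
  msb <- k * sum((rm - gm)^2) / (n - 1)
  msw <- sum((values - rm)^2) / (n * (k - 1))
  if (msb == 0 && msw == 0)
    return(list(icc = 1, ci_low = 1, ci_high = 1, degenerate = TRUE))
  if (msw == 0)
    return(list(icc = 1, ci_low = 1, ci_high = 1, degenerate = FALSE))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  alpha <- 1 - conf
  Fobs <- msb / msw
  fl <- Fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
  fu <- Fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
  clip <- function(x) max(-1, min(1, x))
  list(icc = clip(icc),
       ci_low = clip((fl - 1) / (fl + k - 1)),
       ci_high = clip((fu - 1) / (fu + k - 1)),
       degenerate = FALSE)
}

#' Filter features by ICC stability under augmentation
#'
#' A feature is retained when the lower bound of the 95\% CI of its
#' one-way ICC across augmentation variants is at least the threshold.
#'
#' @param featureArray 3D numeric array patients x variants x features
#'   (dimnames on the feature axis).  Patients with any missing variant are
#'   excluded from that feature's ICC with a warning.
#' @param threshold CI lower-bound retention threshold (default 0.75).
#' @return data.frame(feature, icc, ci_low, ci_high, retained) of class
#'   "StabilityReport".
#' @export
stabilityFilter <- function(featureArray, threshold = 0.75) {
  stopifnot(length(dim(featureArray)) == 3L)
  feats <- dimnames(featureArray)[[3]]
  if (is.null(feats)) feats <- sprintf("f%03d", seq_len(dim(featureArray)[3]))
  rows <- lapply(seq_along(feats), function(fi) {
    tab <- featureArray[, , fi, drop = FALSE]
    dim(tab) <- dim(featureArray)[1:2]
    bad <- apply(tab, 1, anyNA)
    if (any(bad)) {
      warning(sum(bad), " patient(s) with missing variants excluded for ",
              feats[fi])
      tab <- tab[!bad, , drop = FALSE]
    }
    r <- iccOneWay(tab)
    data.frame(feature = feats[fi], icc = r$icc, ci_low = r$ci_low,
               ci_high = r$ci_high, retained = r$ci_low >= threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("StabilityReport", "data.frame")
  out
}
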