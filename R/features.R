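# Radiomics feature families.  Naming convention: base-image features are
# "<family>_<name>" (e.g. morph_vol_dens_aabb, szm_glnu); features from the
# mean Laplacian-of-Gaussian response carry a "log_" prefix (log_stat_p90).
# Morphology uses the morphological mask; statistical, local-intensity,
# histogram and texture families use the intensity mask.  Morphological and
# texture families are never computed on the LoG image.

statFeatures <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  sdv <- sqrt(m2)
  c(stat_mean = mu,
    stat_var = m2,
    stat_skew = if (m2 > 0) m3 / sdv^3 else 0,
    stat_kurt = if (m2 > 0) m4 / m2^2 - 3 else 0,
    stat_median = stats::median(x),
    stat_min = min(x),
    stat_max = max(x),
    stat_p10 = pctl(x, 0.10),
    stat_p90 = pctl(x, 0.90),
    stat_iqr = pctl(x, 0.75) - pctl(x, 0.25),
    stat_range = max(x) - min(x),
    stat_energy = sum(x^2),
    stat_rms = sqrt(mean(x^2)))
}

surfaceAreaVoxel <- function(m, spacing) {
  d <- dim(m)
  area <- 0
  faceArea <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                spacing[1] * spacing[2])
  for (ax in 1:3) {
    pad <- d
    pad[ax] <- pad[ax] + 2L
    big <- array(FALSE, pad)
    idx <- lapply(seq_along(d), function(a)
      if (a == ax) seq_len(d[a]) + 1L else seq_len(d[a]))
    big[idx[[1]], idx[[2]], idx[[3]]] <- m
    lo <- hi <- idx
    lo[[ax]] <- lo[[ax]] - 1L
    hi[[ax]] <- hi[[ax]] + 1L
    nlo <- big[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    nhi <- big[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
    area <- area + (sum(m & !nlo) + sum(m & !nhi)) * faceArea[ax]
  }
  area
}

boundaryVoxelCoords <- function(m, spacing) {
  d <- dim(m)
  idx <- which(m, arr.ind = TRUE)
  onb <- rep(FALSE, nrow(idx))
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, ax] <- nb[, ax] + s
      out <- nb[, ax] < 1L | nb[, ax] > d[ax]
      inside <- !out
      flat <- (nb[inside, 3] - 1L) * d[1] * d[2] +
        (nb[inside, 2] - 1L) * d[1] + nb[inside, 1]
      offmask <- rep(TRUE, nrow(idx))
      offmask[inside] <- !m[flat]
      onb <- onb | out | offmask
    }
  }
  sweep(idx[onb, , drop = FALSE] - 1, 2, spacing, `*`)
}

morphFeatures <- function(mask) {
  m <- morphMask(mask)
  sp <- voxelSpacing(mask)
  n <- sum(m)
  volMm3 <- n * prod(sp)
  idx <- which(m, arr.ind = TRUE)
  bbox <- apply(idx, 2, range)
  bboxVox <- prod(bbox[2, ] - bbox[1, ] + 1L)
  area <- surfaceAreaVoxel(m, sp)
  diam <- if (n == 1L) 0 else .maxPairDist(boundaryVoxelCoords(m, sp))
  c(morph_volume = volMm3 / 1000,             # cm^3 (GTV)
    morph_surface_area = area,                # mm^2
    morph_compactness = 36 * pi * volMm3^2 / area^3,
    morph_sphericity = pi^(1 / 3) * (6 * volMm3)^(2 / 3) / area,
    morph_max_diam = diam,                    # mm
    morph_vol_dens_aabb = n / bboxVox)
}

localIntensityFeatures <- function(vol, mask) {
  sp <- voxelSpacing(vol)
  r <- (3 / (4 * pi) * 1000)^(1 / 3)          # 1 cm^3 sphere radius in mm
  ri <- floor(r / sp)
  g <- as.matrix(expand.grid(di = -ri[1]:ri[1], dj = -ri[2]:ri[2],
                             dk = -ri[3]:ri[3]))
  keep <- sqrt((g[, 1] * sp[1])^2 + (g[, 2] * sp[2])^2 +
                 (g[, 3] * sp[3])^2) <= r
  pk <- .intensityPeaks(as.numeric(voxelArray(vol)),
                        as.integer(dim(voxelArray(vol))),
                        as.integer(intensityMask(mask)),
                        g[keep, , drop = FALSE])
  c(loc_peak_local = pk[1], loc_peak_global = pk[2])
}

histFeatures <- function(disc, nBins) {
  x <- disc[!is.na(disc)]
  cnt <- tabulate(x, nbins = nBins)
  p <- cnt / sum(cnt)
  nz <- p > 0
  grad <- (c(cnt[-1], cnt[nBins]) - c(cnt[1], cnt[-nBins])) / 2
  c(ih_entropy = -sum(p[nz] * log2(p[nz])),
    ih_uniformity = sum(p^2),
    ih_mode = which.max(cnt),                 # lowest bin on ties
    ih_grad_max = max(grad),
    ih_grad_max_level = which.max(grad),
    ih_grad_min = min(grad),
    ih_grad_min_level = which.min(grad))
}

glszmFeatures <- function(disc) {
  zones <- .glszmZones(as.integer(disc), as.integer(dim(disc)))
  lev <- zones[, 1]
  siz <- zones[, 2]
  ns <- nrow(zones)
  nv <- sum(!is.na(disc))
  glCnt <- table(lev)
  zsCnt <- table(siz)
  p <- rep(1 / ns, ns)
  muL <- sum(lev * p)
  muS <- sum(siz * p)
  pj <- as.numeric(table(factor(paste(lev, siz))) / ns)
  c(szm_sze = sum(1 / siz^2) / ns,
    szm_lze = sum(siz^2) / ns,
    szm_glnu = sum(as.numeric(glCnt)^2) / ns,
    szm_glnu_norm = sum(as.numeric(glCnt)^2) / ns^2,
    szm_zsnu = sum(as.numeric(zsCnt)^2) / ns,
    szm_zsnu_norm = sum(as.numeric(zsCnt)^2) / ns^2,
    szm_z_perc = ns / nv,
    szm_gl_var = sum((lev - muL)^2 * p),
    szm_zs_var = sum((siz - muS)^2 * p),
    szm_zs_entr = -sum(pj * log2(pj)))
}

glcmFeaturesOne <- function(cnt) {
  tot <- sum(cnt)
  if (tot == 0) return(NULL)
  p <- cnt / tot
  g <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mu <- sum(i * p)
  sg <- sqrt(sum((i - mu)^2 * p))
  nz <- p > 0
  corr <- if (sg > 0) (sum(i * j * p) - mu^2) / sg^2 else 1
  c(cm_joint_max = max(p),
    cm_contrast = sum((i - j)^2 * p),
    cm_dissimilarity = sum(abs(i - j) * p),
    cm_joint_entr = -sum(p[nz] * log2(p[nz])),
    cm_energy = sum(p^2),
    cm_inv_diff = sum(p / (1 + abs(i - j))),
    cm_inv_diff_mom = sum(p / (1 + (i - j)^2)),
    cm_corr = corr)
}

glcmFeatures <- function(disc, nBins) {
  mats <- .glcmCounts(as.integer(disc), as.integer(dim(disc)),
                      as.integer(nBins))
  per <- Filter(Negate(is.null), lapply(mats, glcmFeaturesOne))
  if (!length(per)) {
    # single-voxel / disconnected ROI: co-occurrence undefined
    nm <- c("cm_joint_max", "cm_contrast", "cm_dissimilarity",
            "cm_joint_entr", "cm_energy", "cm_inv_diff", "cm_inv_diff_mom",
            "cm_corr")
    return(stats::setNames(rep(NaN, length(nm)), nm))
  }
  Reduce(`+`, per) / length(per)
}

glrlmFeaturesOne <- function(cnt, nv) {
  ns <- sum(cnt)
  if (ns == 0) return(NULL)
  p <- cnt / ns
  jl <- col(p)
  rlev <- rowSums(cnt)
  rlen <- colSums(cnt)
  nz <- p > 0
  c(rlm_sre = sum(p / jl^2),
    rlm_lre = sum(p * jl^2),
    rlm_glnu = sum(rlev^2) / ns,
    rlm_rlnu = sum(rlen^2) / ns,
    rlm_r_perc = ns / nv,
    rlm_rl_entr = -sum(p[nz] * log2(p[nz])))
}

glrlmFeatures <- function(disc, nBins) {
  nv <- sum(!is.na(disc))
  mats <- .glrlmCounts(as.integer(disc), as.integer(dim(disc)),
                       as.integer(nBins))
  per <- Filter(Negate(is.null),
                lapply(mats, glrlmFeaturesOne, nv = nv))
  Reduce(`+`, per) / length(per)
}

#' Extract the radiomics feature vector from a pre-processed volume
#'
#' Computes the implemented feature subset for the base image and, where
#' defined, for the mean Laplacian-of-Gaussian response: 13 statistical, 2
#' local-intensity, 6 morphological, 7 intensity-histogram and 24 texture
#' features from the base image, plus the statistical and histogram
#' families on the LoG image (prefix \code{log_}).  Morphological and
#' texture features are structurally never emitted for the LoG image.
#'
#' @param vol base \linkS4class{ImageVolume} (isotropic, re-segmented mask).
#' @param mask \linkS4class{RoiMask} carrying morphological and intensity
#'   masks.
#' @param logVol optional LoG response \linkS4class{ImageVolume}; computed
#'   from \code{vol} via \code{\link{logFilterBank}} when NULL.
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return named numeric vector with a "metadata" attribute (data.frame:
#'   feature, family, image).
#' @examples
#' vol <- ImageVolume(array(40, c(8, 8, 8)))
#' msk <- RoiMask(array(TRUE, c(8, 8, 8)))
#' f <- extractFeatures(vol, msk)
#' f["morph_vol_dens_aabb"]  # cuboid fills its bounding box: 1
#' @export
extractFeatures <- function(vol, mask, logVol = NULL,
                            cfg = preprocessConfig()) {
  stopifnot(identical(dim(voxelArray(vol)), dim(morphMask(mask))))
  if (is.null(logVol)) logVol <- logFilterBank(vol, cfg$logSigmas)
  im <- intensityMask(mask)
  if (!any(im)) stop("empty intensity mask")
  base <- voxelArray(vol)[im]
  disc <- discretiseIntensities(vol, mask, cfg$nBins)
  out <- c(statFeatures(base),
           localIntensityFeatures(vol, mask),
           morphFeatures(mask),
           histFeatures(disc, cfg$nBins),
           glszmFeatures(disc),
           glcmFeatures(disc, cfg$nBins),
           glrlmFeatures(disc, cfg$nBins))
  # LoG image: statistical + histogram families only
  lvol <- logVol
  ldisc <- discretiseIntensities(lvol, mask, cfg$nBins)
  lfeat <- c(statFeatures(voxelArray(lvol)[im]),
             histFeatures(ldisc, cfg$nBins))
  names(lfeat) <- paste0("log_", names(lfeat))
  out <- c(out, lfeat)
  fam <- sub("^log_", "", names(out))
  fam <- sub("_.*$", "", fam)
  famMap <- c(stat = "statistical", loc = "local_intensity",
              morph = "morphological", ih = "intensity_histogram",
              szm = "texture", cm = "texture", rlm = "texture")
  attr(out, "metadata") <- data.frame(
    feature = names(out),
    family = unname(famMap[fam]),
    image = ifelse(grepl("^log_", names(out)), "log", "base"),
    row.names = NULL)
  out
}

#' Full pre-processing and extraction for one patient
#'
#' Resamples to the configured isotropic grid, applies HU re-segmentation,
#' builds the LoG response and extracts all features.
#'
#' @inheritParams extractFeatures
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return as \code{\link{extractFeatures}}.
#' @export
computePatientFeatures <- function(vol, mask, cfg = preprocessConfig()) {
  rs <- resampleIsotropic(vol, mask, cfg$targetSpacing)
  m2 <- resegmentIntensity(rs$volume, rs$mask, cfg$huWindow)
  lv <- logFilterBank(rs$volume, cfg$logSigmas)
  extractFeatures(rs$volume, m2, lv, cfg)
}

#' Feature table for a list of patients
#'
#' @param volumes named list of \linkS4class{ImageVolume}.
#' @param masks named list of \linkS4class{RoiMask} (same names).
#' @param cfg a \code{\link{preprocessConfig}}.
#' @return patients x features numeric matrix with metadata attribute.
#' @export
extractFeatureTable <- function(volumes, masks, cfg = preprocessConfig()) {
  stopifnot(identical(names(volumes), names(masks)))
  rows <- lapply(names(volumes), function(id)
    computePatientFeatures(volumes[[id]], masks[[id]], cfg))
  X <- do.call(rbind, rows)
  rownames(X) <- names(volumes)
  attr(X, "metadata") <- attr(rows[[1]], "metadata")
  X
}
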