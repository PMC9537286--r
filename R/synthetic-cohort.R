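# Synthetic paired image / expression / outcome cohorts with planted,
# recoverable structure.  All randomness flows from one root seed through
# named substreams so regeneration is byte-identical.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the emulated cohort: a 122/84
#' discovery/validation split, subtype prevalences of roughly 16/19/8/11
#' percent with the remainder unclassifiable, moderate expression noise and
#' an additive/multiplicative batch effect on the validation centre.
#'
#' @param nDiscovery,nValidation cohort sizes.
#' @param subtypeProportions named numeric(4) in [0,1]; the remainder up to
#'   1 is generated as unclassifiable 50/50 centroid mixtures.
#' @param noiseSdExpression per-gene Gaussian noise SD around centroids.
#' @param batchEffects named list per batch: list(shift=, scale=).
#' @param tumourShape boundary irregularity amplitude in [0,1].
#' @param tumourTexture grey-level heterogeneity amplitude in [0,1].
#' @param sizeRangeMm tumour diameter range (mm).
#' @param spacing acquisition voxel spacing (mm), CT-like anisotropic.
#' @param hazardCoefficients named map from planted risk factors to log
#'   hazard ratios; names: image_texture, volume, hedgehog, e2f_targets.
#' @param baselineRate exponential baseline event rate (per month).
#' @param censoringRate target fraction of censored patients in [0,1).
#' @param nGenes size of the synthetic gene universe.
#' @param images logical, materialise image volumes (slower) or only the
#'   expression/outcome layers.
#' @param seed root seed (integer).
#' @return list of class "CohortConfig".
#' @export
cohortConfig <- function(nDiscovery = 122L, nValidation = 84L,
                         subtypeProportions = c(atypical = 0.156,
                                                basal = 0.185,
                                                classical = 0.083,
                                                mesenchymal = 0.112),
                         noiseSdExpression = 0.25,
                         batchEffects = list(
                           disc = list(shift = 0, scale = 1),
                           val = list(shift = 0.8, scale = 1.2)),
                         tumourShape = 0.4, tumourTexture = 0.5,
                         sizeRangeMm = c(24, 44),
                         spacing = c(1, 1, 3),
                         hazardCoefficients = c(image_texture = 0.5,
                                                volume = 0.3,
                                                hedgehog = 0.5,
                                                e2f_targets = -0.4),
                         baselineRate = 0.02, censoringRate = 0.3,
                         nGenes = 500L, images = FALSE, seed = 1L) {
  stopifnot(nDiscovery > 0, nValidation > 0,
            all(subtypeProportions >= 0), sum(subtypeProportions) <= 1,
            noiseSdExpression >= 0, tumourShape >= 0, tumourShape <= 1,
            tumourTexture >= 0, tumourTexture <= 1,
            censoringRate >= 0, censoringRate < 1, baselineRate > 0)
  structure(as.list(environment()), class = "CohortConfig")
}

# low-order real spherical harmonics basis for boundary perturbation
sphHarmBasis <- function(theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cbind(3 * ct^2 - 1,
        st^2 * cos(2 * phi),
        st^2 * sin(2 * phi),
        st * ct * cos(phi),
        (5 * ct^3 - 3 * ct),
        st^3 * cos(3 * phi))
}

#' Generate one synthetic tumour volume and segmentation
#'
#' The tumour is a sphere whose boundary radius is perturbed by low-order
#' spherical harmonics (amplitude scaled by \code{shape}) filled with a
#' mean-40 HU Gaussian random field whose variance and correlation length
#' scale with \code{texture}.  Optional air-like (-800 HU) and bone-like
#' (1000 HU) inclusions exercise the HU re-segmentation window.
#'
#' @param shape boundary irregularity in [0,1]; 0 gives a discrete sphere.
#' @param texture grey-level heterogeneity in [0,1]; 0 gives a constant
#'   soft-tissue intensity.
#' @param sizeMm tumour diameter in mm.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param seed integer seed; identical seeds give identical arrays.
#' @param inclusions logical, embed the sub- -150 and supra-180 HU blobs.
#' @return list(volume = \linkS4class{ImageVolume},
#'   mask = \linkS4class{RoiMask}).
#' @export
generateTumourVolume <- function(shape, texture, sizeMm, spacing = c(1, 1, 1),
                                 seed = 1L, inclusions = TRUE) {
  if (sizeMm <= 0 || any(spacing <= 0))
    stop("sizing error: tumour size and voxel spacing must be positive")
  stopifnot(shape >= 0, shape <= 1, texture >= 0, texture <= 1)
  R <- sizeMm / 2
  ext <- sizeMm * 1.6
  d <- pmax(8L, as.integer(ceiling(ext / spacing)))
  ctr <- (d - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing[a] - ctr[a])
  X <- array(ax[[1]], d)
  Y <- array(rep(ax[[2]], each = d[1]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
  r <- sqrt(X^2 + Y^2 + Z^2)
  withSeed(deriveSeed(seed, "tumour-shape"), {
    coefs <- stats::rnorm(6)
    rot <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  })
  # evaluate the harmonics in a randomly rotated frame so the lobes are
  # generically misaligned with the axis-aligned bounding box
  Xr <- rot[1, 1] * X + rot[1, 2] * Y + rot[1, 3] * Z
  Yr <- rot[2, 1] * X + rot[2, 2] * Y + rot[2, 3] * Z
  Zr <- rot[3, 1] * X + rot[3, 2] * Y + rot[3, 3] * Z
  theta <- acos(ifelse(r > 0, Zr / pmax(r, 1e-9), 1))
  phi <- atan2(Yr, Xr)
  pert <- array(sphHarmBasis(as.numeric(theta), as.numeric(phi)) %*% coefs, d)
  pert <- pert / max(1e-9, stats::sd(as.numeric(pert)))
  rBound <- R * pmax(0.25, 1 + 0.3 * shape * pert)
  if (shape == 0) rBound <- array(R, d)
  m <- r <= rBound
  if (!any(m)) stop("sizing error: tumour smaller than one voxel")
  vox <- array(40, d)
  if (texture > 0) {
    withSeed(deriveSeed(seed, "tumour-texture"), {
      noise <- array(stats::rnorm(prod(d)), d)
    })
    # finer-grained (shorter-range) intensity structure as the
    # heterogeneity dial rises: more, smaller grey-level zones
    sigCorr <- 3.5 - 2.5 * texture                # mm correlation length
    sm <- as.numeric(noise)
    for (a in 1:3) {
      kern <- gaussKernel1d(sigCorr / spacing[a], 0L)
      sm <- .conv1dAxis(sm, as.integer(d), kern, a - 1L)
    }
    sm <- array(sm, d)
    sm <- (sm - mean(sm)) / stats::sd(as.numeric(sm))
    vox <- vox + 30 * texture * sm
  }
  if (inclusions) {
    rInc <- max(2 * max(spacing), R / 6)
    airC <- c(-R / 2.5, 0, 0)
    boneC <- c(R / 2.5, 0, 0)
    dAir <- sqrt((X - airC[1])^2 + (Y - airC[2])^2 + (Z - airC[3])^2)
    dBone <- sqrt((X - boneC[1])^2 + (Y - boneC[2])^2 + (Z - boneC[3])^2)
    vox[m & dAir <= rInc] <- -800
    vox[m & dBone <= rInc] <- 1000
  }
  list(volume = ImageVolume(vox, spacing),
       mask = RoiMask(m, spacing))
}

#' Synthetic subtype centroid profiles
#'
#' Independent standard-normal centroid profiles for the four molecular
#' subtypes, a stand-in for published centroid data (which this artifact
#' treats as an input file).
#'
#' @param nGenes number of centroid genes.
#' @param seed integer seed.
#' @return genes x 4 matrix with subtype column names.
#' @export
syntheticCentroids <- function(nGenes = 200L, seed = 1L) {
  withSeed(deriveSeed(seed, "centroids"), {
    m <- matrix(stats::rnorm(nGenes * 4), nGenes, 4)
  })
  rownames(m) <- sprintf("GENE%04d", seq_len(nGenes))
  colnames(m) <- c("atypical", "basal", "classical", "mesenchymal")
  m
}

#' Generate expression profiles around subtype centroids
#'
#' Sample s with subtype label k is centroid_k plus per-gene Gaussian noise;
#' "unclassified" samples are 50/50 mixtures of two random centroids.  A
#' per-batch additive shift and multiplicative scale is then applied.
#' Genes in \code{genes} but absent from the centroids are filled with
#' independent standard-normal noise.
#'
#' @param n number of samples.
#' @param centroids genes x subtypes matrix.
#' @param labels character(n), subtype names or "unclassified".
#' @param noiseSd Gaussian noise SD.
#' @param batchLabels optional character(n) batch per sample.
#' @param batchEffects named list per batch: list(shift=, scale=).
#' @param genes optional full gene universe (character).
#' @param sampleIds optional sample identifiers.
#' @param seed integer seed.
#' @return genes x samples matrix.
#' @export
generateExpression <- function(n, centroids, labels, noiseSd = 0.25,
                               batchLabels = NULL, batchEffects = NULL,
                               genes = NULL, sampleIds = NULL, seed = 1L) {
  if (length(labels) != n) stop("labels length must equal n")
  known <- c(colnames(centroids), "unclassified")
  if (!all(labels %in% known))
    stop("labels must name a centroid column or 'unclassified'")
  if (is.null(genes)) genes <- rownames(centroids)
  if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(n))
  p <- length(genes)
  shared <- intersect(genes, rownames(centroids))
  expr <- matrix(0, p, n, dimnames = list(genes, sampleIds))
  withSeed(deriveSeed(seed, "expression"), {
    for (s in seq_len(n)) {
      base <- stats::setNames(rep(0, p), genes)
      if (labels[s] == "unclassified") {
        pair <- sample(colnames(centroids), 2L)
        base[shared] <- 0.5 * (centroids[shared, pair[1]] +
                                 centroids[shared, pair[2]])
      } else {
        base[shared] <- centroids[shared, labels[s]]
      }
      extra <- setdiff(genes, shared)
      if (length(extra)) base[extra] <- stats::rnorm(length(extra))
      expr[, s] <- base + stats::rnorm(p, 0, noiseSd)
    }
  })
  if (!is.null(batchLabels)) {
    stopifnot(length(batchLabels) == n)
    for (b in unique(batchLabels)) {
      eff <- batchEffects[[b]] %||% list(shift = 0, scale = 1)
      sel <- batchLabels == b
      expr[, sel] <- expr[, sel] * eff$scale + eff$shift
    }
  }
  expr
}

#' Generate exponential survival outcomes from a linear Cox model
#'
#' Event times are exponential with rate
#' \code{baselineRate * exp(design \%*\% coefficients)}; censoring is an
#' independent uniform draw whose upper bound is calibrated by bisection so
#' the expected censored fraction matches \code{censoringRate}.
#'
#' @param design data.frame or matrix, patients x named features.
#' @param coefficients named numeric, log hazard ratios; all names must be
#'   design columns.
#' @param baselineRate positive baseline event rate.
#' @param censoringRate target censored fraction in [0,1).
#' @param seed integer seed.
#' @return data.frame(time, event, lp) with lp the true linear predictor.
#' @export
generateOutcomes <- function(design, coefficients, baselineRate = 0.02,
                             censoringRate = 0.3, seed = 1L) {
  if (baselineRate <= 0) stop("baselineRate must be positive")
  design <- as.data.frame(design)
  miss <- setdiff(names(coefficients), names(design))
  if (length(miss))
    stop("coefficients name features absent from the design: ",
         paste(miss, collapse = ", "))
  lp <- as.numeric(as.matrix(design[names(coefficients)]) %*% coefficients)
  rate <- baselineRate * exp(lp)
  withSeed(deriveSeed(seed, "outcomes"), {
    tEvent <- stats::rexp(length(rate), rate)
    if (censoringRate > 0) {
      censFrac <- function(cmax)
        mean((1 - exp(-rate * cmax)) / (rate * cmax))
      lo <- 1e-6; hi <- 1e7
      for (i in 1:200) {
        mid <- sqrt(lo * hi)
        # censored fraction decreases with the censoring-window width
        if (censFrac(mid) > censoringRate) lo <- mid else hi <- mid
      }
      cmax <- sqrt(lo * hi)
      tCens <- stats::runif(length(rate), 0, cmax)
    } else {
      tCens <- rep(Inf, length(rate))
    }
  })
  time <- pmin(tEvent, tCens)
  data.frame(time = pmax(time, 1e-8), event = as.integer(tEvent <= tCens),
             lp = lp)
}

#' Synthetic gene-set collection
#'
#' Hallmark-style gene sets over the synthetic gene universe, including the
#' hedgehog-signalling and E2F-target sets that carry planted survival
#' signal, six signature-style sets for the surrogate task and decoy sets.
#'
#' @param genes character gene universe.
#' @param seed integer seed.
#' @return named list of character vectors.
#' @export
syntheticGeneSets <- function(genes, seed = 1L) {
  withSeed(deriveSeed(seed, "gene-sets"), {
    pool <- sample(genes)
    sizes <- c(HALLMARK_HEDGEHOG_SIGNALING = 35L,
               HALLMARK_E2F_TARGETS = 60L,
               HALLMARK_HYPOXIA = 40L,
               HALLMARK_INFLAMMATORY_RESPONSE = 40L,
               SIG_DNA_REPAIR_7 = 7L, SIG_RADIOSENS_11 = 11L,
               SIG_IMMUNE_12 = 12L, SIG_HYPOXIA_15 = 15L,
               SIG_RADIOSENS_31 = 31L, SIG_EMT_42 = 42L)
    stopifnot(sum(sizes) <= length(pool))
    out <- list()
    off <- 0L
    for (nm in names(sizes)) {
      out[[nm]] <- sort(pool[(off + 1):(off + sizes[[nm]])])
      off <- off + sizes[[nm]]
    }
    out
  })
}

#' Generate a full paired synthetic cohort
#'
#' Draws subtype labels at the configured prevalences, expression around
#' synthetic centroids with batch effects, pathway activations added to the
#' hedgehog and E2F gene sets, per-patient tumour geometry/texture dials
#' and survival times from a ground-truth Cox model linking the image
#' texture, tumour volume and the two pathway activations to hazard.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \linkS4class{SyntheticCohort}; planted ground truth (labels,
#'   latent risk factors, linear predictor) sits in \code{cohortTruth()}.
#' @examples
#' cfg <- cohortConfig(nDiscovery = 10, nValidation = 6, images = FALSE)
#' coh <- generateCohort(cfg)
#' table(clinicalTable(coh)$split)
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$nDiscovery + config$nValidation
  ids <- sprintf("PT%04d", seq_len(n))
  split <- rep(c("discovery", "validation"),
               c(config$nDiscovery, config$nValidation))
  batch <- rep(names(config$batchEffects)[
    c(1, min(2, length(config$batchEffects)))],
    c(config$nDiscovery, config$nValidation))
  pr <- config$subtypeProportions
  withSeed(deriveSeed(config$seed, "labels"), {
    labels <- sample(c(names(pr), "unclassified"), n, replace = TRUE,
                     prob = c(pr, 1 - sum(pr)))
  })
  centroids <- syntheticCentroids(200L, config$seed)
  genes <- sprintf("GENE%04d", seq_len(max(config$nGenes, nrow(centroids))))
  expr <- generateExpression(n, centroids, labels,
                             noiseSd = config$noiseSdExpression,
                             batchLabels = batch,
                             batchEffects = config$batchEffects,
                             genes = genes, sampleIds = ids,
                             seed = config$seed)
  sets <- syntheticGeneSets(genes, config$seed)
  withSeed(deriveSeed(config$seed, "pathways"), {
    actHH <- stats::rnorm(n)
    actE2F <- stats::rnorm(n)
  })
  expr[sets$HALLMARK_HEDGEHOG_SIGNALING, ] <-
    expr[sets$HALLMARK_HEDGEHOG_SIGNALING, ] +
    matrix(0.6 * actHH, length(sets$HALLMARK_HEDGEHOG_SIGNALING), n,
           byrow = TRUE)
  expr[sets$HALLMARK_E2F_TARGETS, ] <-
    expr[sets$HALLMARK_E2F_TARGETS, ] +
    matrix(0.6 * actE2F, length(sets$HALLMARK_E2F_TARGETS), n, byrow = TRUE)
  withSeed(deriveSeed(config$seed, "geometry"), {
    texAmp <- stats::runif(n, pmax(0, config$tumourTexture - 0.3),
                           pmin(1, config$tumourTexture + 0.3))
    shpAmp <- stats::runif(n, pmax(0, config$tumourShape - 0.3),
                           pmin(1, config$tumourShape + 0.3))
    sizes <- stats::runif(n, config$sizeRangeMm[1], config$sizeRangeMm[2])
  })
  design <- data.frame(
    image_texture = as.numeric(scale(texAmp)),
    volume = as.numeric(scale(sizes^3)),
    hedgehog = actHH,
    e2f_targets = actE2F)
  outcome <- generateOutcomes(design, config$hazardCoefficients,
                              config$baselineRate, config$censoringRate,
                              seed = deriveSeed(config$seed, "surv"))
  volumes <- list(); masks <- list()
  if (isTRUE(config$images)) {
    for (i in seq_len(n)) {
      tv <- generateTumourVolume(shpAmp[i], texAmp[i], sizes[i],
                                 spacing = config$spacing,
                                 seed = deriveSeed(config$seed,
                                                   paste0("img", i)))
      volumes[[ids[i]]] <- tv$volume
      masks[[ids[i]]] <- tv$mask
    }
  }
  clin <- data.frame(id = ids, time_months = outcome$time,
                     event = outcome$event, batch = batch, split = split,
                     stringsAsFactors = FALSE)
  new("SyntheticCohort", volumes = volumes, masks = masks,
      expression = expr, clinical = clin,
      truth = list(subtype = stats::setNames(labels, ids),
                   linear_predictor = stats::setNames(outcome$lp, ids),
                   design = design,
                   hazard_coefficients = config$hazardCoefficients,
                   signature_class = lapply(sets[grep("^SIG_", names(sets))],
                                            function(g) NULL),
                   texture = stats::setNames(texAmp, ids),
                   shape = stats::setNames(shpAmp, ids),
                   size_mm = stats::setNames(sizes, ids),
                   gene_sets = sets),
      centroids = centroids)
}

#' Write a synthetic cohort to the on-disk pipeline layout
#'
#' Emits \code{images/<id>_ct.nii.gz}, \code{masks/<id>_gtv.nii.gz} (when
#' volumes were materialised), \code{expression.csv},
#' \code{clinical.csv}, \code{centroids.csv}, \code{gene_sets.gmt} and
#' \code{truth.json}.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (length(cohort@volumes)) {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (id in names(cohort@volumes)) {
      writeNiftiVolume(cohort@volumes[[id]],
                       file.path(dir, "images", paste0(id, "_ct.nii.gz")))
      m <- cohort@masks[[id]]
      writeNiftiVolume(ImageVolume(array(as.numeric(morphMask(m)),
                                         dim(morphMask(m))),
                                   voxelSpacing(m), volumeOrigin(m)),
                       file.path(dir, "masks", paste0(id, "_gtv.nii.gz")))
    }
  }
  ex <- cohort@expression
  utils::write.csv(data.frame(gene = rownames(ex), ex,
                              check.names = FALSE),
                   file.path(dir, "expression.csv"), row.names = FALSE)
  utils::write.csv(cohort@clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(gene = rownames(cohort@centroids),
                              cohort@centroids, check.names = FALSE),
                   file.path(dir, "centroids.csv"), row.names = FALSE)
  writeGmt(cohort@truth$gene_sets, file.path(dir, "gene_sets.gmt"))
  tr <- cohort@truth
  tr$design <- NULL
  tr$gene_sets <- NULL
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
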