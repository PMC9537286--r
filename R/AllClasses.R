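#' @useDynLib radiogenomix, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' ImageVolume: a 3D intensity grid with physical geometry
#'
#' Container for a scalar 3D image (CT intensities in Hounsfield units) on a
#' regular grid.  Geometry is carried as voxel spacing (mm) and the physical
#' position of the first voxel centre.
#'
#' @slot voxels 3D numeric array, column-major (x, y, z).
#' @slot spacing numeric(3), voxel spacing in mm, all positive.
#' @slot origin numeric(3), physical coordinate (mm) of voxel (1,1,1).
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("ImageVolume", function(object) {
  if (length(dim(object@voxels)) != 3L) return("voxels must be a 3D array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (any(!is.finite(object@voxels))) return("voxels must be finite")
  TRUE
})

#' Construct an ImageVolume
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical position of the first voxel centre (mm).
#' @return An \linkS4class{ImageVolume}.
#' @examples
#' vol <- ImageVolume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' voxelSpacing(vol)
#' @export
ImageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' RoiMask: tumour segmentation with morphological and intensity masks
#'
#' A binary segmentation congruent with its \linkS4class{ImageVolume}.  The
#' morphological mask is the delineated geometry and drives shape features;
#' the intensity mask is the subset surviving Hounsfield-unit re-segmentation
#' and drives intensity, histogram and texture features.  Until
#' \code{\link{resegmentIntensity}} is applied the two coincide.
#'
#' @slot morphology logical 3D array, the delineated region.
#' @slot intensity logical 3D array, voxels kept after HU re-segmentation.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot origin numeric(3) physical origin (mm).
#' @export
setClass("RoiMask",
  representation(morphology = "array", intensity = "array",
                 spacing = "numeric", origin = "numeric")
)

setValidity("RoiMask", function(object) {
  if (!identical(dim(object@morphology), dim(object@intensity)))
    return("morphology and intensity masks must share dimensions")
  if (!any(object@morphology)) return("morphological mask is empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  TRUE
})

#' Construct a RoiMask
#'
#' @param mask logical or 0/1 3D array delineating the region of interest.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) physical origin (mm).
#' @param intensity optional logical array for the intensity mask; defaults
#'   to \code{mask}.
#' @return A \linkS4class{RoiMask}.
#' @export
RoiMask <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                    intensity = NULL) {
  m <- array(as.logical(mask), dim(mask))
  if (is.null(intensity)) intensity <- m
  new("RoiMask", morphology = m,
      intensity = array(as.logical(intensity), dim(intensity)),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' @describeIn ImageVolume-class accessor for the voxel array
#' @param x an ImageVolume or RoiMask
#' @export
setGeneric("voxelArray", function(x) standardGeneric("voxelArray"))
#' @export
setMethod("voxelArray", "ImageVolume", function(x) x@voxels)

#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @export
setMethod("voxelSpacing", "RoiMask", function(x) x@spacing)

#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)
#' @export
setMethod("volumeOrigin", "RoiMask", function(x) x@origin)

#' Morphological (delineated) mask array
#' @param x a RoiMask
#' @export
setGeneric("morphMask", function(x) standardGeneric("morphMask"))
#' @export
setMethod("morphMask", "RoiMask", function(x) x@morphology)

#' Intensity mask array (after HU re-segmentation)
#' @param x a RoiMask
#' @export
setGeneric("intensityMask", function(x) standardGeneric("intensityMask"))
#' @export
setMethod("intensityMask", "RoiMask", function(x) x@intensity)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume %dx%dx%d voxels, spacing %.2fx%.2fx%.2f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f]\n", min(object@voxels),
              max(object@voxels)))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@morphology)
  cat(sprintf(
    "RoiMask %dx%dx%d, %d morphological / %d intensity voxels\n",
    d[1], d[2], d[3], sum(object@morphology), sum(object@intensity)))
})

#' FittedModel: a frozen classification or prognostic model
#'
#' Stores everything needed to apply a discovery-fitted model to new
#' patients: the ordered feature list, per-feature Yeo-Johnson and
#' z-transform parameters, coefficients (with an intercept for logistic
#' models; none for Cox), forced covariates, a classification cutoff or risk
#' stratification threshold, the Breslow baseline cumulative hazard for Cox
#' calibration, and selection provenance.
#'
#' @slot kind "logistic_ova" or "cox".
#' @slot features character, model features in design order.
#' @slot coefficients named numeric, per-feature coefficients (log scale for
#'   Cox, i.e. log hazard ratios).
#' @slot intercept numeric(1), logistic intercept (NA for Cox).
#' @slot transforms data.frame with columns feature, lambda, shift, scale.
#' @slot forced character, covariates always kept in the design.
#' @slot cutoff numeric(1), probability cutoff (logistic) or NA.
#' @slot threshold numeric(1), risk stratification threshold (Cox) or NA.
#' @slot baseline data.frame (time, cumhaz) Breslow baseline, possibly empty.
#' @slot stats data.frame of per-coefficient Wald statistics (se, ci, p).
#' @slot provenance list, e.g. CV ranking table and median selected size.
#' @export
setClass("FittedModel",
  representation(kind = "character", features = "character",
                 coefficients = "numeric", intercept = "numeric",
                 transforms = "data.frame", forced = "character",
                 cutoff = "numeric", threshold = "numeric",
                 baseline = "data.frame", stats = "data.frame",
                 provenance = "list")
)

setValidity("FittedModel", function(object) {
  if (!object@kind %in% c("logistic_ova", "cox"))
    return("kind must be 'logistic_ova' or 'cox'")
  if (!setequal(object@features, names(object@coefficients)))
    return("coefficients must be named by the model features")
  if (nrow(object@transforms) &&
      !all(object@features %in% object@transforms$feature))
    return("every feature needs transform parameters")
  if (nrow(object@transforms) && any(object@transforms$scale <= 0))
    return("z-scale must be positive")
  if (object@kind == "cox" && is.finite(object@intercept))
    return("a Cox model has no intercept")
  TRUE
})

setMethod("show", "FittedModel", function(object) {
  cat(sprintf("FittedModel <%s> with %d feature(s)\n", object@kind,
              length(object@features)))
  co <- object@coefficients
  if (object@kind == "cox") {
    df <- data.frame(coef = co, HR = exp(co))
  } else {
    df <- data.frame(coef = c(co, `(Intercept)` = object@intercept))
  }
  print(round(df, 3))
  if (is.finite(object@cutoff))
    cat(sprintf("  probability cutoff: %.3f\n", object@cutoff))
  if (is.finite(object@threshold))
    cat(sprintf("  risk threshold: %.3f\n", object@threshold))
})

#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))
#' @export
setMethod("modelFeatures", "FittedModel", function(x) x@features)

#' @export
setGeneric("modelCoefficients",
           function(x) standardGeneric("modelCoefficients"))
#' @export
setMethod("modelCoefficients", "FittedModel", function(x) x@coefficients)

#' Hazard ratios of a Cox FittedModel
#' @param x a FittedModel of kind "cox"
#' @export
setGeneric("hazardRatios", function(x) standardGeneric("hazardRatios"))
#' @export
setMethod("hazardRatios", "FittedModel", function(x) {
  stopifnot(x@kind == "cox")
  exp(x@coefficients)
})

#' SyntheticCohort: a paired image/expression/outcome cohort
#'
#' @slot volumes named list of ImageVolume (may be empty when images were
#'   not materialised).
#' @slot masks named list of RoiMask.
#' @slot expression genes x samples numeric matrix (log2 scale).
#' @slot clinical data.frame: id, time_months, event, batch, split.
#' @slot truth list of planted ground truth (labels, coefficients, linear
#'   predictors, signature classes).
#' @slot centroids genes x subtypes centroid matrix used for generation.
#' @export
setClass("SyntheticCohort",
  representation(volumes = "list", masks = "list", expression = "matrix",
                 clinical = "data.frame", truth = "list",
                 centroids = "matrix")
)

setValidity("SyntheticCohort", function(object) {
  cl <- object@clinical
  need <- c("id", "time_months", "event", "batch", "split")
  if (!all(need %in% names(cl)))
    return(paste("clinical table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(cl$id)) return("duplicate patient ids")
  if (!all(cl$event %in% c(0, 1))) return("event flag must be 0/1")
  if (any(cl$time_months <= 0)) return("times must be positive")
  if (ncol(object@expression) &&
      !identical(colnames(object@expression), cl$id))
    return("expression columns must match clinical ids")
  TRUE
})

setMethod("show", "SyntheticCohort", function(object) {
  cl <- object@clinical
  cat(sprintf(
    "SyntheticCohort: %d patients (%d discovery / %d validation)\n",
    nrow(cl), sum(cl$split == "discovery"), sum(cl$split == "validation")))
  cat(sprintf("  %d genes, %d image volumes, %d events\n",
              nrow(object@expression), length(object@volumes),
              sum(cl$event)))
})

#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @export
setMethod("clinicalTable", "SyntheticCohort", function(x) x@clinical)

#' @export
setGeneric("expressionMatrix",
           function(x) standardGeneric("expressionMatrix"))
#' @export
setMethod("expressionMatrix", "SyntheticCohort", function(x) x@expression)

#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
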