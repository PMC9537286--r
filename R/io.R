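# Readers and writers for the on-disk cohort layout: NIfTI volumes and
# masks, CSV matrices with strict headers, GMT gene sets.

#' Write an ImageVolume as NIfTI
#' @param vol an \linkS4class{ImageVolume}.
#' @param path output path (.nii or .nii.gz).
#' @export
writeNiftiVolume <- function(vol, path) {
  img <- RNifti::asNifti(voxelArray(vol))
  RNifti::pixdim(img) <- voxelSpacing(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an ImageVolume
#' @param path NIfTI path; spacing is taken from the header pixdim (mm).
#' @return an \linkS4class{ImageVolume}.
#' @export
readNiftiVolume <- function(path) {
  img <- RNifti::readNifti(path)
  ImageVolume(array(as.numeric(img), dim(img)[1:3]),
              spacing = RNifti::pixdim(img)[1:3])
}

#' Read an expression matrix from CSV
#'
#' Expects a "gene" column followed by one column per sample; duplicate
#' gene symbols or sample ids are rejected, as are missing values.
#'
#' @param path CSV path.
#' @return genes x samples numeric matrix.
#' @export
readExpressionCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "gene") stop("expression CSV must start with 'gene'")
  if (anyDuplicated(df$gene)) stop("duplicate gene symbols")
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  if (anyNA(m)) stop("missing values in expression matrix")
  m
}

#' Read the clinical/outcome table from CSV
#' @param path CSV with columns id, time_months, event, batch, split.
#' @return validated data.frame.
#' @export
readClinicalCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "time_months", "event", "batch", "split")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical CSV lacks: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate patient ids")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0/1")
  df
}

#' Read subtype centroid profiles from CSV
#' @param path CSV with columns gene, atypical, basal, classical,
#'   mesenchymal.
#' @return genes x 4 matrix.
#' @export
readCentroidsCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("gene", "atypical", "basal", "classical", "mesenchymal")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("centroid CSV lacks: ", paste(miss, collapse = ", "))
  m <- as.matrix(df[need[-1]])
  rownames(m) <- df$gene
  m
}

#' Read a written cohort directory back into memory
#'
#' Reads the layout written by \code{\link{writeCohort}}; NIfTI geometry
#' is validated against its mask.
#'
#' @param dir cohort directory.
#' @param images read image volumes too (default TRUE when present).
#' @return a \linkS4class{SyntheticCohort}.
#' @export
readCohort <- function(dir, images = TRUE) {
  clin <- readClinicalCsv(file.path(dir, "clinical.csv"))
  expr <- readExpressionCsv(file.path(dir, "expression.csv"))
  centroids <- readCentroidsCsv(file.path(dir, "centroids.csv"))
  sets <- if (file.exists(file.path(dir, "gene_sets.gmt")))
    readGmt(file.path(dir, "gene_sets.gmt")) else list()
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath))
    jsonlite::read_json(truthPath, simplifyVector = TRUE) else list()
  truth$gene_sets <- sets
  volumes <- list(); masks <- list()
  if (images && dir.exists(file.path(dir, "images"))) {
    for (id in clin$id) {
      ip <- file.path(dir, "images", paste0(id, "_ct.nii.gz"))
      mp <- file.path(dir, "masks", paste0(id, "_gtv.nii.gz"))
      if (!file.exists(ip)) next
      v <- readNiftiVolume(ip)
      m <- readNiftiVolume(mp)
      if (!identical(dim(voxelArray(v)), dim(voxelArray(m))) ||
          max(abs(voxelSpacing(v) - voxelSpacing(m))) > 1e-6)
        stop("volume/mask grid mismatch for ", id, ": volume ",
             paste(dim(voxelArray(v)), collapse = "x"), " @ ",
             paste(voxelSpacing(v), collapse = "/"), " vs mask ",
             paste(dim(voxelArray(m)), collapse = "x"), " @ ",
             paste(voxelSpacing(m), collapse = "/"))
      volumes[[id]] <- v
      masks[[id]] <- RoiMask(voxelArray(m) >= 0.5, voxelSpacing(m))
    }
  }
  new("SyntheticCohort", volumes = volumes, masks = masks,
      expression = expr, clinical = clin, truth = as.list(truth),
      centroids = centroids)
}

#' Write a feature table with its metadata
#' @param features patients x features matrix with optional metadata
#'   attribute.
#' @param dir output directory.
#' @export
writeFeatureTable <- function(features, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(id = rownames(features), features,
                              check.names = FALSE),
                   file.path(dir, "features.csv"), row.names = FALSE)
  md <- attr(features, "metadata")
  if (!is.null(md))
    jsonlite::write_json(md, file.path(dir, "feature_metadata.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#' @param dir directory holding features.csv.
#' @return patients x features matrix.
#' @export
readFeatureTable <- function(dir) {
  df <- utils::read.csv(file.path(dir, "features.csv"),
                        check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  mdPath <- file.path(dir, "feature_metadata.json")
  if (file.exists(mdPath))
    attr(m, "metadata") <- jsonlite::read_json(mdPath,
                                               simplifyVector = TRUE)
  m
}
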