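# Consensus-cluster-guided reference selection and reference-batch ComBat.

#' Identify a reference patient cluster by consensus clustering
#'
#' Z-scores the statistical / intensity-histogram / texture features, takes
#' principal components up to 90 percent cumulative variance, and runs
#' subsampled hierarchical consensus clustering for each cluster number k.
#' The reference set is the largest group of patients that stay pairwise
#' co-assigned (same final cluster) at every k; the remainder are outliers
#' to be ComBat-aligned to the reference.
#'
#' @param features patients x features numeric matrix (already restricted
#'   to the intended families).
#' @param kRange integer cluster numbers to scan (default 2:6).
#' @param nResamples subsampling iterations per k (default 100).
#' @param subsampleFrac fraction of patients per resample (default 0.8).
#' @param seed integer seed.
#' @return list(reference, outliers, partitions, consensus) where
#'   partitions is a patients x k matrix of final cluster labels.
#' @export
referenceCluster <- function(features, kRange = 2:6, nResamples = 100L,
                             subsampleFrac = 0.8, seed = 1L) {
  X <- as.matrix(features)
  if (nrow(X) < 3L) stop("need at least 3 patients")
  sds <- apply(X, 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  ncomp <- max(1L, which(cum >= 0.90)[1])
  S <- pc$x[, seq_len(ncomp), drop = FALSE]
  n <- nrow(S)
  ids <- rownames(X) %||% sprintf("P%03d", seq_len(n))
  partitions <- matrix(NA_integer_, n, length(kRange),
                       dimnames = list(ids, paste0("k", kRange)))
  consensus <- list()
  withSeed(deriveSeed(seed, "consensus"), {
    for (ki in seq_along(kRange)) {
      k <- kRange[ki]
      hits <- matrix(0, n, n)
      both <- matrix(0, n, n)
      for (r in seq_len(nResamples)) {
        sub <- sort(sample(n, max(k + 1L, floor(subsampleFrac * n))))
        cl <- stats::cutree(stats::hclust(stats::dist(S[sub, , drop = FALSE]),
                                          method = "complete"), k)
        same <- outer(cl, cl, `==`)
        hits[sub, sub] <- hits[sub, sub] + same
        both[sub, sub] <- both[sub, sub] + 1
      }
      C <- ifelse(both > 0, hits / both, 0)
      diag(C) <- 1
      fin <- stats::cutree(stats::hclust(stats::as.dist(1 - C),
                                         method = "complete"), k)
      partitions[, ki] <- fin
      consensus[[paste0("k", k)]] <- C
    }
  })
  # no-structure guard: when clustering is ambiguous at every k (high
  # proportion of ambiguous consensus entries), the cohort is one stable
  # group and nobody is an outlier
  pac <- vapply(consensus, function(C) {
    off <- C[upper.tri(C)]
    mean(off > 0.1 & off < 0.9)
  }, numeric(1))
  if (min(pac) > 0.35)
    return(list(reference = ids, outliers = character(0),
                partitions = partitions, consensus = consensus))
  key <- apply(partitions, 1, paste, collapse = "|")
  tab <- table(factor(key, levels = unique(key)))   # ties: first occurrence
  refKey <- names(tab)[which.max(tab)]
  reference <- ids[key == refKey]
  if (length(reference) < 2L)
    stop("no stable patient set of size >= 2 found; supply a manual ",
         "reference batch")
  list(reference = reference, outliers = setdiff(ids, reference),
       partitions = partitions, consensus = consensus)
}

#' Reference-batch ComBat harmonisation
#'
#' Location/scale empirical-Bayes batch correction with a reference batch:
#' all batches are aligned to the reference, which is returned unchanged.
#' The nonparametric prior follows the original empirical-Bayes weighting;
#' the parametric mode uses normal / inverse-gamma priors.  Features with
#' zero variance inside any batch are passed through unadjusted with a
#' warning.  The same core serves imaging feature tables and expression
#' matrices (transpose accordingly).
#'
#' @param features patients x features numeric matrix.
#' @param batch character/factor batch label per patient.
#' @param referenceBatch the batch to hold fixed.
#' @param mode "nonparametric" (default) or "parametric".
#' @return adjusted matrix, same shape and dimnames.
#' @export
combatAdjust <- function(features, batch, referenceBatch,
                         mode = c("nonparametric", "parametric")) {
  mode <- match.arg(mode)
  X <- as.matrix(features)
  batch <- as.character(batch)
  stopifnot(length(batch) == nrow(X))
  if (!referenceBatch %in% batch) stop("reference batch not present")
  if (any(table(batch) < 2L)) stop("each batch needs >= 2 members")
  if (length(unique(batch)) < 2L) return(X)
  # zero within-batch variance breaks the scale model: pass through
  wv <- apply(X, 2, function(col)
    min(tapply(col, batch, stats::var)))
  skip <- which(wv <= 0 | !is.finite(wv))
  if (length(skip))
    warning("passing through ", length(skip),
            " feature(s) with zero within-batch variance")
  keep <- setdiff(seq_len(ncol(X)), skip)
  out <- X
  if (length(keep)) {
    dat <- t(X[, keep, drop = FALSE])    # features x samples
    adj <- sva::ComBat(dat = dat, batch = batch,
                       par.prior = (mode == "parametric"),
                       ref.batch = referenceBatch)
    out[, keep] <- t(adj)
  }
  out
}
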