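# Expression-side computations: nearest-centroid molecular subtyping,
# k-means gene-signature classes with leak-free transfer, and gene-set
# variation (GSVA-style) metagene scoring.

#' Assign molecular subtypes by centroid correlation
#'
#' Restricts expression and centroids to shared genes, median-centres each
#' sample over those genes, computes the Pearson correlation with each
#' subtype centroid and applies the classification rule: a sample is
#' unclassified when its largest correlation is below 0.2 or when the gap
#' between the two highest correlations is 0.2 or less.
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param centroids genes x subtypes centroid matrix.
#' @return data.frame with one row per sample: the four correlations and
#'   the assigned \code{label}.
#' @export
assignSubtypes <- function(expr, centroids) {
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < 2L) stop("need >= 2 genes shared with the centroids")
  E <- expr[shared, , drop = FALSE]
  C <- centroids[shared, , drop = FALSE]
  E <- sweep(E, 2, apply(E, 2, stats::median))
  labs <- colnames(C)
  cors <- matrix(NA_real_, ncol(E), length(labs),
                 dimnames = list(colnames(E), labs))
  for (s in seq_len(ncol(E))) {
    x <- E[, s]
    if (stats::sd(x) == 0) next          # constant profile: unclassified
    cors[s, ] <- apply(C, 2, stats::cor, y = x)
  }
  label <- apply(cors, 1, function(r) {
    if (anyNA(r)) return("unclassified")
    o <- order(r, decreasing = TRUE)
    if (r[o[1]] < 0.2 || (r[o[1]] - r[o[2]]) <= 0.2) "unclassified"
    else labs[o[1]]
  })
  out <- data.frame(cors, label = label, check.names = FALSE)
  out$flag_constant <- apply(cors, 1, anyNA)
  out
}

#' Binary gene-signature classes via k-means, with centroid transfer
#'
#' In \code{fit} mode the discovery samples are clustered into two classes
#' by k-means on the per-gene z-scored signature expression (10 restarts,
#' best inertia); classes are relabelled so class 1 has the higher mean
#' signature expression, and the z-parameters and class centroids are
#' stored.  In \code{transfer} mode the stored parameters are applied and
#' each sample is assigned to the nearest stored centroid by Euclidean
#' distance (ties to the lower-indexed centroid).
#'
#' @param expr genes x samples matrix.
#' @param signature character vector of signature genes (missing genes are
#'   dropped with a warning).
#' @param mode "fit" or "transfer".
#' @param fitted the object returned by a previous \code{fit} call
#'   (required for transfer).
#' @param seed seed for the k-means restarts.
#' @return list(labels, centroids, zCenter, zScale, genes).
#' @export
signatureClasses <- function(expr, signature, mode = c("fit", "transfer"),
                             fitted = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "fit") {
    genes <- intersect(signature, rownames(expr))
    if (length(genes) < length(signature))
      warning(length(signature) - length(genes),
              " signature gene(s) absent from the expression matrix")
    if (length(genes) < 1L) stop("no signature genes measured")
    X <- t(expr[genes, , drop = FALSE])   # samples x genes
    if (ncol(X) < 1L || nrow(X) < 2L) stop("need >= 2 samples to fit")
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0] <- 1
    Z <- scale(X, center = ctr, scale = scl)
    if (all(stats::dist(Z) < 1e-12)) stop("k-means degenerate: all ",
                                          "samples identical")
    km <- withSeed(deriveSeed(seed, "kmeans"),
                   stats::kmeans(Z, centers = 2L, nstart = 10L))
    meanExpr <- tapply(rowMeans(X), km$cluster, mean)
    ord <- order(meanExpr, decreasing = TRUE)   # class 1 = higher expression
    relab <- match(km$cluster, ord)
    centroids <- km$centers[ord, , drop = FALSE]
    rownames(centroids) <- c("1", "2")
    list(labels = stats::setNames(relab, rownames(X)),
         centroids = centroids, zCenter = ctr, zScale = scl, genes = genes)
  } else {
    if (is.null(fitted)) stop("transfer mode needs the fitted object")
    genes <- fitted$genes
    if (!all(genes %in% rownames(expr)))
      stop("transfer expression matrix lacks fitted signature genes")
    Z <- scale(t(expr[genes, , drop = FALSE]), center = fitted$zCenter,
               scale = fitted$zScale)
    d <- sapply(seq_len(nrow(fitted$centroids)), function(ci)
      rowSums(sweep(Z, 2, fitted$centroids[ci, ])^2))
    labels <- apply(d, 1, which.min)            # ties -> lower index
    list(labels = stats::setNames(labels, colnames(expr)),
         centroids = fitted$centroids, zCenter = fitted$zCenter,
         zScale = fitted$zScale, genes = genes)
  }
}

#' Gene-set variation scores (per-sample enrichment)
#'
#' Per-gene kernel-CDF statistics (Gaussian kernel, bandwidth = gene SD/4;
#' zero-SD genes dropped), per-sample decreasing rank with symmetric rank
#' weight |rank - (p+1)/2|, and a weighted Kolmogorov-style random walk
#' (weight exponent tau = 1).  The enrichment score is the signed maximum
#' deviation from zero of the running sum.  Compute cohorts separately to
#' avoid information leakage; this function never pools across calls.
#'
#' @param expr genes x samples matrix, >= 3 samples.
#' @param geneSets named list of gene vectors; sets with fewer than 2
#'   measured genes are skipped with a warning.
#' @param tau rank-weight exponent (default 1).
#' @return samples x gene-sets matrix of scores in [-1, 1].
#' @export
gsvaScores <- function(expr, geneSets, tau = 1) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  sds <- apply(expr, 1, stats::sd)
  keep <- sds > 0
  expr <- expr[keep, , drop = FALSE]
  sds <- sds[keep]
  p <- nrow(expr); n <- ncol(expr)
  # kernel CDF statistic per gene/sample
  z <- matrix(0, p, n, dimnames = dimnames(expr))
  for (i in seq_len(p)) {
    xi <- expr[i, ]
    h <- sds[i] / 4
    z[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, `-`) / h))
  }
  out <- matrix(NA_real_, n, 0, dimnames = list(colnames(expr), NULL))
  for (nm in names(geneSets)) {
    set <- intersect(unique(geneSets[[nm]]), rownames(expr))
    if (length(set) < 2L) {
      warning("gene set ", nm, " has < 2 measured genes; skipped")
      next
    }
    m <- length(set)
    inSet <- rownames(expr) %in% set
    score <- numeric(n)
    for (s in seq_len(n)) {
      ord <- order(z[, s], decreasing = TRUE)   # stable: ties by gene order
      w <- abs(seq_len(p) - (p + 1) / 2)        # weight of rank position
      inOrd <- inSet[ord]
      wIn <- (w * inOrd)^tau * inOrd
      stepUp <- wIn / sum(w[inOrd]^tau)
      stepDn <- (!inOrd) / (p - m)
      walk <- cumsum(stepUp - stepDn)
      score[s] <- walk[which.max(abs(walk))]
    }
    out <- cbind(out, score)
    colnames(out)[ncol(out)] <- nm
  }
  out
}

#' Subset a gene-set collection by a keep list
#'
#' Stands in for the manual literature filtering of pathway collections:
#' the decision is a configuration list, applied in keep-list order.
#'
#' @param sets named list of gene sets.
#' @param keep character, names to retain (order preserved).
#' @return the filtered list.
#' @export
filterGeneSets <- function(sets, keep) {
  if (!length(keep)) stop("keep list must be nonempty")
  miss <- setdiff(keep, names(sets))
  if (length(miss)) {
    near <- vapply(miss, function(m) {
      d <- utils::adist(m, names(sets))
      names(sets)[which.min(d)]
    }, character(1))
    stop("unknown gene set(s): ", paste(miss, collapse = ", "),
         "; nearest available: ", paste(unique(near), collapse = ", "),
         "; available: ", paste(names(sets), collapse = ", "))
  }
  sets[keep]
}

#' Read gene sets from a GMT file
#'
#' Tab-separated lines: name, description, genes.  Lines with fewer than
#' two genes are rejected with their line number.
#'
#' @param path GMT file path.
#' @return named list of character gene vectors (duplicates removed).
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L)
      stop("GMT line ", i, " has fewer than 2 genes")
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of gene vectors.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
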