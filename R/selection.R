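# Redundancy clustering, MRMR ranking and Borda aggregation under repeated
# cross-validation.

#' Cluster redundant features and pick representatives
#'
#' Complete-linkage hierarchical clustering on D = 1 - |Spearman rho|, cut
#' at the given height.  The representative of each cluster is the feature
#' with the highest mean absolute Spearman correlation to its co-members
#' (singletons represent themselves); ties break by feature-name order.
#'
#' @param features patients x features matrix; zero-variance features are
#'   dropped with a warning.
#' @param threshold dendrogram cut height on 1 - |rho| (default 0.3).
#' @return list(representatives, clusters) with clusters a named integer
#'   vector of cluster ids per feature.
#' @export
clusterRepresentatives <- function(features, threshold = 0.3) {
  X <- as.matrix(features)
  if (!ncol(X)) stop("empty feature table")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance feature(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) == 1L)
    return(list(representatives = colnames(X),
                clusters = stats::setNames(1L, colnames(X))))
  rho <- stats::cor(X, method = "spearman")
  D <- 1 - abs(rho)
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  cl <- stats::cutree(hc, h = threshold)
  reps <- vapply(sort(unique(cl)), function(k) {
    members <- sort(names(cl)[cl == k])
    if (length(members) == 1L) return(members)
    score <- vapply(members, function(f)
      mean(abs(rho[f, setdiff(members, f)])), numeric(1))
    members[which.max(score)]          # ties: first in name order
  }, character(1))
  list(representatives = unname(reps), clusters = cl)
}

#' Discard features correlated with tumour volume
#'
#' Pre-filter for the prognostic radiomics signature: features with an
#' absolute Spearman correlation above the threshold with the volume are
#' discarded (the volume itself is forced into the model separately).
#'
#' @param features patients x features matrix.
#' @param volume numeric vector of tumour volumes.
#' @param threshold absolute Spearman cutoff (default 0.5).
#' @return character vector of retained feature names.
#' @export
volumeCorrelationFilter <- function(features, volume, threshold = 0.5) {
  X <- as.matrix(features)
  rho <- apply(X, 2, stats::cor, y = volume, method = "spearman")
  colnames(X)[is.na(rho) | abs(rho) <= threshold]
}

mrmrPrepareY <- function(y) {
  if (is.numeric(y) && length(unique(y)) > 8L) equalFreqBins(y, 4L)
  else as.integer(factor(y))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy MRMR with the quotient criterion: the next feature maximises
#' relevance(f; y) / mean redundancy(f; selected), both mutual information
#' with 4-bin equal-frequency discretisation of continuous variables.
#' Ties break deterministically by feature-name order.
#'
#' @param X patients x features matrix.
#' @param y class labels (factor-like) or a binary target; for survival
#'   endpoints pass the event indicator at the analysis horizon (see
#'   \code{\link{survivalTargetAtHorizon}}).
#' @param nSelect number of features to rank (truncated with a warning if
#'   larger than available).
#' @return character vector, features in selection order.
#' @export
mrmrRank <- function(X, y, nSelect = ncol(X)) {
  X <- as.matrix(X)
  if (ncol(X) < 1L) stop("need at least one feature")
  if (nSelect > ncol(X)) {
    warning("nSelect truncated to ", ncol(X))
    nSelect <- ncol(X)
  }
  ord <- order(colnames(X))
  X <- X[, ord, drop = FALSE]            # name order resolves ties
  yd <- mrmrPrepareY(y)
  D <- apply(X, 2, equalFreqBins, nBins = 4L)
  rel <- apply(D, 2, mutualInfo, b = yd)
  feats <- colnames(X)
  sel <- character(0)
  avail <- feats
  redCache <- matrix(NA_real_, ncol(X), ncol(X),
                     dimnames = list(feats, feats))
  while (length(sel) < nSelect) {
    if (!length(sel)) {
      pick <- avail[which.max(rel[avail])]
    } else {
      score <- vapply(avail, function(f) {
        red <- vapply(sel, function(s) {
          if (is.na(redCache[f, s]))
            redCache[f, s] <<- mutualInfo(D[, f], D[, s])
          redCache[f, s]
        }, numeric(1))
        rel[f] / max(mean(red), 1e-12)
      }, numeric(1))
      pick <- avail[which.max(score)]
    }
    sel <- c(sel, pick)
    avail <- setdiff(avail, pick)
  }
  sel
}

#' Event indicator at a fixed horizon for survival feature ranking
#'
#' Patients censored before the horizon without an event are excluded
#' (status unknown); events before the horizon are 1, patients at risk
#' beyond it are 0.
#'
#' @param time event/censoring times.
#' @param event 0/1 event indicator.
#' @param horizon analysis horizon (default 24 months).
#' @return list(y, keep) with y the indicator on the kept patients.
#' @export
survivalTargetAtHorizon <- function(time, event, horizon = 24) {
  keep <- !(time < horizon & event == 0)
  list(y = as.integer(time <= horizon & event == 1)[keep], keep = keep)
}

innerCvScore <- function(X, y, time = NULL, event = NULL, size, folds = 3L,
                         task = "classification", seed = 1L) {
  n <- nrow(X)
  idx <- makeStratifiedFolds(if (task == "classification") y else event,
                             folds, seed)
  scores <- numeric(0)
  for (f in seq_len(folds)) {
    tr <- idx != f; te <- idx == f
    feats <- colnames(X)[seq_len(min(size, ncol(X)))]
    if (task == "classification") {
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) next
      fit <- ridgeLogisticIrls(X[tr, feats, drop = FALSE], y[tr],
                               penalty = 1e-6)
      pr <- stats::plogis(cbind(1, X[te, feats, drop = FALSE]) %*% fit$beta)
      scores <- c(scores, aucRank(pr, y[te]))
    } else {
      if (sum(event[tr]) < 2L || sum(event[te]) < 1L) next
      df <- data.frame(X[tr, feats, drop = FALSE])
      fit <- tryCatch(
        survival::coxph(survival::Surv(time[tr], event[tr]) ~ .,
                        data = df, ties = "efron"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      lp <- as.matrix(data.frame(X[te, feats, drop = FALSE])) %*%
        stats::coef(fit)
      cc <- survival::concordance(
        survival::Surv(time[te], event[te]) ~ lp, reverse = TRUE)
      scores <- c(scores, cc$concordance)
    }
  }
  if (!length(scores)) return(NA_real_)
  mean(scores)
}

makeStratifiedFolds <- function(strata, folds, seed) {
  n <- length(strata)
  idx <- integer(n)
  withSeed(seed, {
    for (g in unique(strata)) {
      sel <- which(strata == g)
      idx[sel] <- sample(rep_len(seq_len(folds), length(sel)))
    }
  })
  idx
}

#' Repeated-CV MRMR ranking with enhanced Borda aggregation
#'
#' Within each of reps x folds cross-validation folds the training part is
#' MRMR-ranked and an inner-CV search picks the per-fold model size.  The
#' enhanced Borda score of feature f is the occurrence-weighted normalised
#' Borda sum: sum over folds selecting f of (M_fold - rank + 1)/M_fold,
#' divided by the total number of folds.  The final model size is the
#' median per-fold size (rounded half up, minimum 1).
#'
#' @param X patients x features matrix (transformed scale).
#' @param y class labels (classification) or NULL for survival.
#' @param time,event survival endpoint (task = "survival").
#' @param task "classification" or "survival".
#' @param reps,folds repetitions and folds (defaults 33 x 3).
#' @param sMax largest model size scanned (default min(10, p)).
#' @param horizon survival ranking horizon in months.
#' @param seed integer seed; fixed seed gives identical tables.
#' @return list(ranking, medianSize) where ranking is a data.frame
#'   (feature, occurrence, borda, final_rank) sorted by final rank.
#' @export
cvRankAggregate <- function(X, y = NULL, time = NULL, event = NULL,
                            task = c("classification", "survival"),
                            reps = 33L, folds = 3L, sMax = NULL,
                            horizon = 24, seed = 1L) {
  task <- match.arg(task)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L * folds) stop("need at least ", 3L * folds, " patients")
  if (is.null(sMax)) sMax <- min(10L, ncol(X))
  feats <- colnames(X)
  borda <- stats::setNames(numeric(length(feats)), feats)
  occ <- stats::setNames(integer(length(feats)), feats)
  sizes <- integer(0)
  nFolds <- 0L
  strata <- if (task == "classification") y else event
  for (r in seq_len(reps)) {
    foldIdx <- makeStratifiedFolds(strata, folds,
                                   deriveSeed(seed, paste0("rep", r)))
    for (f in seq_len(folds)) {
      tr <- which(foldIdx != f)
      if (task == "classification" && length(unique(y[tr])) < 2L) next
      nFolds <- nFolds + 1L
      if (task == "classification") {
        yTr <- y[tr]
        rk <- mrmrRank(X[tr, , drop = FALSE], yTr, nSelect = sMax)
      } else {
        tgt <- survivalTargetAtHorizon(time[tr], event[tr], horizon)
        rk <- mrmrRank(X[tr, , drop = FALSE][tgt$keep, , drop = FALSE],
                       tgt$y, nSelect = sMax)
      }
      Xrk <- X[tr, rk, drop = FALSE]
      sc <- vapply(seq_along(rk), function(s)
        innerCvScore(Xrk, if (task == "classification") y[tr] else NULL,
                     time[tr], event[tr], size = s, task = task,
                     seed = deriveSeed(seed, paste0("inner", r, "_", f))),
        numeric(1))
      size <- if (all(is.na(sc))) 1L else which.max(sc)   # ties: smaller
      sizes <- c(sizes, size)
      mFold <- size
      selected <- rk[seq_len(size)]
      borda[selected] <- borda[selected] +
        (mFold - seq_len(size) + 1) / mFold
      occ[selected] <- occ[selected] + 1L
    }
  }
  borda <- borda / max(nFolds, 1L)
  ord <- order(-borda, feats)
  ranking <- data.frame(feature = feats[ord], occurrence = occ[ord],
                        borda = borda[ord],
                        final_rank = seq_along(feats), row.names = NULL)
  attr(ranking, "n_folds") <- nFolds
  list(ranking = ranking,
       medianSize = max(1L, as.integer(roundHalfUp(stats::median(sizes)))))
}
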