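# Final model fitting: ridge-penalised one-versus-all logistic regression
# (iteratively reweighted least squares) and Cox proportional hazards
# (partial likelihood, Efron ties, via the survival package), plus the
# FittedModel constructor, prediction and JSON persistence.

aucRank <- function(scores, labels) {
  y <- as.integer(labels == sort(unique(labels))[length(unique(labels))])
  if (is.logical(labels)) y <- as.integer(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) y <- labels
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)                      # mid-ranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

ridgeLogisticIrls <- function(X, y, penalty = 0, maxIter = 50L,
                              tol = 1e-9) {
  X <- as.matrix(X)
  yb <- if (is.logical(y)) as.numeric(y) else
    as.numeric(y == sort(unique(y))[length(unique(y))])
  if (is.numeric(y) && all(y %in% c(0, 1))) yb <- as.numeric(y)
  Xd <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xd)
  pen <- diag(c(0, rep(penalty, p - 1)), p)    # intercept unpenalised
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- as.numeric(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (yb - mu) / w
    A <- crossprod(Xd, w * Xd) + pen
    betaNew <- solve(A, crossprod(Xd, w * z))
    if (max(abs(betaNew - beta)) < tol) {
      beta <- betaNew
      converged <- TRUE
      break
    }
    beta <- betaNew
  }
  beta <- as.numeric(beta)
  names(beta) <- colnames(Xd)
  eta <- as.numeric(Xd %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  cov <- solve(crossprod(Xd, w * Xd) + pen)
  list(beta = beta, se = sqrt(diag(cov)), converged = converged,
       separated = !converged || max(abs(beta[-1])) > 30)
}

#' Construct a FittedModel from explicit parameters
#'
#' Also the entry point for applying published model tables: build the
#' model from printed coefficients and transform parameters, then use
#' \code{\link{predictModel}}.
#'
#' @param kind "logistic_ova" or "cox".
#' @param coefficients named numeric feature coefficients.
#' @param intercept logistic intercept (ignored for Cox).
#' @param transforms data.frame(feature, lambda, shift, scale) or NULL for
#'   identity.
#' @param forced forced covariate names.
#' @param cutoff,threshold stored decision parameters.
#' @param baseline Breslow baseline data.frame(time, cumhaz).
#' @param stats per-coefficient Wald table.
#' @param provenance free-form list.
#' @return a \linkS4class{FittedModel}.
#' @examples
#' tab <- data.frame(feature = c("morph_vol_dens_aabb", "szm_glnu"),
#'                   lambda = c(-0.5, 0), shift = c(0.246, 4.190),
#'                   scale = c(0.046, 0.669))
#' m <- fittedModel("logistic_ova",
#'                  c(morph_vol_dens_aabb = 0.114, szm_glnu = -0.545),
#'                  intercept = -0.968, transforms = tab)
#' @export
fittedModel <- function(kind, coefficients, intercept = NA_real_,
                        transforms = NULL, forced = character(),
                        cutoff = NA_real_, threshold = NA_real_,
                        baseline = NULL, stats = NULL,
                        provenance = list()) {
  if (is.null(transforms))
    transforms <- data.frame(feature = character(), lambda = numeric(),
                             shift = numeric(), scale = numeric())
  transforms <- as.data.frame(transforms)
  class(transforms) <- "data.frame"
  if (is.null(baseline))
    baseline <- data.frame(time = numeric(), cumhaz = numeric())
  if (is.null(stats))
    stats <- data.frame()
  if (kind == "cox") intercept <- NA_real_
  new("FittedModel", kind = kind, features = names(coefficients),
      coefficients = coefficients, intercept = intercept,
      transforms = transforms, forced = forced, cutoff = cutoff,
      threshold = threshold, baseline = baseline, stats = stats,
      provenance = provenance)
}

#' Fit a one-versus-all ridge logistic model
#'
#' Binary logistic regression by iteratively reweighted least squares with
#' a ridge penalty chosen from a small grid by inner 3-fold AUC.  Perfect
#' separation at penalty 0 falls back to the smallest nonzero grid value
#' (flagged in provenance).  Wald confidence intervals and p-values are
#' reported per coefficient.
#'
#' @param X patients x features matrix on the transformed scale.
#' @param labels class labels.
#' @param positiveClass the label treated as the positive class.
#' @param penaltyGrid ridge grid (default c(0, 0.01, 0.1, 1, 10)).
#' @param transforms frozen \code{\link{fitTransforms}} parameters to store
#'   with the model (optional).
#' @param seed seed for the inner folds.
#' @return a \linkS4class{FittedModel} of kind "logistic_ova".
#' @export
fitLogisticOva <- function(X, labels, positiveClass,
                           penaltyGrid = c(0, 0.01, 0.1, 1, 10),
                           transforms = NULL, seed = 1L) {
  X <- as.matrix(X)
  yb <- as.integer(labels == positiveClass)
  if (length(unique(yb)) < 2L) stop("both classes must be present")
  cvAuc <- vapply(penaltyGrid, function(lam) {
    idx <- makeStratifiedFolds(yb, 3L, deriveSeed(seed, "ridge-grid"))
    auc <- numeric(0)
    for (f in 1:3) {
      tr <- idx != f
      if (length(unique(yb[tr])) < 2L || length(unique(yb[!tr])) < 2L) next
      fit <- ridgeLogisticIrls(X[tr, , drop = FALSE], yb[tr], lam)
      pr <- stats::plogis(cbind(1, X[!tr, , drop = FALSE]) %*% fit$beta)
      auc <- c(auc, aucRank(pr, yb[!tr]))
    }
    if (length(auc)) mean(auc) else NA_real_
  }, numeric(1))
  lam <- penaltyGrid[which.max(cvAuc)]
  fit <- ridgeLogisticIrls(X, yb, lam)
  flagged <- FALSE
  if (lam == 0 && fit$separated) {
    lam <- min(penaltyGrid[penaltyGrid > 0])
    fit <- ridgeLogisticIrls(X, yb, lam)
    flagged <- TRUE
  }
  beta <- fit$beta
  z <- beta / fit$se
  statTab <- data.frame(term = names(beta), estimate = beta, se = fit$se,
                        ci_low = beta - 1.96 * fit$se,
                        ci_high = beta + 1.96 * fit$se,
                        p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  fittedModel("logistic_ova", beta[-1], intercept = unname(beta[1]),
              transforms = transforms, stats = statTab,
              provenance = list(penalty = lam, cv_auc = cvAuc,
                                positive_class = positiveClass,
                                separation_fallback = flagged))
}

#' Fit a Cox proportional hazards model
#'
#' Partial-likelihood Newton optimisation with Efron tie handling (via the
#' survival package), Wald confidence intervals, hazard ratios and the
#' Breslow baseline cumulative hazard for calibration.  Forced covariates
#' (the tumour volume, by default upstream) are recorded in the model.
#'
#' @param X patients x features matrix on the transformed scale.
#' @param time,event the endpoint (months, 0/1).
#' @param forced names of forced covariates (bookkeeping).
#' @param transforms frozen transform parameters to store.
#' @return a \linkS4class{FittedModel} of kind "cox".
#' @export
fitCox <- function(X, time, event, forced = character(),
                   transforms = NULL) {
  X <- as.matrix(X)
  if (sum(event) == 0) stop("no events")
  if (sum(event) < 10) warning("fewer than 10 events: estimates unstable")
  df <- data.frame(X, check.names = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ .,
                         data = df, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)))
    stop("Cox fit did not converge; max gradient ",
         format(max(abs(colSums(survival::residuals(fit, "score"))))))
  names(beta) <- colnames(X)
  se <- sqrt(diag(fit$var))
  statTab <- data.frame(term = names(beta), estimate = beta,
                        hr = exp(beta), se = se,
                        hr_ci_low = exp(beta - 1.96 * se),
                        hr_ci_high = exp(beta + 1.96 * se),
                        p = 2 * stats::pnorm(-abs(beta / se)),
                        row.names = NULL)
  bh <- survival::basehaz(fit, centered = FALSE)
  fittedModel("cox", beta, transforms = transforms, forced = forced,
              baseline = data.frame(time = bh$time, cumhaz = bh$hazard),
              stats = statTab, provenance = list(n_events = sum(event)))
}

#' Apply a FittedModel to raw feature values
#'
#' Pure function: applies the stored Yeo-Johnson/z transforms (when
#' present), then the coefficients.  Logistic models return the positive
#' class probability; Cox models return the relative risk exp(beta' z) and
#' optionally the predicted survival probability at a horizon via the
#' Breslow baseline.
#'
#' @param model a \linkS4class{FittedModel}.
#' @param newdata data.frame/matrix with the model's raw features (or
#'   already-transformed values if the model has no stored transforms).
#' @param horizon optional time at which to return predicted survival
#'   (Cox only).
#' @return numeric vector (probabilities or risks), or data.frame(risk,
#'   survival) when \code{horizon} is given.
#' @export
predictModel <- function(model, newdata, horizon = NULL) {
  nd <- as.data.frame(newdata)
  miss <- setdiff(model@features, names(nd))
  if (length(miss))
    stop("missing model feature(s): ", paste(miss, collapse = ", "))
  if (nrow(model@transforms)) {
    Z <- applyTransforms(nd[model@features],
                         model@transforms[
                           match(model@features, model@transforms$feature), ])
  } else {
    Z <- as.matrix(nd[model@features])
  }
  lp <- as.numeric(Z %*% model@coefficients[model@features])
  if (model@kind == "logistic_ova")
    return(stats::plogis(model@intercept + lp))
  risk <- exp(lp)
  if (is.null(horizon)) return(risk)
  if (!nrow(model@baseline)) stop("model has no baseline hazard stored")
  h0 <- stats::approxfun(model@baseline$time, model@baseline$cumhaz,
                         method = "constant", yleft = 0,
                         rule = 2)(horizon)
  data.frame(risk = risk, survival = exp(-h0 * risk))
}

#' Persist a FittedModel as JSON
#' @param model a \linkS4class{FittedModel}.
#' @param path output path.
#' @export
writeModel <- function(model, path) {
  obj <- list(kind = model@kind, features = model@features,
              coefficients = as.list(model@coefficients),
              intercept = model@intercept,
              transforms = model@transforms, forced = model@forced,
              cutoff = model@cutoff, threshold = model@threshold,
              baseline = model@baseline, stats = model@stats,
              provenance = model@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read a FittedModel back from JSON
#' @param path JSON path written by \code{\link{writeModel}}.
#' @return a \linkS4class{FittedModel}.
#' @export
readModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  fittedModel(o$kind, unlist(o$coefficients),
              intercept = o$intercept %||% NA_real_,
              transforms = if (length(o$transforms)) o$transforms else NULL,
              forced = as.character(o$forced %||% character()),
              cutoff = o$cutoff %||% NA_real_,
              threshold = o$threshold %||% NA_real_,
              baseline = if (length(o$baseline)) o$baseline else NULL,
              stats = if (length(o$stats)) as.data.frame(o$stats) else NULL,
              provenance = as.list(o$provenance %||% list()))
}
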