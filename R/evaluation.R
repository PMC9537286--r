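# Performance, stratification and calibration statistics: AUC and f1 with
# reference-value cutoffs (600-bootstrap CIs), Harrell concordance,
# Hosmer-Lemeshow and Greenwood-Nam-d'Agostino calibration, Kaplan-Meier /
# log-rank stratification and the Schoenfeld proportional-hazards test.

#' EvalReport: a metric with its bootstrap confidence interval
#'
#' @slot metric metric name.
#' @slot estimate point estimate (median over bootstraps).
#' @slot ciLow,ciHigh 95 percent percentile bootstrap bounds.
#' @slot nBoot number of bootstrap resamples.
#' @slot aux auxiliary values (cutoffs, groups, p-values).
#' @export
setClass("EvalReport",
  representation(metric = "character", estimate = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", nBoot = "numeric",
                 aux = "list"))

setValidity("EvalReport", function(object) {
  if (object@ciLow > object@estimate || object@estimate > object@ciHigh)
    return("point estimate must lie inside the CI")
  TRUE
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("%s: %.3f [%.3f-%.3f] (%d bootstraps)\n", object@metric,
              object@estimate, object@ciLow, object@ciHigh, object@nBoot))
})

#' @export
setGeneric("reportEstimate", function(x) standardGeneric("reportEstimate"))
#' @export
setMethod("reportEstimate", "EvalReport", function(x) x@estimate)

#' @export
setGeneric("reportCI", function(x) standardGeneric("reportCI"))
#' @export
setMethod("reportCI", "EvalReport", function(x) c(x@ciLow, x@ciHigh))

bootReport <- function(metric, statFun, n, nBoot, seed, aux = list()) {
  vals <- withSeed(deriveSeed(seed, paste0("boot-", metric)), {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      statFun(idx)
    }, numeric(1))
  })
  vals <- vals[is.finite(vals)]
  q <- stats::quantile(vals, c(0.5, 0.025, 0.975), names = FALSE)
  new("EvalReport", metric = metric, estimate = q[1], ciLow = q[2],
      ciHigh = q[3], nBoot = nBoot,
      aux = c(aux, list(point = statFun(seq_len(n)))))
}

#' AUC of the empirical ROC with a percentile bootstrap CI
#'
#' Trapezoidal AUC (mid-rank handling of ties), bootstrapped over patients.
#'
#' @param scores predicted scores or probabilities.
#' @param labels binary labels (0/1, logical, or factor with the positive
#'   class last).
#' @param nBoot bootstrap resamples (default 600).
#' @param seed integer seed.
#' @return an \linkS4class{EvalReport}.
#' @export
rocAuc <- function(scores, labels, nBoot = 600L, seed = 1L) {
  y <- as.integer(as.logical(labels) | labels == 1)
  if (is.factor(labels) || is.character(labels))
    y <- as.integer(labels == sort(unique(as.character(labels)))[
      length(unique(labels))])
  if (length(unique(y)) < 2L) stop("both classes required")
  bootReport("auc", function(idx) {
    if (length(unique(y[idx])) < 2L) return(NA_real_)
    aucRank(scores[idx], y[idx])
  }, length(y), nBoot, seed)
}

f1Score <- function(pred, y) {
  tp <- sum(pred & y == 1)
  fp <- sum(pred & y == 0)
  fn <- sum(!pred & y == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' f1 score with a reference-value-guided cutoff
#'
#' In fit mode, candidate cutoffs are the midpoints of the sorted observed
#' scores.  The reference value is the f1 of the always-positive
#' classifier, 2 pi / (1 + pi) for positive-class prevalence pi, which
#' maximises expected f1 among label-independent rules.  Eligible cutoffs
#' have a median bootstrap f1 above the reference; the chosen cutoff
#' maximises the lower end of the 95 percent bootstrap CI among the
#' eligible (flagged if none is eligible).  Apply mode reuses a stored
#' cutoff without refitting anything.
#'
#' @param scores predicted scores.
#' @param labels binary labels.
#' @param mode "fit" (discovery) or "apply".
#' @param cutoff stored cutoff for apply mode.
#' @param nBoot bootstraps (default 600).
#' @param seed integer seed.
#' @return list(cutoff, report, reference, eligible).
#' @export
f1WithCutoff <- function(scores, labels, mode = c("fit", "apply"),
                         cutoff = NULL, nBoot = 600L, seed = 1L) {
  mode <- match.arg(mode)
  y <- as.integer(labels == 1 | as.logical(labels))
  prev <- mean(y)
  ref <- 2 * prev / (1 + prev)
  n <- length(y)
  bootIdx <- withSeed(deriveSeed(seed, "f1-boot"),
                      matrix(sample.int(n, n * nBoot, replace = TRUE),
                             nBoot, n))
  if (mode == "fit") {
    su <- sort(unique(scores))
    if (length(su) < 2L) stop("all scores identical")
    cands <- (su[-1] + su[-length(su)]) / 2
    med <- lo <- numeric(length(cands))
    for (ci in seq_along(cands)) {
      pred <- scores > cands[ci]
      f1s <- vapply(seq_len(nBoot), function(b) {
        idx <- bootIdx[b, ]
        f1Score(pred[idx], y[idx])
      }, numeric(1))
      f1s <- f1s[is.finite(f1s)]
      med[ci] <- stats::median(f1s)
      lo[ci] <- stats::quantile(f1s, 0.025, names = FALSE)
    }
    eligible <- med > ref
    pick <- if (any(eligible)) which(eligible)[which.max(lo[eligible])]
            else which.max(lo)
    cutoff <- cands[pick]
  }
  pred <- scores > cutoff
  rep <- bootReport("f1", function(idx) f1Score(pred[idx], y[idx]),
                    n, nBoot, seed,
                    aux = list(cutoff = cutoff, reference = ref))
  list(cutoff = cutoff, report = rep, reference = ref,
       eligible = if (mode == "fit") any(eligible) else NA)
}

#' Harrell's concordance index with bootstrap CI
#'
#' Concordant over comparable pairs under censoring; ties in risk count
#' one half.  Higher risk is expected to pair with shorter survival.
#'
#' @param risk predicted risk scores.
#' @param time,event the endpoint.
#' @param nBoot bootstraps (default 600).
#' @param seed integer seed.
#' @return an \linkS4class{EvalReport}.
#' @export
concordanceIndex <- function(risk, time, event, nBoot = 600L, seed = 1L) {
  cidx <- function(idx) {
    cc <- tryCatch(survival::concordance(
      survival::Surv(time[idx], event[idx]) ~ risk[idx], reverse = TRUE),
      error = function(e) NULL)
    if (is.null(cc) || is.na(cc$concordance)) NA_real_ else cc$concordance
  }
  point <- cidx(seq_along(risk))
  if (is.na(point)) stop("no comparable pairs")
  bootReport("c_index", cidx, length(risk), nBoot, seed)
}

#' Hosmer-Lemeshow calibration test
#'
#' Decile-of-risk groups (ties kept together); chi-squared statistic
#' sum (O - E)^2 / (E (1 - E/n_g)) on g - 2 degrees of freedom.
#' Near-degenerate groups are merged with their neighbour.
#'
#' @param probabilities predicted event probabilities.
#' @param outcomes observed 0/1 outcomes.
#' @param g number of groups (default 10).
#' @return list(statistic, df, p_value, table).
#' @export
hosmerLemeshow <- function(probabilities, outcomes, g = 10L) {
  stopifnot(g >= 2L, length(outcomes) >= 2L * g)
  br <- unique(stats::quantile(probabilities, seq(0, 1, length.out = g + 1),
                               type = 7))
  grp <- if (length(br) < 2L) rep(1L, length(probabilities))
         else cut(probabilities, breaks = br, include.lowest = TRUE,
                  labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(k) {
    sel <- grp == k
    data.frame(n = sum(sel), obs = sum(outcomes[sel]),
               exp = sum(probabilities[sel]))
  }))
  # merge groups whose variance term degenerates
  repeat {
    v <- tab$exp * (1 - tab$exp / tab$n)
    bad <- which(v < 1e-8)
    if (!length(bad) || nrow(tab) <= 2L) break
    i <- bad[1]
    j <- if (i == 1L) 2L else i - 1L
    tab[j, ] <- tab[j, ] + tab[i, ]
    tab <- tab[-i, , drop = FALSE]
    message("Hosmer-Lemeshow: merged a degenerate group")
  }
  v <- pmax(tab$exp * (1 - tab$exp / tab$n), 1e-12)
  stat <- sum((tab$obs - tab$exp)^2 / v)
  df <- max(nrow(tab) - 2L, 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Greenwood-Nam-d'Agostino calibration test at a horizon
#'
#' Patients are grouped by predicted survival (risk deciles by default,
#' merged until every group holds at least two events by the horizon).
#' Per group the Kaplan-Meier observed survival at the horizon (Greenwood
#' variance) is compared with the mean model-predicted survival; the
#' statistic is chi-squared on groups - 1 degrees of freedom.
#'
#' @param predicted model-predicted survival probability at the horizon
#'   per patient.
#' @param time,event the endpoint.
#' @param horizon calibration horizon (default 24 months).
#' @param g initial number of risk groups (default 10).
#' @param groups optional explicit group assignment overriding deciles.
#' @return list(statistic, df, p_value, table).
#' @export
gndCalibration <- function(predicted, time, event, horizon = 24, g = 10L,
                           groups = NULL) {
  if (all(time[event == 1] > horizon) || sum(event) == 0)
    stop("no events observed before the horizon")
  if (is.null(groups)) {
    br <- unique(stats::quantile(predicted, seq(0, 1, length.out = g + 1),
                                 type = 7))
    if (length(br) < 3L) br <- c(-Inf, stats::median(predicted), Inf)
    groups <- cut(predicted, br, include.lowest = TRUE, labels = FALSE)
  }
  groups <- as.integer(factor(groups))
  # merge adjacent groups until every group has >= 2 events by the horizon
  repeat {
    ev <- tapply(event == 1 & time <= horizon, groups, sum)
    bad <- which(ev < 2)
    if (!length(bad)) break
    if (length(unique(groups)) <= 2L)
      stop("cannot form >= 2 groups with >= 2 events each")
    tgt <- as.integer(names(ev)[bad[1]])
    nb <- if (tgt == max(groups)) tgt - 1L else tgt + 1L
    groups[groups == tgt] <- nb
    groups <- as.integer(factor(groups))
  }
  ug <- sort(unique(groups))
  if (length(ug) < 2L) stop("need at least two risk groups")
  rows <- lapply(ug, function(k) {
    sel <- groups == k
    sf <- survival::survfit(survival::Surv(time[sel], event[sel]) ~ 1)
    ss <- summary(sf, times = horizon, extend = TRUE)
    data.frame(group = k, n = sum(sel), km = ss$surv,
               se = ss$std.err, expected = mean(predicted[sel]))
  })
  tab <- do.call(rbind, rows)
  v <- pmax(tab$se^2, 1e-12)
  stat <- sum((tab$km - tab$expected)^2 / v)
  df <- nrow(tab) - 1L
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Kaplan-Meier curves and log-rank test between groups
#'
#' @param time,event the endpoint.
#' @param group group labels (>= 2 nonempty groups).
#' @return list(fit, statistic, df, p_value).
#' @export
kmLogrank <- function(time, event, group) {
  group <- factor(group)
  if (nlevels(group) < 2L || any(table(group) == 0))
    stop("need >= 2 nonempty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  if (sum(event) == 0)           # no events: the test has no information
    return(list(fit = fit, statistic = NA_real_,
                df = nlevels(group) - 1L, p_value = NA_real_))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(fit = fit, statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Risk stratification threshold optimised on the discovery cohort
#'
#' Fit mode scans candidate thresholds (midpoints of observed risks
#' between the 10th and 90th percentiles) and picks the one minimising the
#' discovery log-rank p-value; apply mode splits new patients at the
#' stored threshold and reports their log-rank test.
#'
#' @param risk predicted risk scores.
#' @param time,event the endpoint.
#' @param mode "fit" or "apply".
#' @param threshold stored threshold for apply mode.
#' @return list(threshold, p_value, statistic, groups).
#' @export
stratificationThreshold <- function(risk, time, event,
                                    mode = c("fit", "apply"),
                                    threshold = NULL) {
  mode <- match.arg(mode)
  if (mode == "fit") {
    su <- sort(unique(risk))
    if (length(su) < 2L) stop("all risks identical")
    mids <- (su[-1] + su[-length(su)]) / 2
    qs <- stats::quantile(risk, c(0.1, 0.9), names = FALSE)
    cands <- mids[mids >= qs[1] & mids <= qs[2]]
    if (!length(cands)) cands <- stats::median(risk)
    ps <- vapply(cands, function(th) {
      gr <- risk > th
      if (!any(gr) || all(gr)) return(1)
      kmLogrank(time, event, gr)$p_value
    }, numeric(1))
    threshold <- cands[which.min(ps)]    # ties: lowest threshold
  }
  gr <- factor(ifelse(risk > threshold, "high", "low"),
               levels = c("low", "high"))
  lr <- if (nlevels(droplevels(gr)) == 2L) kmLogrank(time, event, gr)
        else list(p_value = NA_real_, statistic = NA_real_)
  list(threshold = threshold, p_value = lr$p_value,
       statistic = lr$statistic, groups = gr)
}

#' Schoenfeld-residual proportional-hazards test
#'
#' Scaled Schoenfeld residuals regressed on Kaplan-Meier-transformed time;
#' score-type chi-squared per covariate plus a global test.
#'
#' @param X patients x features matrix on the model scale.
#' @param time,event the endpoint.
#' @param model optional \linkS4class{FittedModel} of kind "cox"; when
#'   given, its features subset X.
#' @return data.frame(term, chisq, df, p).
#' @export
schoenfeldPhTest <- function(X, time, event, model = NULL) {
  X <- as.matrix(X)
  if (!is.null(model)) X <- X[, model@features, drop = FALSE]
  if (sum(event) <= ncol(X)) stop("fewer events than covariates")
  df <- data.frame(X, check.names = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "efron")
  zp <- survival::cox.zph(fit, transform = "km")
  out <- data.frame(term = rownames(zp$table), chisq = zp$table[, "chisq"],
                    df = zp$table[, "df"], p = zp$table[, "p"],
                    row.names = NULL)
  out
}
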