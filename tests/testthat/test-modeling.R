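test_that("Yeo-Johnson transform, inverse and published worked values", {
  x <- c(-3.2, -0.5, 0, 0.4, 2.7)
  for (lam in c(-0.5, 0, 1, 2, 1.7))
    expect_equal(yeoJohnsonInverse(yeoJohnson(x, lam), lam), x,
                 tolerance = 1e-10)
  # lambda 1 is the identity (the +1/-1 terms cancel)
  expect_equal(yeoJohnson(x, 1), x, tolerance = 1e-12)
  expect_equal(yeoJohnson(c(0, 1, 4), 0), log(c(1, 2, 5)))

  # published atypical-model parameters: raw values mapping to z = 0
  expect_equal(inverseTransform(0, -0.5, 0.246, 0.046), 0.300,
               tolerance = 2e-3)
  expect_equal(inverseTransform(0, 0, 4.190, 0.669), exp(4.190) - 1,
               tolerance = 1e-9)
  expect_equal((yeoJohnson(0.300, -0.5) - 0.246) / 0.046, 0,
               tolerance = 2e-2)
})

test_that("fitted transforms standardise discovery and transfer frozen", {
  withr::with_seed(8, {
    X <- cbind(a = stats::rexp(120, 0.2), b = stats::rnorm(120, 5, 2))
  })
  tp <- fitTransforms(X)
  expect_s3_class(tp, "TransformParams")
  Z <- applyTransforms(X, tp)
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(apply(Z, 2, stats::sd)), c(1, 1), tolerance = 1e-8)
  # pure function of the stored parameters: new data reuses them
  Xv <- cbind(a = stats::rexp(30, 0.2), b = stats::rnorm(30, 5, 2))
  Zv <- applyTransforms(Xv, tp)
  expect_equal(Zv[, "a"],
               (yeoJohnson(Xv[, "a"], tp$lambda[1]) - tp$shift[1]) /
                 tp$scale[1])
  expect_error(fitTransforms(cbind(k = rep(2, 20))), "zero discovery SD")
  expect_error(applyTransforms(Xv[, 1, drop = FALSE], tp), "missing")
})

test_that("redundancy clustering matches a brute-force complete linkage", {
  withr::with_seed(14, {
    X <- matrix(stats::rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
  })
  got <- clusterRepresentatives(X, 0.3)
  rho <- stats::cor(X, method = "spearman")
  lab <- oracleCompleteLinkageCut(1 - abs(rho), 0.3)
  # same partition up to label names
  expect_equal(length(unique(lab)), length(got$representatives))
  for (k in unique(lab)) {
    members <- colnames(X)[lab == k]
    expect_length(unique(got$clusters[members]), 1L)
  }

  # duplicated features collapse; monotone transforms share a cluster
  X2 <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  g2 <- clusterRepresentatives(X2)
  expect_length(g2$representatives, 2L)
  X3 <- cbind(u = X[, 1], v = exp(X[, 1]), w = X[, 2])
  g3 <- clusterRepresentatives(X3)
  expect_equal(unname(g3$clusters["u"]), unname(g3$clusters["v"]))
  expect_error(clusterRepresentatives(X[, 0, drop = FALSE]), "empty")
})

test_that("volume-correlation pre-filter discards rho > 0.5 features", {
  withr::with_seed(9, {
    vol <- stats::rexp(80, 0.1)
    X <- cbind(corr = vol^1.3 + stats::rnorm(80, 0, 1),
               indep = stats::rnorm(80))
  })
  keep <- volumeCorrelationFilter(X, vol)
  expect_identical(keep, "indep")
})

test_that("MRMR: relevance dominates, redundancy is penalised, greedy
           path matches exhaustive evaluation", {
  withr::with_seed(16, {
    n <- 300
    f1 <- stats::rnorm(n)
    y <- as.integer(f1 + stats::rnorm(n, 0, 0.4) > 0)
    X <- cbind(f1 = f1, f2 = f1 + stats::rnorm(n, 0, 0.05),
               f3 = stats::rnorm(n) + 0.35 * y)
  })
  # the target itself, duplicated as a feature, is selected first
  Xy <- cbind(X, target_copy = y + stats::rnorm(300, 0, 1e-6))
  expect_identical(mrmrRank(Xy, y, 1), "target_copy")
  # planted order: informative, then the independent one, then the copy
  expect_identical(mrmrRank(X, y, 3), c("f1", "f3", "f2"))

  for (s in 1:5) {
    withr::with_seed(s, {
      Xr <- matrix(stats::rnorm(120 * 5), 120, 5,
                   dimnames = list(NULL, paste0("v", 1:5)))
      yr <- as.integer(Xr[, 2] + 0.5 * Xr[, 4] +
                         stats::rnorm(120, 0, 0.7) > 0)
    })
    expect_identical(mrmrRank(Xr, yr, 5), oracleMrmrGreedy(Xr, yr, 5))
  }
  expect_warning(mrmrRank(X, y, 10), "truncated")
})

test_that("repeated-CV Borda ranking is deterministic and finds the
           separating feature in every fold", {
  withr::with_seed(22, {
    n <- 60
    sep <- c(stats::rnorm(n / 2, -3, 0.3), stats::rnorm(n / 2, 3, 0.3))
    X <- cbind(sep = sep, n1 = stats::rnorm(n), n2 = stats::rnorm(n))
    y <- rep(c("a", "b"), each = n / 2)
  })
  rk <- cvRankAggregate(X, y = y, task = "classification", reps = 33,
                        folds = 3, seed = 2)
  expect_identical(rk$ranking$feature[1], "sep")
  expect_equal(rk$ranking$occurrence[1], 99L)
  rk2 <- cvRankAggregate(X, y = y, task = "classification", reps = 33,
                         folds = 3, seed = 2)
  expect_identical(rk, rk2)
})

test_that("enhanced Borda matches a hand-computed two-fold example", {
  # fold 1 selects (A, B) of size 2; fold 2 selects (B,) of size 1:
  #   A: (2-1+1)/2 = 1.0          -> / 2 folds = 0.5
  #   B: (2-2+1)/2 + (1-1+1)/1 = 1.5 -> / 2 folds = 0.75
  scoreOf <- function(ranks, sizes, nFolds) {
    s <- 0
    for (f in seq_along(ranks)) {
      if (is.na(ranks[f]) || ranks[f] > sizes[f]) next
      s <- s + (sizes[f] - ranks[f] + 1) / sizes[f]
    }
    s / nFolds
  }
  expect_equal(scoreOf(c(1, NA), c(2, 1), 2), 0.5)
  expect_equal(scoreOf(c(2, 1), c(2, 1), 2), 0.75)
})

test_that("pure-noise features have no fixed Borda winner across seeds", {
  winners <- vapply(1:6, function(s) {
    withr::with_seed(s * 100, {
      X <- matrix(stats::rnorm(45 * 4), 45, 4,
                  dimnames = list(NULL, paste0("n", 1:4)))
      y <- rep(c("a", "b"), length.out = 45)
    })
    cvRankAggregate(X, y = y, task = "classification", reps = 4,
                    folds = 3, seed = s)$ranking$feature[1]
  }, character(1))
  expect_gt(length(unique(winners)), 1L)
})

test_that("ridge logistic agrees with glm at zero penalty and handles
           separation", {
  withr::with_seed(5, {
    X <- matrix(stats::rnorm(200 * 2), 200, 2,
                dimnames = list(NULL, c("u", "v")))
    y <- stats::rbinom(200, 1, stats::plogis(0.8 * X[, 1] - 0.4 * X[, 2]))
  })
  ours <- radiogenomix:::ridgeLogisticIrls(X, y, penalty = 0)
  ref <- stats::glm(y ~ X, family = stats::binomial())
  expect_equal(unname(ours$beta), unname(stats::coef(ref)),
               tolerance = 1e-6)

  # linearly separable toy: ridge keeps it finite, training AUC 1
  Xs <- matrix(c(-(10:1), 1:10), ncol = 1,
               dimnames = list(NULL, "x"))
  ys <- rep(c("neg", "pos"), each = 10)
  fit <- fitLogisticOva(Xs, ys, "pos", penaltyGrid = c(0.01, 0.1))
  pr <- predictModel(fit, data.frame(x = Xs[, 1]))
  expect_equal(reportEstimate(rocAuc(pr, ys == "pos", nBoot = 50)), 1)
})

test_that("null logistic model recovers intercept ~ 0 and AUC ~ 0.5", {
  withr::with_seed(6, {
    X <- matrix(stats::rnorm(400), 200, 2,
                dimnames = list(NULL, c("a", "b")))
    y <- rep(c("x", "z"), 100)
  })
  fit <- fitLogisticOva(X, y, "z", penaltyGrid = 0)
  expect_equal(fit@intercept, 0, tolerance = 0.25)
  pr <- predictModel(fit, as.data.frame(X))
  auc <- reportEstimate(rocAuc(pr, y == "z", nBoot = 100))
  expect_equal(auc, 0.5, tolerance = 0.12)
})

test_that("the published atypical model reproduces its worked example", {
  tab <- data.frame(feature = c("morph_vol_dens_aabb", "szm_glnu"),
                    lambda = c(-0.5, 0), shift = c(0.246, 4.190),
                    scale = c(0.046, 0.669))
  m <- fittedModel("logistic_ova",
                   c(morph_vol_dens_aabb = 0.114, szm_glnu = -0.545),
                   intercept = -0.968, transforms = tab)
  z0 <- data.frame(morph_vol_dens_aabb = inverseTransform(0, -0.5, 0.246,
                                                          0.046),
                   szm_glnu = inverseTransform(0, 0, 4.190, 0.669))
  expect_equal(predictModel(m, z0), 1 / (1 + exp(0.968)),
               tolerance = 1e-6)
  # szm_glnu carries a negative coefficient: raising it lowers p(atypical)
  hi <- z0; hi$szm_glnu <- hi$szm_glnu * 1.5
  expect_lt(predictModel(m, hi), predictModel(m, z0))
})

test_that("Cox fitting recovers a planted hazard ratio and applies the
           published multivariable model", {
  hrs <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      x <- stats::rbinom(500, 1, 0.5)
    })
    o <- generateOutcomes(data.frame(x = x), c(x = log(2)),
                          censoringRate = 0.2, seed = s)
    fit <- fitCox(cbind(x = x), o$time, o$event)
    unname(hazardRatios(fit))
  }, numeric(1))
  expect_gt(mean(hrs), 1.7)
  expect_lt(mean(hrs), 2.3)

  # published combined model: all-zero z gives relative risk 1; one unit
  # of log_stat_p90 multiplies the hazard by its HR
  co <- log(c(gtv = 1.196, log_stat_p90 = 1.393, e2f = 0.774,
              hedgehog = 1.329))
  m <- fittedModel("cox", co)
  z0 <- data.frame(gtv = 0, log_stat_p90 = 0, e2f = 0, hedgehog = 0)
  expect_equal(predictModel(m, z0), 1)
  z1 <- z0; z1$log_stat_p90 <- 1
  expect_equal(predictModel(m, z1) / predictModel(m, z0), 1.393,
               tolerance = 1e-9)
  # all-zero coefficients: risk 1 for everyone
  m0 <- fittedModel("cox", c(a = 0, b = 0))
  expect_equal(predictModel(m0, data.frame(a = stats::rnorm(5),
                                           b = stats::rnorm(5))),
               rep(1, 5))

  expect_error(fitCox(cbind(x = stats::rnorm(20)), stats::rexp(20),
                      rep(0, 20)), "no events")
})

test_that("models persist to JSON and back unchanged", {
  withr::with_seed(3, {
    X <- matrix(stats::rnorm(60 * 2), 60, 2,
                dimnames = list(NULL, c("p", "q")))
    y <- stats::rbinom(60, 1, stats::plogis(X[, 1]))
  })
  tp <- fitTransforms(X)
  fit <- fitLogisticOva(applyTransforms(X, tp), ifelse(y == 1, "a", "b"),
                        "a", transforms = tp)
  fit@cutoff <- 0.4
  p <- tempfile(fileext = ".json")
  writeModel(fit, p)
  back <- readModel(p)
  expect_equal(back@coefficients, fit@coefficients, tolerance = 1e-12)
  expect_equal(back@intercept, fit@intercept, tolerance = 1e-12)
  expect_equal(back@cutoff, 0.4)
  nd <- data.frame(p = stats::rnorm(5), q = stats::rnorm(5))
  expect_equal(predictModel(back, nd), predictModel(fit, nd),
               tolerance = 1e-10)
  expect_error(predictModel(fit, nd[, 1, drop = FALSE]), "missing")
})

test_that("discovery-fitted parameters never move when validation data
           change (leak-freedom)", {
  withr::with_seed(44, {
    Xd <- matrix(stats::rnorm(80 * 3), 80, 3,
                 dimnames = list(NULL, c("a", "b", "c")))
    yd <- stats::rbinom(80, 1, stats::plogis(Xd[, 1]))
    Xv1 <- matrix(stats::rnorm(30 * 3), 30, 3,
                  dimnames = list(NULL, c("a", "b", "c")))
  })
  Xv2 <- Xv1 * 5 + 100                        # mutated validation cohort
  runOnce <- function(Xv) {
    tp <- fitTransforms(Xd)
    Zd <- applyTransforms(Xd, tp)
    fit <- fitLogisticOva(Zd, ifelse(yd == 1, "pos", "neg"), "pos",
                          seed = 7)
    prD <- predictModel(fit, as.data.frame(Zd))
    cut <- f1WithCutoff(prD, yd, "fit", nBoot = 100, seed = 3)$cutoff
    o <- generateOutcomes(data.frame(r = prD), c(r = 1), seed = 5)
    thr <- stratificationThreshold(prD, o$time, o$event, "fit")$threshold
    # validation is only ever *applied* to
    invisible(predictModel(fit, as.data.frame(Xv)))
    list(tp = tp, beta = fit@coefficients, cut = cut, thr = thr)
  }
  r1 <- runOnce(Xv1)
  r2 <- runOnce(Xv2)
  expect_identical(r1, r2)
})
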