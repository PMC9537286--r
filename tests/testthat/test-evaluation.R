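test_that("AUC handles perfect ordering, ties and label noise", {
  expect_equal(reportEstimate(rocAuc(1:4, c(0, 0, 1, 1), nBoot = 100)), 1)
  expect_equal(radiogenomix:::aucRank(rep(2, 10),
                                      rep(c(0, 1), 5)), 0.5)
  withr::with_seed(2, {
    sc <- stats::rnorm(200)
    y <- stats::rbinom(200, 1, 0.4)
  })
  r <- rocAuc(sc, y, nBoot = 200, seed = 5)
  expect_equal(reportEstimate(r), 0.5, tolerance = 0.08)
  expect_lte(r@ciLow, reportEstimate(r))
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
})

test_that("bootstrap CIs are seed-stable and shrink with n", {
  widths <- vapply(c(50, 200, 800), function(n) {
    withr::with_seed(n, {
      sc <- stats::rnorm(n)
      y <- stats::rbinom(n, 1, stats::plogis(sc))
    })
    r <- rocAuc(sc, y, nBoot = 200, seed = 9)
    diff(reportCI(r))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  r1 <- rocAuc(1:20, rep(c(0, 1), 10), nBoot = 150, seed = 4)
  r2 <- rocAuc(1:20, rep(c(0, 1), 10), nBoot = 150, seed = 4)
  expect_equal(reportCI(r1), reportCI(r2))
})

test_that("f1 cutoff selection uses the always-positive reference value", {
  # prevalence 0.2 -> reference 2*0.2/1.2 = 1/3, the f1 of predicting
  # everyone positive (tp = n1, fn = 0, fp = n0)
  y <- rep(c(1, 0), c(20, 80))
  refOracle <- {
    tp <- 20; fp <- 80; fn <- 0
    2 * tp / (2 * tp + fp + fn)
  }
  withr::with_seed(3, sc <- stats::rnorm(100) + y)
  res <- f1WithCutoff(sc, y, "fit", nBoot = 150, seed = 2)
  expect_equal(res$reference, 1 / 3, tolerance = 1e-12)
  expect_equal(res$reference, refOracle, tolerance = 1e-12)

  # perfectly separating scores reach f1 = 1 at an interior cutoff
  ys <- rep(c(0, 1), each = 10)
  res2 <- f1WithCutoff(c(1:10, 101:110), ys, "fit", nBoot = 100, seed = 1)
  expect_equal(reportEstimate(res2$report), 1)

  # apply mode refits nothing: stored cutoff passes through
  res3 <- f1WithCutoff(c(1:10, 101:110) + 0.01, ys, "apply",
                       cutoff = res2$cutoff, nBoot = 100, seed = 1)
  expect_equal(res3$cutoff, res2$cutoff)
})

test_that("concordance matches pair enumeration and behaves under null", {
  expect_equal(reportEstimate(concordanceIndex(c(3, 2, 1), 1:3,
                                               rep(1, 3), nBoot = 60)), 1)
  expect_equal(concordanceIndex(c(1, 2, 3), 1:3, rep(1, 3),
                                nBoot = 60)@aux$point, 0)
  withr::with_seed(7, {
    risk <- stats::rnorm(200)
    tm <- stats::rexp(200)
  })
  r <- concordanceIndex(risk, tm, rep(1, 200), nBoot = 150, seed = 3)
  expect_equal(reportEstimate(r), 0.5, tolerance = 0.05)
  expect_error(concordanceIndex(1, 1, 0), "comparable")
})

test_that("AUC and C-index coincide on binary uncensored time encodings", {
  withr::with_seed(10, {
    sc <- stats::rnorm(100)
    y <- stats::rbinom(100, 1, stats::plogis(sc))
  })
  auc <- radiogenomix:::aucRank(sc, y)
  # event time 1 for cases, 2 for controls; all events observed
  ci <- concordanceIndex(sc, ifelse(y == 1, 1, 2), rep(1, 100),
                         nBoot = 50)@aux$point
  expect_equal(ci, auc, tolerance = 1e-12)
})

test_that("Hosmer-Lemeshow is exact on degenerate input and detects
           miscalibration", {
  # all probabilities 0.5, half the outcomes 1: chi-squared 0, p 1
  hl <- hosmerLemeshow(rep(0.5, 100), rep(c(0, 1), 50), g = 10)
  expect_equal(hl$statistic, 0)
  expect_equal(hl$p_value, 1)

  withr::with_seed(6, {
    p <- stats::runif(500, 0.1, 0.7)
    yGood <- stats::rbinom(500, 1, p)
  })
  pBad <- pmin(p + 0.2, 0.99)
  expect_gt(hosmerLemeshow(p, yGood)$p_value, 0.01)
  expect_lt(hosmerLemeshow(pBad, yGood)$p_value, 0.05)
})

test_that("GND calibration needs >= 2 informative groups and flags
           doubled hazards", {
  withr::with_seed(8, {
    lp <- stats::rnorm(300, 0, 0.8)
    o <- generateOutcomes(data.frame(x = lp), c(x = 1),
                          baselineRate = 0.03, censoringRate = 0.2,
                          seed = 8)
  })
  fit <- fitCox(cbind(x = lp), o$time, o$event)
  sv <- predictModel(fit, data.frame(x = lp), horizon = 24)
  g <- gndCalibration(sv$survival, o$time, o$event, horizon = 24, g = 5)
  expect_gt(g$p_value, 0.001)
  # doubling predicted hazards breaks calibration
  svBad <- sv$survival^2
  gBad <- gndCalibration(svBad, o$time, o$event, horizon = 24, g = 5)
  expect_lt(gBad$p_value, g$p_value)
  expect_error(gndCalibration(rep(0.5, 10), rep(30, 10), rep(0, 10)),
               "events")
})

test_that("log-rank: identical groups give chi-squared 0; no events give
           flat curves", {
  tm <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- c(1, 0, 1, 1, 1, 0, 1, 1)
  gr <- rep(c("a", "b"), each = 4)
  lr <- kmLogrank(tm, ev, gr)
  expect_equal(lr$statistic, 0, tolerance = 1e-10)
  sf <- kmLogrank(tm, rep(0, 8), gr)$fit
  expect_true(all(sf$surv == 1))
  expect_error(kmLogrank(tm, ev, rep("a", 8)), "groups")
  # planted rate ratio 2 is detected
  ps <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      t1 <- stats::rexp(200, 0.05)
      t2 <- stats::rexp(200, 0.1)
    })
    kmLogrank(c(t1, t2), rep(1, 400), rep(1:2, each = 200))$p_value
  }, numeric(1))
  expect_lt(stats::median(ps), 0.01)
})

test_that("stratification threshold finds the gap and transfers frozen", {
  withr::with_seed(12, {
    riskLow <- stats::runif(60, 0.5, 1.0)
    riskHigh <- stats::runif(60, 2.0, 2.5)
    tLow <- stats::rexp(60, 0.01)
    tHigh <- stats::rexp(60, 0.3)
  })
  risk <- c(riskLow, riskHigh)
  fit <- stratificationThreshold(risk, c(tLow, tHigh), rep(1, 120), "fit")
  expect_gt(fit$threshold, 1.0)
  expect_lt(fit$threshold, 2.0)
  # the stored example: 1.502 splits {1.4, 1.6} into low/high
  ap <- stratificationThreshold(c(1.4, 1.6, 1.3, 1.7),
                                c(30, 5, 28, 6), c(0, 1, 0, 1),
                                "apply", threshold = 1.502)
  expect_identical(as.character(ap$groups),
                   c("low", "high", "low", "high"))
  expect_error(stratificationThreshold(rep(1, 10), stats::rexp(10),
                                       rep(1, 10), "fit"), "identical")
})

test_that("Schoenfeld test accepts proportional hazards and rejects a
           time-varying effect", {
  withr::with_seed(19, {
    x <- stats::rnorm(250)
    o <- generateOutcomes(data.frame(x = x), c(x = 0.7),
                          censoringRate = 0.2, seed = 19)
  })
  tab <- schoenfeldPhTest(cbind(x = x), o$time, o$event)
  expect_true(all(c("x", "GLOBAL") %in% tab$term))
  expect_gt(tab$p[tab$term == "x"], 0.01)
  expect_error(schoenfeldPhTest(cbind(x = x[1:3], y = x[4:6]),
                                c(1, 2, 3), c(1, 0, 0)), "events")
})
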