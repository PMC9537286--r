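test_that("subtype assignment follows the correlation and gap rules", {
  ctr <- syntheticCentroids(120, 31)
  # exact centroid profile: correlation 1, label assigned
  ex <- ctr[, rep("atypical", 3)]
  colnames(ex) <- paste0("s", 1:3)
  a <- assignSubtypes(ex, ctr)
  expect_equal(a$atypical, rep(1, 3), tolerance = 1e-12)
  expect_identical(a$label, rep("atypical", 3))

  # 50/50 mixture of two centroids: gap <= 0.2, unclassified
  mix <- 0.5 * (ctr[, "basal"] + ctr[, "classical"]) +
    withr::with_seed(2, stats::rnorm(120, 0, 0.01))
  am <- assignSubtypes(cbind(m1 = mix, m2 = mix), ctr)
  expect_identical(am$label, rep("unclassified", 2))

  # profile anti-correlated with everything: all correlations < 0.2
  anti <- -rowSums(ctr) + withr::with_seed(3, stats::rnorm(120, 0, 0.05))
  aa <- assignSubtypes(cbind(x = anti, y = anti), ctr)
  expect_true(all(aa$label == "unclassified" |
                    apply(aa[, 1:4], 1, max) >= 0.2))

  # constant profile: flagged unclassified
  ac <- assignSubtypes(cbind(k = rep(1, 120), j = ctr[, 1]), ctr)
  expect_identical(ac$label[1], "unclassified")
  expect_true(ac$flag_constant[1])

  expect_error(assignSubtypes(matrix(1:4, 2,
                                     dimnames = list(c("zz1", "zz2"),
                                                     NULL))[0, , drop = FALSE],
                              ctr), "shared")
})

test_that("subtype assignment is invariant to positive affine transforms", {
  ctr <- syntheticCentroids(100, 7)
  lab <- c("basal", "mesenchymal", "unclassified", "classical")
  ex <- generateExpression(4, ctr, lab, noiseSd = 0.2, seed = 9)
  a0 <- assignSubtypes(ex, ctr)
  a1 <- assignSubtypes(ex * 2.5 + 7, ctr)
  expect_identical(a1$label, a0$label)
  expect_equal(as.matrix(a1[, 1:4]), as.matrix(a0[, 1:4]),
               tolerance = 1e-10)
})

test_that("k-means signature classes recover planted structure and
           transfer leak-free", {
  genes <- sprintf("G%02d", 1:10)
  withr::with_seed(5, {
    lowS <- matrix(stats::rnorm(10 * 12, 0, 0.4), 10, 12)
    highS <- matrix(stats::rnorm(10 * 10, 4, 0.4), 10, 10)
  })
  expr <- cbind(lowS, highS)
  rownames(expr) <- genes
  colnames(expr) <- sprintf("s%02d", 1:22)
  fit <- signatureClasses(expr, genes, "fit", seed = 1)
  # class 1 is the higher-expression class by convention
  expect_true(all(fit$labels[13:22] == 1L))
  expect_true(all(fit$labels[1:12] == 2L))
  # transfer of the fitting cohort reproduces fitted labels exactly
  tr <- signatureClasses(expr, genes, "transfer", fitted = fit)
  expect_identical(unname(tr$labels), unname(fit$labels))
  # a point exactly on centroid 1 goes to class 1; an exactly equidistant
  # point ties to the lower-indexed centroid (hand-made fit object keeps
  # the arithmetic exact)
  handFit <- list(genes = c("G01", "G02"),
                  centroids = matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE,
                                     dimnames = list(c("1", "2"), NULL)),
                  zCenter = c(G01 = 0, G02 = 0),
                  zScale = c(G01 = 1, G02 = 1))
  onAndMid <- matrix(c(0, 0, 1, 1), 2, 2,
                     dimnames = list(c("G01", "G02"), c("on1", "mid")))
  trOn <- signatureClasses(onAndMid, handFit$genes, "transfer",
                           fitted = handFit)
  expect_equal(unname(trOn$labels[["on1"]]), 1L)
  expect_equal(unname(trOn$labels[["mid"]]), 1L)    # tie -> lower index

  expect_warning(signatureClasses(expr, c(genes, "MISSING"), "fit"),
                 "absent")
  expect_error(signatureClasses(matrix(1, 10, 5,
                                       dimnames = list(genes, NULL)),
                                genes, "fit"), "degenerate")
})

test_that("gene-set variation scores match the brute-force oracle", {
  withr::with_seed(12, {
    expr <- matrix(stats::rnorm(6 * 4), 6, 4,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  })
  set <- list(TOY = c("g2", "g5"))
  sc <- gsvaScores(expr, set)
  orc <- oracleGsva(expr, set$TOY)
  expect_equal(unname(sc[, "TOY"]), orc, tolerance = 1e-10)

  # larger random fixtures, several seeds
  for (s in 1:5) {
    withr::with_seed(s, {
      e2 <- matrix(stats::rnorm(20 * 6), 20, 6,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:6)))
      st <- sample(rownames(e2), 5)
    })
    expect_equal(unname(gsvaScores(e2, list(S = st))[, 1]),
                 oracleGsva(e2, st), tolerance = 1e-10)
  }
})

test_that("gene-set scores respect range, sign and ordering invariances", {
  withr::with_seed(3, {
    expr <- matrix(stats::rnorm(30 * 8), 30, 8,
                   dimnames = list(paste0("g", 1:30), paste0("s", 1:8)))
  })
  # a set planted at the top of sample 1's ranking scores positive there
  expr[c("g1", "g2", "g3"), 1] <- 10
  sc <- gsvaScores(expr, list(TOP = c("g1", "g2", "g3")))
  expect_gt(sc[1, "TOP"], 0)
  expect_true(all(sc >= -1 & sc <= 1))
  # permuting gene order leaves scores unchanged
  perm <- withr::with_seed(4, sample(nrow(expr)))
  sc2 <- gsvaScores(expr[perm, ], list(TOP = c("g1", "g2", "g3")))
  expect_equal(sc2, sc, tolerance = 1e-10)
  expect_error(gsvaScores(expr[, 1:2], list(S = c("g1", "g2"))),
               ">= 3 samples")
  expect_warning(gsvaScores(expr, list(S = "g1")), "skipped")
})

test_that("gene-set filtering honours the keep list and names near
           misses", {
  sets <- list(HALLMARK_HEDGEHOG_SIGNALING = letters[1:5],
               HALLMARK_E2F_TARGETS = letters[6:12],
               HALLMARK_HYPOXIA = letters[3:9])
  expect_identical(filterGeneSets(sets, names(sets)), sets)
  two <- filterGeneSets(sets, c("HALLMARK_HEDGEHOG_SIGNALING",
                                "HALLMARK_E2F_TARGETS"))
  expect_identical(names(two), c("HALLMARK_HEDGEHOG_SIGNALING",
                                 "HALLMARK_E2F_TARGETS"))
  expect_error(filterGeneSets(sets, "HALLMARK_E2F_TARGET"),
               "HALLMARK_E2F_TARGETS")
  expect_error(filterGeneSets(sets, character(0)), "nonempty")
})

test_that("GMT round-trip and malformed-line rejection", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
  p <- tempfile(fileext = ".gmt")
  writeGmt(sets, p)
  expect_identical(readGmt(p), sets)
  writeLines(c("A\tdesc\tg1\tg2", "B\tdesc\tg9"), p)
  expect_error(readGmt(p), "line 2")
})
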