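constLog <- function(d) ImageVolume(array(0, d))

test_that("isotropic resampling preserves constants and sphere volume", {
  # constant volume stays constant through the spline
  cv <- ImageVolume(array(5, c(9, 9, 5)), spacing = c(2, 2, 4))
  cm <- RoiMask(array(TRUE, c(9, 9, 5)), spacing = c(2, 2, 4))
  rs <- resampleIsotropic(cv, cm, 1)
  expect_equal(voxelSpacing(rs$volume), c(1, 1, 1))
  expect_true(max(abs(voxelArray(rs$volume) - 5)) < 1e-9)

  # already-isotropic input: identity up to grid alignment
  v1 <- ImageVolume(array(stats::rnorm(8^3), c(8, 8, 8)))
  m1 <- RoiMask(array(TRUE, c(8, 8, 8)))
  r1 <- resampleIsotropic(v1, m1, 1)
  expect_equal(dim(voxelArray(r1$volume)), c(8L, 8L, 8L))
  expect_equal(voxelArray(r1$volume), voxelArray(v1), tolerance = 1e-9)

  # 2 mm sphere of radius 10 mm: resampled mask within 5% of (4/3)pi 10^3
  msk <- makeSphereMask(5, 15)                 # radius 5 vox @ 2 mm
  sv <- ImageVolume(array(0, dim(msk)), spacing = c(2, 2, 2))
  sm <- RoiMask(msk, spacing = c(2, 2, 2))
  rs2 <- resampleIsotropic(sv, sm, 1)
  volMm <- sum(morphMask(rs2$mask))            # 1 mm^3 voxels
  expect_equal(volMm, 4 / 3 * pi * 10^3, tolerance = 0.05)
})

test_that("HU re-segmentation removes out-of-window voxels, keeps bounds", {
  arr <- array(0, c(6, 6, 3))
  m <- array(TRUE, c(6, 6, 3))
  arr[1:5, 1, 1] <- -800                       # air
  arr[1, 2, 1] <- -150                         # boundary: retained
  arr[2, 2, 1] <- 180
  arr[3, 2, 1] <- 181                          # just outside
  vol <- ImageVolume(arr)
  rm2 <- resegmentIntensity(vol, RoiMask(m))
  expect_equal(sum(intensityMask(rm2)), prod(dim(arr)) - 5 - 1)
  expect_true(intensityMask(rm2)[1, 2, 1] && intensityMask(rm2)[2, 2, 1])
  expect_false(intensityMask(rm2)[3, 2, 1])
  expect_identical(morphMask(rm2), m)          # morphology untouched

  allAir <- ImageVolume(array(-900, c(4, 4, 4)))
  expect_error(resegmentIntensity(allAir, RoiMask(array(TRUE, c(4, 4, 4)))),
               "degenerate")
})

test_that("LoG bank: zero on constants and ramps, analytic at an impulse", {
  expect_lt(max(abs(voxelArray(logFilterBank(
    ImageVolume(array(3, c(12, 12, 12))))))), 1e-10)

  # linear ramp: interior response ~ 0 (away from the mirrored boundary)
  ramp <- array(rep(seq_len(26), each = 1), c(26, 26, 26))
  r <- voxelArray(logFilterBank(ImageVolume(ramp), sigmas = c(1, 2)))
  expect_lt(max(abs(r[10:17, 10:17, 10:17])), 1e-8)

  # central impulse: response equals the mean of the analytic LoG kernels
  d <- c(41, 41, 41)
  imp <- array(0, d); imp[21, 21, 21] <- 1
  sig <- c(2, 3, 4)
  resp <- voxelArray(logFilterBank(ImageVolume(imp), sigmas = sig))
  analytic <- mean(vapply(sig, function(s)
    (0 - 3 * s^2) / s^4 * (2 * pi * s^2)^(-3 / 2), numeric(1)))
  expect_equal(resp[21, 21, 21], analytic, tolerance = 0.02)

  expect_error(logFilterBank(ImageVolume(array(0, c(5, 5, 5)),
                                         spacing = c(4, 4, 4)),
                             sigmas = 1), "sigma")
})

test_that("fixed-bin-number discretisation follows the conventions", {
  arr <- array(rep(0:31, 2), c(8, 4, 2))
  m <- RoiMask(array(TRUE, c(8, 4, 2)))
  disc <- discretiseIntensities(ImageVolume(arr), m, 32)
  expect_identical(as.integer(disc), as.integer(arr) + 1L)

  const <- discretiseIntensities(ImageVolume(array(7, c(4, 4, 2))),
                                 RoiMask(array(TRUE, c(4, 4, 2))), 16)
  expect_true(all(const == 1L))

  two <- discretiseIntensities(
    ImageVolume(array(c(0, 10), c(2, 2, 2))),
    RoiMask(array(TRUE, c(2, 2, 2))), 2)
  expect_identical(sort(unique(as.integer(two))), c(1L, 2L))
})

test_that("morphology: cuboids fill their bounding box; sphere metrics", {
  arr <- array(40, c(10, 8, 6))
  msk <- array(FALSE, c(10, 8, 6)); msk[2:7, 2:5, 2:4] <- TRUE
  f <- extractFeatures(ImageVolume(arr), RoiMask(msk),
                       logVol = constLog(c(10, 8, 6)))
  expect_equal(unname(f["morph_vol_dens_aabb"]), 1.0)
  expect_equal(unname(f["morph_volume"]), 6 * 4 * 3 / 1000)
  expect_equal(unname(f["morph_surface_area"]),
               2 * (6 * 4 + 6 * 3 + 4 * 3))

  sph <- makeSphereMask(8, 21)
  fs <- extractFeatures(ImageVolume(array(0, dim(sph))), RoiMask(sph),
                        logVol = constLog(dim(sph)))
  expect_lt(fs[["morph_vol_dens_aabb"]], 0.60)   # ball in box: ~pi/6
  expect_gt(fs[["morph_vol_dens_aabb"]], 0.40)   # discrete sphere loss
  expect_equal(fs[["morph_max_diam"]], 16, tolerance = 0.1)
})

test_that("GLSZM matches hand enumeration on the documented toy grid", {
  # grey levels [[1,1,2],[2,2,2],[3,3,3]] on one slice, 26-connectivity
  g <- array(NA_integer_, c(3, 3, 1))
  g[1, , 1] <- c(1, 1, 2)
  g[2, , 1] <- c(2, 2, 2)
  g[3, , 1] <- c(3, 3, 3)
  z <- .glszmZones(as.integer(g), dim(g))
  z <- z[order(z[, 1]), , drop = FALSE]
  expect_equal(z[, 1], c(1L, 2L, 3L))
  expect_equal(z[, 2], c(2L, 4L, 3L))
  expect_equal(oracleGlnu(z), 1.0)
})

test_that("constant region yields exactly one size zone and szm_glnu 1", {
  arr <- array(12, c(5, 5, 3))
  f <- extractFeatures(ImageVolume(arr), RoiMask(array(TRUE, c(5, 5, 3))),
                       logVol = constLog(c(5, 5, 3)))
  expect_equal(unname(f["szm_glnu"]), 1.0)
  expect_equal(unname(f["szm_z_perc"]), 1 / (5 * 5 * 3))
})

test_that("GLSZM and GLCM agree with brute-force oracles on random grids", {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                c(1, -1, 0), c(1, 0, 1), c(1, 0, -1), c(0, 1, 1),
                c(0, 1, -1), c(1, 1, 1), c(1, 1, -1), c(1, -1, 1),
                c(1, -1, -1))
  for (s in 1:25) {
    withr::with_seed(s, {
      d <- sample(2:5, 3, replace = TRUE)
      g <- array(sample(1:4, prod(d), replace = TRUE), d)
      g[sample(length(g), round(length(g) * 0.2))] <- NA   # masked out
    })
    if (all(is.na(g))) next
    z <- .glszmZones(as.integer(g), as.integer(d))
    zo <- oracleZones(g)
    expect_equal(sort(paste(z[, 1], z[, 2])),
                 sort(paste(zo[, 1], zo[, 2])))
    cm <- .glcmCounts(as.integer(g), as.integer(d), 4L)
    for (di in c(1, 5, 10))
      expect_identical(as.integer(cm[[di]]),
                       as.integer(oracleGlcm(g, dirs[di, ], 4L)))
  }
})

test_that("p90 matches a sort-based percentile oracle", {
  for (s in 1:20) {
    x <- withr::with_seed(s, stats::rnorm(60 + s))
    arr <- array(c(x, numeric(64 - length(x) %% 64)),
                 c(8, 8, ceiling(length(x) / 64)))
    m <- array(FALSE, dim(arr)); m[seq_along(x)] <- TRUE
    f <- extractFeatures(ImageVolume(arr), RoiMask(m),
                         logVol = constLog(dim(arr)))
    srt <- sort(x)
    h <- (length(x) - 1) * 0.9 + 1
    oracle <- srt[floor(h)] + (h - floor(h)) *
      (srt[ceiling(h)] - srt[floor(h)])
    expect_equal(unname(f["stat_p90"]), oracle, tolerance = 1e-12)
  }
})

test_that("features are invariant to translation, 90-degree rotation and
           axis permutation on cubic grids", {
  strip <- function(v) { attributes(v) <- list(names = names(v)); v }
  # canvas large enough that the local-intensity spheres of all in-mask
  # voxels stay inside the image before and after translation
  n <- 26
  withr::with_seed(42, base <- array(stats::rnorm(n^3, 40, 20), rep(n, 3)))
  msk <- array(FALSE, rep(n, 3))
  ctr <- 12
  g <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  msk[g[sqrt(rowSums(sweep(g, 2, ctr)^2)) <= 3, ]] <- TRUE
  f0 <- strip(extractFeatures(ImageVolume(base), RoiMask(msk),
                              logVol = constLog(rep(n, 3))))
  # translation of volume and mask content together by 2 voxels
  tr <- array(base[c(n - 1, n, 1:(n - 2)), c(n - 1, n, 1:(n - 2)),
                   c(n - 1, n, 1:(n - 2))], rep(n, 3))
  tm <- array(msk[c(n - 1, n, 1:(n - 2)), c(n - 1, n, 1:(n - 2)),
                  c(n - 1, n, 1:(n - 2))], rep(n, 3))
  f1 <- strip(extractFeatures(ImageVolume(tr), RoiMask(tm),
                              logVol = constLog(rep(n, 3))))
  expect_equal(f1[names(f0)], f0, tolerance = 1e-9)
  # 90-degree rotation about z (content rotates with the mask)
  rot <- aperm(base, c(2, 1, 3))[n:1, , ]
  rm <- aperm(msk, c(2, 1, 3))[n:1, , ]
  f2 <- strip(extractFeatures(ImageVolume(rot), RoiMask(rm),
                              logVol = constLog(rep(n, 3))))
  expect_equal(f2[names(f0)], f0, tolerance = 1e-9)
  # axis permutation
  f3 <- strip(extractFeatures(ImageVolume(aperm(base, c(3, 1, 2))),
                              RoiMask(aperm(msk, c(3, 1, 2))),
                              logVol = constLog(rep(n, 3))))
  expect_equal(f3[names(f0)], f0, tolerance = 1e-9)
})

test_that("szm_glnu respects its Cauchy-Schwarz bounds on random grids", {
  for (s in 1:30) {
    withr::with_seed(s, {
      d <- sample(3:6, 3, replace = TRUE)
      g <- array(sample(1:5, prod(d), replace = TRUE), d)
    })
    z <- .glszmZones(as.integer(g), as.integer(d))
    ns <- nrow(z)
    glnu <- oracleGlnu(z)
    nLev <- length(unique(z[, 1]))
    expect_gte(glnu + 1e-12, ns / nLev)   # (sum s_i)^2/(N_s N_lev) w/ s_i=1
    expect_lte(glnu, ns)
  }
})

test_that("LoG-image morphology and texture are structurally absent", {
  arr <- array(stats::rnorm(5^3, 40, 15), c(5, 5, 5))
  f <- extractFeatures(ImageVolume(arr), RoiMask(array(TRUE, c(5, 5, 5))),
                       logVol = constLog(c(5, 5, 5)))
  md <- attr(f, "metadata")
  logFams <- unique(md$family[md$image == "log"])
  expect_true(all(logFams %in% c("statistical", "intensity_histogram")))
  expect_true("log_stat_p90" %in% names(f))
})

test_that("single-voxel ROI flags undefined texture as NaN", {
  arr <- array(0, c(4, 4, 4))
  m <- array(FALSE, c(4, 4, 4)); m[2, 2, 2] <- TRUE
  f <- extractFeatures(ImageVolume(arr), RoiMask(m),
                       logVol = constLog(c(4, 4, 4)))
  expect_true(is.nan(f[["cm_contrast"]]))
  expect_equal(unname(f["stat_var"]), 0)
})
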