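test_that("reference depth averages only valid samples in the window", {
  vals <- matrix(3000, 9, 9)
  img <- depthImage(vals)
  p <- depthFilterParams()
  # constant window
  expect_equal(referenceDepth(img, c(2, 4), c(6, 4), p), 3000)
  # a dropout inside the window is excluded from the mean
  vals[5, 5] <- 0
  expect_equal(referenceDepth(depthImage(vals), c(2, 4), c(6, 4), p), 3000)
  # out-of-range sample (> 7000) excluded as well
  vals[5, 5] <- 8000
  expect_equal(referenceDepth(depthImage(vals), c(2, 4), c(6, 4), p), 3000)
  # mixed window: mean over the valid eight of nine
  vals[5, 5] <- 0; vals[4, 4] <- 3090
  expect_equal(referenceDepth(depthImage(vals), c(2, 4), c(6, 4), p),
               (3090 + 7 * 3000) / 8)
})

test_that("empty reference windows error unless growth is enabled", {
  vals <- matrix(0, 11, 11)
  vals[1, 6] <- 2500                       # (u = 5, v = 0), outside the 3x3
  img <- depthImage(vals)
  expect_error(referenceDepth(img, c(3, 5), c(7, 5), depthFilterParams()),
               "no-reference")
  grown <- depthFilterParams(growReference = TRUE)
  expect_equal(referenceDepth(img, c(3, 5), c(7, 5), grown), 2500)
  expect_error(referenceDepth(depthImage(matrix(8000, 9, 9)), c(2, 4), c(6, 4),
                              depthFilterParams()), "no-reference")
  expect_error(referenceDepth(img, c(-20, 5), c(-18, 5), depthFilterParams()),
               "outside")
})

test_that("nearest-valid-depth search honours validity, tolerance and radius", {
  vals <- matrix(0, 21, 21)
  img0 <- depthImage(vals)
  p <- depthFilterParams()
  # center already valid
  vals1 <- vals; vals1[11, 11] <- 2950
  expect_equal(findNearestValidDepth(depthImage(vals1), 10, 10, 3000, p), 2950)
  # qualifying pixel at Chebyshev radius 2 is found
  vals2 <- vals; vals2[9, 13] <- 3100     # (u = 12, v = 8): radius 2 from (10, 10)
  expect_equal(findNearestValidDepth(depthImage(vals2), 10, 10, 3000, p), 3100)
  # candidates violating the validity band or the 500 mm tolerance are skipped
  vals3 <- vals; vals3[11, 11] <- 8000; vals3[10, 11] <- 3600; vals3[12, 11] <- 0
  expect_true(is.na(findNearestValidDepth(depthImage(vals3), 10, 10, 3000, p)))
  # tolerance boundary: exactly 500 mm off is accepted, 7000 is valid
  vals4 <- vals; vals4[11, 11] <- 7000
  expect_equal(findNearestValidDepth(depthImage(vals4), 10, 10, 6500, p), 7000)
  expect_true(is.na(findNearestValidDepth(depthImage(vals4), 10, 10, 6499, p)))
  # beyond maxRadius stays absent
  small <- depthFilterParams(maxRadius = 2L)
  vals5 <- vals; vals5[11, 16] <- 3000    # radius 5
  expect_true(is.na(findNearestValidDepth(depthImage(vals5), 10, 10, 3000, small)))
  expect_error(findNearestValidDepth(img0, 30, 10, 3000, p), "outside")
})

test_that("ring search returns the nearest hit where raster scan does not", {
  vals <- matrix(0, 21, 21)
  vals[11, 12] <- 3010                     # (u = 11, v = 10): radius 1
  vals[3, 3] <- 2990                       # (u = 2, v = 2): radius 8
  img <- depthImage(vals)
  expect_equal(findNearestValidDepth(img, 10, 10, 3000, depthFilterParams()),
               3010)
  # the literal nested loop hits the far top-left pixel first
  expect_equal(findNearestValidDepth(img, 10, 10, 3000,
                                     depthFilterParams(search = "raster")),
               2990)
  # deterministic tie-break inside a ring: smaller dy wins, then smaller dx
  vals2 <- matrix(0, 21, 21)
  vals2[10, 10] <- 2900                    # (9, 9): dy = -1, dx = -1
  vals2[12, 12] <- 3100                    # (11, 11): dy = +1, dx = +1
  img2 <- depthImage(vals2)
  r1 <- replicate(5, findNearestValidDepth(img2, 10, 10, 3000, depthFilterParams()))
  expect_true(all(r1 == 2900))
})

test_that("keypoint localization is exact on clean renders and flags gaps", {
  sc <- defaultScene()
  wk <- localizeKeypoints(sc$img, sc$kps, sc$K)
  # on a noiseless render the filter must not alter a qualifying raw depth;
  # a silhouette landmark whose rounded pixel falls just off the body is
  # recovered from the adjacent ring instead
  co <- keypointCoords(sc$kps)
  p0 <- depthFilterParams()
  for (nm in names(refinedDepths(wk))) {
    raw <- depthAt(sc$img, co[nm, 1], co[nm, 2])
    if (raw > p0@validMin && raw <= p0@validMax &&
        abs(raw - wk@referenceDepth) <= p0@refTolerance)
      expect_equal(refinedDepths(wk)[[nm]], raw, info = nm)
  }
  # on a scene with data everywhere the identity holds for all landmarks
  fw <- flatWallScene()
  wkF <- localizeKeypoints(fw$img, fw$kps, fw$K)
  expect_true(all(refinedDepths(wkF) == 3000))
  # refined depths satisfy the validity and tolerance constraints
  p <- depthFilterParams()
  d <- refinedDepths(wk)
  expect_true(all(d > p@validMin & d <= p@validMax))
  expect_true(all(abs(d - wk@referenceDepth) <= p@refTolerance))
  # Shoulder or Pin missing blocks the reference depth
  kpsNoPin <- keypointSet(keypointCoords(sc$kps)[c("Withers", "Sole", "Shoulder",
                                                   "Chest1", "Chest2", "Lumbar"), ])
  expect_error(localizeKeypoints(sc$img, kpsNoPin, sc$K), "missing-landmark")
  # a scene with no depth in the valid band cannot provide a reference
  wall <- depthImage(matrix(8000, 720, 1280))
  expect_error(localizeKeypoints(wall, sc$kps, sc$K), "no-reference")
})

test_that("dropout at a landmark is recovered from its neighbourhood", {
  sc <- defaultScene()
  base <- bodyHeight(localizeKeypoints(sc$img, sc$kps, sc$K))
  co <- keypointCoords(sc$kps)
  u0 <- round(co["Withers", 1]); v0 <- round(co["Withers", 2])
  vals <- depthValues(sc$img)
  vals[v0 + 1, u0 + 1] <- 0                   # zero the exact landmark pixel
  wk <- localizeKeypoints(depthImage(vals), sc$kps, sc$K)
  expect_true("Withers" %in% rownames(worldPoints(wk)))
  expect_lt(relErr(bodyHeight(wk), base), 0.01)
})
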