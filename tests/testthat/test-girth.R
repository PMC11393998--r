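test_that("intermediate points interpolate the chord linearly", {
  c1 <- c(0, 0, 0); c2 <- c(0, 10, 0)
  pts <- curvePoints(generateIntermediatePoints(c1, c2, 3))
  expect_equal(pts, cbind(X = c(0, 0, 0), Y = c(0, 5, 10), Z = c(0, 0, 0)))
  set.seed(9)
  a <- runif(3, -100, 100); b <- runif(3, -100, 100)
  pts2 <- curvePoints(generateIntermediatePoints(a, b, 17))
  expect_equal(pts2[1, ], a, ignore_attr = TRUE)
  expect_equal(pts2[17, ], b, ignore_attr = TRUE)
  dir <- (b - a) / sqrt(sum((b - a)^2))
  rel <- sweep(pts2, 2, a)
  crossNorm <- sqrt(rowSums(cbind(rel[, 2] * dir[3] - rel[, 3] * dir[2],
                                  rel[, 3] * dir[1] - rel[, 1] * dir[3],
                                  rel[, 1] * dir[2] - rel[, 2] * dir[1])^2))
  expect_lt(max(crossNorm), 1e-12 * max(abs(rel)))
  expect_error(generateIntermediatePoints(a, a, 5), "degenerate chord")
})

test_that("surface profiles follow the rendered cylinder flank", {
  sc <- defaultScene()
  wk <- localizeKeypoints(sc$img, sc$kps, sc$K)
  co <- keypointCoords(sc$kps)
  pr <- sampleSurfaceProfile(sc$img, co["Chest1", ], co["Chest2", ], 150,
                             sc$K, wk@referenceDepth)
  pts <- curvePoints(pr)
  # every sample must satisfy the torso-ellipse equation of the generator
  zAxis <- sc$pose@distance + sc$m@torsoSemiDepth
  yAxis <- sc$pose@height - sc$m@axisHeight
  resid <- sqrt(((pts[, 2] - yAxis) / sc$m@torsoSemiHeight)^2 +
                ((pts[, 3] - zAxis) / sc$m@torsoSemiDepth)^2) - 1
  expect_lt(max(abs(resid)) * sc$m@torsoSemiHeight, 3)  # within 3 mm of the surface
  # flat wall: the profile degenerates to a straight vertical segment
  fw <- flatWallScene()
  co2 <- keypointCoords(fw$kps)
  pr2 <- sampleSurfaceProfile(fw$img, co2["Chest1", ], co2["Chest2", ], 20,
                              fw$K, 3000)
  p2 <- curvePoints(pr2)
  expect_true(all(p2[, 3] == 3000))
  expect_lt(diff(range(p2[, 1])), 1e-9)
  expect_error(sampleSurfaceProfile(depthImage(matrix(0, 720, 1280)),
                                    co2["Chest1", ], co2["Chest2", ], 20,
                                    fw$K, 3000),
               "insufficient-profile")
})

test_that("RBF smoothing interpolates at zero and reproduces straight lines", {
  set.seed(2)
  pts <- cbind(seq(0, 100, length.out = 12), seq(5, 50, length.out = 12),
               3000 + 40 * sin(seq(0, pi, length.out = 12)))
  c0 <- curve3D(pts)
  # refineFactor 1 evaluates exactly at the knots: interpolation limit
  back <- curvePoints(rbfSmoothCurve(c0, smoothFactor = 0, refineFactor = 1L))
  expect_equal(back, pts, tolerance = 1e-6, ignore_attr = TRUE)
  # output count is refineFactor times the input count
  expect_identical(nrow(curvePoints(rbfSmoothCurve(c0, 1, 10L))), 120L)
  # collinear input stays collinear after densification
  lin <- cbind(seq(0, 100, length.out = 12), seq(5, 50, length.out = 12),
               seq(3000, 3100, length.out = 12))
  sm <- curvePoints(rbfSmoothCurve(curve3D(lin), 0, 10L))
  dir <- (lin[12, ] - lin[1, ]) / sqrt(sum((lin[12, ] - lin[1, ])^2))
  rel <- sweep(sm, 2, lin[1, ])
  crossNorm <- sqrt(rowSums(cbind(rel[, 2] * dir[3] - rel[, 3] * dir[2],
                                  rel[, 3] * dir[1] - rel[, 1] * dir[3],
                                  rel[, 1] * dir[2] - rel[, 2] * dir[1])^2))
  expect_lt(max(crossNorm / max(abs(lin))), 1e-6)
  expect_error(rbfSmoothCurve(curve3D(lin[1:2, ]), 1), "at least 3")
})

test_that("RBF smoothing attenuates an isolated outlier", {
  t <- seq(0, 1, length.out = 20)
  clean <- cbind(1000 * t, 100 * sin(pi * t), rep(3000, 20))
  noisy <- clean; noisy[10, 2] <- noisy[10, 2] + 50
  smNoisy <- curvePoints(rbfSmoothCurve(curve3D(noisy), 50, 10L))
  smClean <- curvePoints(rbfSmoothCurve(curve3D(clean), 50, 10L))
  # the smoothed deviation stays well below the raw 50 mm spike
  expect_lt(max(abs(smNoisy - smClean)), 25)
})

test_that("mirroring reflects across the chord plane", {
  th <- seq(-pi / 2, pi / 2, length.out = 30)
  semi <- cbind(rep(0, 30), 400 * sin(th) + 100, 3000 - 400 * cos(th))
  c1 <- semi[1, ]; c2 <- semi[30, ]
  mir <- curvePoints(mirrorHalfCurve(curve3D(semi), c1, c2, c(0, 0, 0)))
  # chord endpoints are fixed by the mirror (returned order is reversed)
  expect_equal(mir[1, ], c2, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(mir[30, ], c1, tolerance = 1e-9, ignore_attr = TRUE)
  # reflection midpoints lie on the chord plane (z = 3000 here)
  mid <- (semi + mir[rev(seq_len(30)), ]) / 2
  expect_lt(max(abs(mid[, 3] - 3000)), 1e-9 * 3000)
  # a semicircle bulging toward the camera completes to the full circle
  rad <- sqrt((mir[, 2] - 100)^2 + (mir[, 3] - 3000)^2)
  expect_lt(max(abs(rad - 400)), 1e-6)
  # literal parity mode negates camera-frame Y
  lit <- curvePoints(mirrorHalfCurve(curve3D(semi), c1, c2, c(0, 0, 0),
                                     frame = "literal_y"))
  expect_equal(lit[, 2], rev(-semi[, 2]))
  expect_error(mirrorHalfCurve(curve3D(semi), c1, c1, c(0, 0, 0)),
               "degenerate chord")
})

test_that("the closing spline interpolates and stays on a sampled circle", {
  th <- seq(0, 2 * pi, length.out = 17)[1:16]
  circ <- cbind(rep(0, 16), 400 * sin(th), 3000 + 400 * cos(th))
  dense <- closeCurveSpline(curve3D(circ), "periodic", 10L)
  pts <- curvePoints(dense)
  expect_true(dense@closed)
  expect_identical(nrow(pts), 160L)
  r <- sqrt(pts[, 2]^2 + (pts[, 3] - 3000)^2)
  expect_lt(max(abs(r - 400)), 0.5)
  # duplicate consecutive points are dropped before fitting
  dup <- circ[rep(1:16, each = 2), ]
  dense2 <- closeCurveSpline(curve3D(dup), "periodic", 10L)
  r2 <- sqrt(curvePoints(dense2)[, 2]^2 + (curvePoints(dense2)[, 3] - 3000)^2)
  expect_lt(max(abs(r2 - 400)), 0.5)
  expect_error(closeCurveSpline(curve3D(circ[1:3, ]), "periodic", 10L),
               "at least 4")
})

test_that("polyline length matches analytic perimeters and is isometric", {
  sq <- curve3D(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                closed = TRUE)
  expect_equal(polylineLength(sq), 4)
  th <- seq(0, 2 * pi, length.out = 1001)[1:1000]
  circ <- curve3D(cbind(rep(0, 1000), 500 * sin(th), 500 * cos(th)),
                  closed = TRUE)
  expect_lt(relErr(polylineLength(circ), 2 * pi * 500), 1e-4)
  # rigid rotation + translation leaves the length unchanged
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  moved <- curve3D(curvePoints(circ) %*% t(R) +
                   matrix(c(100, -50, 2000), 1000, 3, byrow = TRUE),
                   closed = TRUE)
  expect_equal(polylineLength(moved), polylineLength(circ), tolerance = 1e-9)
})

test_that("chest girth recovers the cylinder circumference in surface mode", {
  sc <- defaultScene()
  g <- chestGirth(sc$img, sc$kps, sc$K)
  expect_lt(relErr(g, sc$truth[["chest_girth_cm"]]), 0.03)
  # circular torso against the closed-form circumference
  m2 <- cattleModel(torsoSemiHeight = 350, torsoSemiDepth = 350)
  p <- cameraPose(3000); K <- defaultIntrinsics()
  img2 <- renderDepth(m2, p, K)
  kps2 <- groundTruthKeypoints(m2, p, K, img = img2)
  expect_lt(relErr(chestGirth(img2, kps2, K), 2 * pi * 350 / 10), 0.03)
})

test_that("chord mode degenerates to twice the chord with a warning", {
  sc <- defaultScene()
  cfg <- girthConfig(profileMode = "chord")
  expect_warning(g <- chestGirth(sc$img, sc$kps, sc$K, gconf = cfg),
                 "chord")
  wk <- localizeKeypoints(sc$img, sc$kps, sc$K)
  chord <- euclideanDistance(worldPoints(wk)["Chest1", ],
                             worldPoints(wk)["Chest2", ]) / 10
  expect_lt(relErr(g, 2 * chord), 0.05)
})

test_that("girth grows with torso radius across a seeded sweep", {
  K <- defaultIntrinsics(); p <- cameraPose(3000)
  radii <- c(300, 350, 400, 450)
  girths <- vapply(radii, function(r) {
    m <- cattleModel(torsoSemiHeight = r * 350 / 450, torsoSemiDepth = r)
    img <- renderDepth(m, p, K)
    kps <- groundTruthKeypoints(m, p, K, img = img)
    chestGirth(img, kps, K)
  }, numeric(1))
  expect_true(all(diff(girths) > 0))
})
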