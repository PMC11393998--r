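#' Construct chest-girth pipeline settings
#'
#' @param numPoints number of samples between Chest1 and Chest2 (>= 3).
#'   The default 150 keeps the steep near-silhouette ends of the profile
#'   well sampled, which stabilizes the girth-section estimate at close
#'   range.
#' @param smoothFactor RBF smoothing parameter; 0 gives exact
#'   interpolation, larger values pull the fit toward a smooth trend.
#' @param refineFactor densification multiplier applied at the RBF and
#'   spline resampling stages.
#' @param profileMode `"surface"` samples the depth map along the
#'   Chest1-Chest2 image line so the half curve follows the visible flank;
#'   `"chord"` uses the straight 3-D segment (degenerate parity mode).
#' @param mirrorFrame `"chord_local"` reflects across the plane spanned by
#'   the chord and the viewing direction; `"literal_y"` negates the
#'   camera-frame Y coordinate (parity mode for pre-centred inputs).
#' @param splineClosure `"periodic"` (closed girth loop) or `"open"`.
#' @param rbfEpsilon multiquadric shape parameter on the index grid.
#' @return A [GirthConfig-class] object.
#' @export
girthConfig <- function(numPoints = 150L, smoothFactor = 1.0, refineFactor = 10L,
                        profileMode = c("surface", "chord"),
                        mirrorFrame = c("chord_local", "literal_y"),
                        splineClosure = c("periodic", "open"),
                        rbfEpsilon = 1.0) {
  methods::new("GirthConfig", numPoints = as.integer(numPoints),
               smoothFactor = as.numeric(smoothFactor),
               refineFactor = as.integer(refineFactor),
               profileMode = match.arg(profileMode),
               mirrorFrame = match.arg(mirrorFrame),
               splineClosure = match.arg(splineClosure),
               rbfEpsilon = as.numeric(rbfEpsilon))
}

#' Construct a Curve3D
#'
#' @param points n x 3 numeric matrix of camera-frame coordinates in mm.
#' @param closed whether the curve is a closed loop.
#' @return A [Curve3D-class] object.
#' @export
curve3D <- function(points, closed = FALSE) {
  pts <- as.matrix(points)
  colnames(pts) <- c("X", "Y", "Z")
  methods::new("Curve3D", points = pts, closed = isTRUE(closed))
}

#' @describeIn curve3D the point matrix.
#' @param c a [Curve3D-class] object.
#' @export
curvePoints <- function(c) c@points

setMethod("show", "Curve3D", function(object) {
  cat(sprintf("Curve3D | %d points, %s\n", nrow(object@points),
              if (object@closed) "closed" else "open"))
})

#' Linearly spaced intermediate points between two 3-D points
#'
#' @param c1,c2 length-3 numeric endpoints (mm); must differ.
#' @param n number of points including both endpoints (>= 2).
#' @return An open [Curve3D-class] with n collinear points.
#' @export
generateIntermediatePoints <- function(c1, c2, n) {
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  if (n < 2L) stop("n must be >= 2")
  if (isTRUE(all.equal(c1, c2, tolerance = 0)) || sum((c2 - c1)^2) == 0)
    stop("degenerate chord: coincident endpoints")
  t <- seq(0, 1, length.out = n)
  curve3D(cbind(c1[1] + t * (c2[1] - c1[1]),
                c1[2] + t * (c2[2] - c1[2]),
                c1[3] + t * (c2[3] - c1[3])))
}

#' Sample the visible flank surface between the chest landmarks
#'
#' Places `n` pixels linearly along the image-space segment from the
#' Chest1 pixel to the Chest2 pixel, refines each sample's depth with the
#' same conditional filter used for the landmarks, and back-projects every
#' surviving sample to 3-D. Samples with no qualifying depth are dropped.
#'
#' @param img a [DepthImage-class] object.
#' @param c1px,c2px `c(u, v)` pixel positions of Chest1 and Chest2.
#' @param n number of samples along the segment (>= 3).
#' @param K a [CameraIntrinsics-class] object.
#' @param ref benchmark depth in mm.
#' @param params a [DepthFilterParams-class] object.
#' @return An open [Curve3D-class] of at least 3 surface points.
#' @export
sampleSurfaceProfile <- function(img, c1px, c2px, n, K, ref,
                                 params = depthFilterParams()) {
  if (n < 3L) stop("need at least 3 profile samples")
  w <- imageWidth(img); h <- imageHeight(img)
  chk <- rbind(as.numeric(c1px[1:2]), as.numeric(c2px[1:2]))
  if (any(chk[, 1] < 0 | chk[, 1] >= w | chk[, 2] < 0 | chk[, 2] >= h))
    stop("chest pixels outside the image")
  t <- seq(0, 1, length.out = n)
  us <- chk[1, 1] + t * (chk[2, 1] - chk[1, 1])
  vs <- chk[1, 2] + t * (chk[2, 2] - chk[1, 2])
  pts <- NULL
  for (i in seq_len(n)) {
    d <- findNearestValidDepth(img, us[i], vs[i], ref, params)
    if (is.na(d)) next
    pts <- rbind(pts, pixelToWorld(us[i], vs[i], d, K))
  }
  if (is.null(pts) || nrow(pts) < 3L)
    stop("insufficient-profile: fewer than 3 valid depth samples along the chest line")
  curve3D(pts)
}

## Multiquadric RBF fit of one coordinate against the sample index.
## The kernel phi(r) = sqrt(r^2 + eps^2) is conditionally positive
## definite of order 1, so the fit carries a linear polynomial tail; this
## makes straight-line data reproduce exactly. Smoothing follows the
## kernel-ridge convention A - s*I on the kernel block (s = 0 therefore
## interpolates).
rbfFit1d <- function(y, smooth, eps) {
  n <- length(y)
  x <- seq_len(n) - 1
  A <- sqrt(outer(x, x, "-")^2 + eps^2) - diag(smooth, n)
  P <- cbind(1, x)
  M <- rbind(cbind(A, P), cbind(t(P), matrix(0, 2, 2)))
  rhs <- c(y, 0, 0)
  coef <- tryCatch(solve(M, rhs), error = function(e) {
    solve(M + diag(1e-8 * max(abs(M)), n + 2L), rhs)  # regularized fallback
  })
  function(t) {
    B <- sqrt(outer(t, x, "-")^2 + eps^2)
    as.numeric(B %*% coef[seq_len(n)] + coef[n + 1L] + t * coef[n + 2L])
  }
}

#' Smooth and densify a curve with multiquadric RBF fits
#'
#' Each coordinate is fit independently as a 1-D function of the sample
#' index with a multiquadric kernel and smoothing parameter, then
#' evaluated on a `refineFactor`-times denser index grid. With
#' `smoothFactor = 0` the fit interpolates the input exactly.
#'
#' @param c an open [Curve3D-class] with at least 3 points.
#' @param smoothFactor smoothing parameter (0 = exact interpolation).
#' @param refineFactor densification multiplier (output count =
#'   `refineFactor * n`).
#' @param eps multiquadric shape parameter on the index grid.
#' @return A densified open [Curve3D-class].
#' @export
rbfSmoothCurve <- function(c, smoothFactor = 1.0, refineFactor = 10L, eps = 1.0) {
  pts <- c@points
  n <- nrow(pts)
  if (n < 3L) stop("need at least 3 points to smooth")
  tNew <- seq(0, n - 1, length.out = n * refineFactor)
  out <- vapply(1:3, function(j) rbfFit1d(pts[, j], smoothFactor, eps)(tNew),
                numeric(length(tNew)))
  curve3D(out)
}

#' Mirror a half curve across the girth plane
#'
#' Completes the hidden half of the girth loop by reflection. In the
#' default `chord_local` frame an orthonormal basis is built at the chord
#' midpoint O: e1 along the chord `c2 - c1`, e2 the component of the
#' viewing direction (`cameraOrigin - O`) orthogonal to e1; each point's
#' e2 coordinate is negated. Points on the chord are fixed by the mirror.
#' The mirrored sequence is returned in reversed order so that
#' concatenating the upper curve with it winds consistently around the
#' closed loop. `literal_y` instead negates the camera-frame Y coordinate
#' (parity mode, geometric only for pre-centred inputs).
#'
#' @param c an open [Curve3D-class] ordered from `c1` to `c2`.
#' @param c1,c2 length-3 chord endpoints (mm).
#' @param cameraOrigin camera position in the working frame (default the
#'   camera-frame origin).
#' @param frame `"chord_local"` or `"literal_y"`.
#' @return The mirrored [Curve3D-class], reversed.
#' @export
mirrorHalfCurve <- function(c, c1, c2, cameraOrigin = c(0, 0, 0),
                            frame = c("chord_local", "literal_y")) {
  frame <- match.arg(frame)
  pts <- c@points
  if (frame == "literal_y") {
    m <- pts
    m[, 2] <- -m[, 2]
    return(curve3D(m[rev(seq_len(nrow(m))), , drop = FALSE]))
  }
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  chord <- c2 - c1
  len <- sqrt(sum(chord^2))
  if (len < 1e-9) stop("degenerate chord: coincident endpoints")
  e1 <- chord / len
  O <- (c1 + c2) / 2
  wv <- as.numeric(cameraOrigin) - O
  wPerp <- wv - sum(wv * e1) * e1
  wn <- sqrt(sum(wPerp^2))
  if (wn < 1e-9) stop("degenerate frame: viewing direction parallel to the chord")
  e2 <- wPerp / wn
  q <- as.numeric((pts - matrix(O, nrow(pts), 3, byrow = TRUE)) %*% e2)
  m <- pts - 2 * outer(q, e2)
  curve3D(m[rev(seq_len(nrow(m))), , drop = FALSE])
}

#' Close a curve with an interpolating cubic spline
#'
#' Fits an interpolating parametric cubic spline (no smoothing) through
#' the points over chord-length parameterization and resamples it at
#' `refineFactor * n` uniformly spaced parameter values. With
#' `closure = "periodic"` the spline wraps so the last point joins the
#' first smoothly. Consecutive duplicate points are removed before
#' fitting.
#'
#' @param c a [Curve3D-class] with at least 4 distinct points.
#' @param closure `"periodic"` or `"open"`.
#' @param refineFactor densification multiplier.
#' @return A dense [Curve3D-class]; closed when `closure = "periodic"`.
#' @export
closeCurveSpline <- function(c, closure = c("periodic", "open"), refineFactor = 10L) {
  closure <- match.arg(closure)
  pts <- c@points
  n0 <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n0, , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-6)
  pts <- pts[keep, , drop = FALSE]
  if (closure == "periodic" &&
      sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2)) <= 1e-6)
    pts <- pts[-nrow(pts), , drop = FALSE]
  m <- nrow(pts)
  if (m < 4L) stop("need at least 4 distinct points for the cubic spline")
  nOut <- refineFactor * n0
  # centripetal parameterization (square root of chord length): damps the
  # outward overshoot of cubic interpolation across the long bridging
  # spans where the mirrored half joins the sampled half; identical to
  # chord length for evenly spaced points
  if (closure == "periodic") {
    ext <- rbind(pts, pts[1, ])
    tt <- c(0, cumsum(sqrt(rowSums((ext[-1, , drop = FALSE] -
                                    ext[-(m + 1L), , drop = FALSE])^2))^0.5))
    tEval <- seq(0, tt[m + 1L], length.out = nOut + 1L)[seq_len(nOut)]
    out <- vapply(1:3, function(j)
      stats::splinefun(tt, ext[, j], method = "periodic")(tEval),
      numeric(nOut))
    curve3D(out, closed = TRUE)
  } else {
    tt <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                                    pts[-m, , drop = FALSE])^2))^0.5))
    tEval <- seq(0, tt[m], length.out = nOut)
    out <- vapply(1:3, function(j)
      stats::splinefun(tt, pts[, j], method = "natural")(tEval),
      numeric(nOut))
    curve3D(out, closed = FALSE)
  }
}

#' Polyline length of a curve
#'
#' Sum of consecutive segment lengths; for a closed curve the last-to-first
#' segment is included.
#'
#' @param c a [Curve3D-class] object.
#' @return Length in mm.
#' @export
polylineLength <- function(c) {
  pts <- c@points
  n <- nrow(pts)
  len <- sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-n, , drop = FALSE])^2)))
  if (c@closed) len <- len + sqrt(sum((pts[1, ] - pts[n, ])^2))
  len
}

#' Chest girth in cm
#'
#' Full girth pipeline: sample the half profile between Chest1 and Chest2
#' (visible flank surface by default), smooth and densify it with
#' multiquadric RBF fits, mirror it across the girth plane to complete the
#' hidden half, close the loop with an interpolating cubic spline, and sum
#' the polyline length.
#'
#' @param img a [DepthImage-class] object.
#' @param kps a [KeypointSet-class] object with Chest1 and Chest2 marked.
#' @param K a [CameraIntrinsics-class] object.
#' @param dparams a [DepthFilterParams-class] object.
#' @param gconf a [GirthConfig-class] object.
#' @param wk optional pre-computed [WorldKeypoints-class] (avoids
#'   recomputing the reference depth).
#' @return Chest girth in cm.
#' @export
chestGirth <- function(img, kps, K, dparams = depthFilterParams(),
                       gconf = girthConfig(), wk = NULL) {
  vis <- kps@visibility
  if (vis[["Chest1"]] == 0L || vis[["Chest2"]] == 0L)
    stop("missing-landmark: Chest1, Chest2")
  if (is.null(wk)) wk <- localizeKeypoints(img, kps, K, dparams)
  requireLandmarks(wk, c("Chest1", "Chest2"))
  ref <- wk@referenceDepth
  profile <- if (gconf@profileMode == "surface") {
    withStage("profile", sampleSurfaceProfile(
      img, kps@coords["Chest1", ], kps@coords["Chest2", ],
      gconf@numPoints, K, ref, dparams))
  } else {
    warning("chord profile mode: the girth degenerates to a flat loop of ",
            "about twice the Chest1-Chest2 distance")
    withStage("profile", generateIntermediatePoints(
      wk@points["Chest1", ], wk@points["Chest2", ], gconf@numPoints))
  }
  sm <- withStage("rbf-smoothing", rbfSmoothCurve(
    profile, gconf@smoothFactor, gconf@refineFactor, gconf@rbfEpsilon))
  spts <- sm@points
  c1 <- spts[1, ]; c2 <- spts[nrow(spts), ]
  origin <- c(0, 0, 0)
  if (gconf@mirrorFrame == "chord_local") {
    # Mirror across the vertical diameter of the estimated girth section
    # rather than across the raw endpoint chord: at finite camera
    # distance the visible flank arc subtends less than half the section
    # (the silhouette is bounded by the tangent rays), so reflecting
    # across the endpoint chord systematically shortens the loop and
    # makes it distance-dependent. The section centre and semi-axes come
    # from an axis-aligned ellipse fit of the raw profile; the mirror
    # chord is then the vertical diameter and the viewing direction is
    # taken level with the centre, making the reflection a pure
    # depth-axis flip that maps the fitted section onto itself.
    fitE <- fitSectionEllipse(profile@points)
    if (!is.null(fitE)) {
      xMid <- (c1[1] + c2[1]) / 2
      c1 <- c(xMid, fitE$centreY - fitE$semiY, fitE$centreZ)
      c2 <- c(xMid, fitE$centreY + fitE$semiY, fitE$centreZ)
      origin <- c(xMid, fitE$centreY, 0)
    }
  }
  mirrored <- withStage("mirroring", mirrorHalfCurve(
    sm, c1, c2, origin, gconf@mirrorFrame))
  loop <- curve3D(rbind(spts, mirrored@points))
  dense <- withStage("spline-closure", closeCurveSpline(
    loop, gconf@splineClosure, gconf@refineFactor))
  polylineLength(dense) / 10
}

## Axis-aligned ellipse fit of the girth cross-section in the camera
## frame. A standing animal viewed square-on has its section axes aligned
## with the camera frame (vertical Y by gravity, depth Z along the view),
## so flank samples satisfy the conic Y^2 + c*Z^2 + d*Y + e*Z + f = 0,
## linear in (c, d, e, f). The unconstrained conic fit is accurate on
## clean profiles but slides along a curvature ridge under heavy depth
## noise, so it is used only when the profile's measured depth noise is
## small and the result is plausible for a torso section; otherwise a
## constrained fallback fixes the vertical centre
## and semi-axis from the profile extent and regresses Z on the ellipse
## ordinate, which is robust to noise. Returns NULL when the profile is
## degenerate (e.g. a straight chord) or no plausible fit exists.
fitSectionEllipse <- function(pts) {
  Y <- pts[, 2]; Z <- pts[, 3]
  yHalf <- (max(Y) - min(Y)) / 2
  if (yHalf < 50 || stats::sd(Z) < 1e-6) return(NULL)
  plausible <- function(p) {
    !anyNA(p) && all(is.finite(unlist(p))) &&
      p$semiY > 50 && p$semiY < 2000 && p$semiZ > 50 && p$semiZ < 2000 &&
      p$semiZ / p$semiY > 0.4 && p$semiZ / p$semiY < 2.5 &&
      p$semiY / yHalf > 0.6 && p$semiY / yHalf < 1.8 &&
      p$centreZ > min(Z)
  }
  # high-frequency depth noise along the profile (second differences of a
  # smooth arc are dominated by sensor noise; the curvature term is tiny)
  noiseEst <- if (length(Z) > 4) stats::sd(diff(Z, differences = 2)) / sqrt(6)
              else 0
  if (noiseEst <= 3) {
    fit <- tryCatch(stats::lm.fit(cbind(Z * Z, Y, Z, 1), -Y * Y)$coefficients,
                    error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit) && fit[1] > 1e-12) {
      cy <- -fit[2] / 2
      cz <- -fit[3] / (2 * fit[1])
      s2 <- cy^2 + fit[1] * cz^2 - fit[4]
      if (s2 > 0) {
        cand <- list(centreY = unname(cy), centreZ = unname(cz),
                     semiY = sqrt(s2), semiZ = sqrt(s2 / fit[1]))
        if (plausible(cand)) return(cand)
      }
    }
  }
  # constrained fallback: the chord spans the section height
  cy <- (max(Y) + min(Y)) / 2
  a <- 1.05 * yHalf                       # entry points sit just short of the apexes
  w <- sqrt(pmax(0, 1 - ((Y - cy) / a)^2))
  reg <- tryCatch(stats::lm.fit(cbind(1, w), Z)$coefficients,
                  error = function(e) NULL)
  if (is.null(reg) || anyNA(reg) || reg[2] >= 0) return(NULL)
  cand <- list(centreY = cy, centreZ = unname(reg[1]), semiY = a,
               semiZ = unname(-reg[2]))
  if (plausible(cand)) return(cand)
  NULL
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("girth stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}
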