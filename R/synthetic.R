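#' Build a parametric cattle model
#'
#' Constructs the synthetic animal: an elliptical-cylinder torso with its
#' axis horizontal along the body, four vertical circular-cylinder legs,
#' and the seven landmark anchors placed analytically on the surface.
#' Defaults describe a medium-frame adult animal (torso 1.5 m long,
#' cross-section semi-axes 450 x 350 mm, axis 900 mm above ground).
#'
#' Anchor placement: Withers on the torso topline above the front legs
#' (plus `withersOffset`), Sole at ground level on the near front leg,
#' Shoulder and Pin at the front/rear ends of the flank at axis height
#' (inset 10 mm from the boundary so they lie strictly on the surface),
#' Chest1 and Chest2 at the top and bottom of the girth cross-section
#' (a plane `girthOffset` behind the front-leg line), and Lumbar on the
#' rear topline.
#'
#' @param torsoLength torso length along the body (mm).
#' @param torsoSemiHeight vertical semi-axis of the torso ellipse (mm).
#' @param torsoSemiDepth horizontal (camera-axis) semi-axis (mm).
#' @param axisHeight torso axis height above ground (mm).
#' @param legRadius leg cylinder radius (mm).
#' @param legInset distance of leg centres from the torso ends (mm).
#' @param legPairOffset lateral half-spacing of each leg pair (mm).
#' @param withersOffset Withers anchor height above the torso top (mm).
#' @param girthOffset girth plane distance behind the front legs (mm).
#' @return A [CattleModel-class] object.
#' @export
cattleModel <- function(torsoLength = 1500, torsoSemiHeight = 350,
                        torsoSemiDepth = 450, axisHeight = 900,
                        legRadius = 60, legInset = 150, legPairOffset = 0,
                        withersOffset = 0, girthOffset = 150) {
  xFore <- torsoLength / 2 - legInset
  xRear <- -torsoLength / 2 + legInset
  xGirth <- xFore - girthOffset
  top <- axisHeight + torsoSemiHeight
  endInset <- 10  # keeps the anchor pixels strictly on the rendered surface
  anchors <- rbind(
    Withers  = c(xFore, top + withersOffset, 0),
    Sole     = c(xFore, 0, legPairOffset + legRadius),
    Shoulder = c(torsoLength / 2 - endInset, axisHeight, torsoSemiDepth),
    Pin      = c(-torsoLength / 2 + endInset, axisHeight, torsoSemiDepth),
    Chest1   = c(xGirth, top, 0),
    Chest2   = c(xGirth, axisHeight - torsoSemiHeight, 0),
    Lumbar   = c(xRear + 150, top, 0))
  colnames(anchors) <- c("x", "y", "z")
  methods::new("CattleModel", torsoLength = as.numeric(torsoLength),
               torsoSemiHeight = as.numeric(torsoSemiHeight),
               torsoSemiDepth = as.numeric(torsoSemiDepth),
               axisHeight = as.numeric(axisHeight),
               legRadius = as.numeric(legRadius), legInset = as.numeric(legInset),
               legPairOffset = as.numeric(legPairOffset),
               withersOffset = as.numeric(withersOffset),
               girthOffset = as.numeric(girthOffset), anchors = anchors)
}

#' Perimeter of an ellipse by adaptive quadrature
#'
#' Arc-length integral of the ellipse with semi-axes a (horizontal) and b
#' (vertical), evaluated by adaptive quadrature to about 1e-10 relative
#' accuracy.
#'
#' @param a,b semi-axes (a > 0, b >= 0).
#' @return The perimeter, in the units of a and b.
#' @export
ellipsePerimeter <- function(a, b) {
  stopifnot(a > 0, b >= 0)
  stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                   0, 2 * pi, rel.tol = 1e-12, abs.tol = 0,
                   subdivisions = 400L)$value
}

#' Analytic ground-truth dimensions of a cattle model
#'
#' Body height and body oblique length are anchor-to-anchor distances,
#' lumbar height is the Lumbar anchor's height above ground, and chest
#' girth is the torso-ellipse perimeter by quadrature.
#'
#' @param m a [CattleModel-class] object.
#' @return A [BodyMeasurements-class] object (values in cm).
#' @export
trueDimensions <- function(m) {
  a <- m@anchors
  vals <- c(
    body_height_cm = euclideanDistance(a["Withers", ], a["Sole", ]) / 10,
    lumbar_height_cm = a["Lumbar", "y"] / 10,
    body_length_cm = euclideanDistance(a["Shoulder", ], a["Pin", ]) / 10,
    chest_girth_cm = ellipsePerimeter(m@torsoSemiDepth, m@torsoSemiHeight) / 10)
  methods::new("BodyMeasurements", values = vals, depths = numeric(0),
               notes = character(0))
}

#' Construct a synthetic camera pose
#'
#' Side view: the optical axis is horizontal and perpendicular to the
#' body, emulating a tripod-mounted depth camera about 1 m above ground at
#' 1-5 m stand-off.
#'
#' @param distance camera stand-off to the near flank surface (mm).
#' @param height camera height above ground (mm).
#' @return A [CameraPose-class] object.
#' @export
cameraPose <- function(distance = 3000, height = 1000) {
  methods::new("CameraPose", distance = as.numeric(distance),
               height = as.numeric(height))
}

#' Default synthetic camera intrinsics
#'
#' A 1280x720 synthetic camera with fx = fy = 700 px and centred principal
#' point. These are not the intrinsics of any physical device; real use
#' requires the camera's own calibration.
#'
#' @return A [CameraIntrinsics-class] object.
#' @export
syntheticIntrinsics <- function() {
  cameraIntrinsics(700, 700, 640, 360, 1280, 720)
}

modelAnchorsCamera <- function(m, pose) {
  a <- m@anchors
  zAxis <- pose@distance + m@torsoSemiDepth
  cbind(X = a[, "x"], Y = pose@height - a[, "y"], Z = zAxis - a[, "z"])
}

#' Render the depth image of a cattle model
#'
#' Ray-casts every pixel against the torso, legs and ground plane and
#' stores the Z coordinate (along the optical axis, mm) of the nearest
#' positive hit, rounded to integer millimeters to mimic 16-bit sensor
#' storage. Pixels with no hit within 7000 mm are 0.
#'
#' @param m a [CattleModel-class] object.
#' @param pose a [CameraPose-class] object; the camera must stand clear of
#'   the animal.
#' @param K a [CameraIntrinsics-class] object.
#' @param farLimit maximum encoded depth (mm).
#' @return A [DepthImage-class] object.
#' @export
renderDepth <- function(m, pose, K, farLimit = 7000) {
  if (pose@distance <= 0)
    stop("pose error: camera placed inside the animal volume")
  w <- as.integer(K@width); h <- as.integer(K@height)
  dx <- matrix((seq_len(w) - 1 - K@cx) / K@fx, h, w, byrow = TRUE)
  dy <- matrix((seq_len(h) - 1 - K@cy) / K@fy, h, w)
  tBest <- matrix(Inf, h, w)

  # torso: elliptical cylinder, axis along X at (Yc0, Zc0)
  Yc0 <- pose@height - m@axisHeight
  Zc0 <- pose@distance + m@torsoSemiDepth
  bv <- m@torsoSemiHeight; bh <- m@torsoSemiDepth
  A <- (dy / bv)^2 + 1 / bh^2
  B <- -2 * (dy * Yc0 / bv^2 + Zc0 / bh^2)
  Cc <- Yc0^2 / bv^2 + Zc0^2 / bh^2 - 1
  disc <- B^2 - 4 * A * Cc
  hit <- disc >= 0
  tt <- matrix(Inf, h, w)
  tt[hit] <- (-B[hit] - sqrt(disc[hit])) / (2 * A[hit])
  bad <- !is.finite(tt) | tt <= 0 | abs(tt * dx) > m@torsoLength / 2
  tt[bad] <- Inf
  tBest <- pmin(tBest, tt)

  # legs: vertical circular cylinders between axis height and the ground
  xFore <- m@torsoLength / 2 - m@legInset
  xRear <- -m@torsoLength / 2 + m@legInset
  for (xl in c(xFore, xRear)) for (zl in c(m@legPairOffset, -m@legPairOffset)) {
    Zcl <- pose@distance + m@torsoSemiDepth - zl
    A <- dx^2 + 1
    B <- -2 * (dx * xl + Zcl)
    Cc <- xl^2 + Zcl^2 - m@legRadius^2
    disc <- B^2 - 4 * A * Cc
    hit <- disc >= 0
    tt <- matrix(Inf, h, w)
    tt[hit] <- (-B[hit] - sqrt(disc[hit])) / (2 * A[hit])
    yHit <- tt * dy
    bad <- !is.finite(tt) | tt <= 0 | yHit < Yc0 | yHit > pose@height
    tt[bad] <- Inf
    tBest <- pmin(tBest, tt)
  }

  # ground plane at camera height below the camera
  tg <- ifelse(dy > 0, pose@height / dy, Inf)
  tBest <- pmin(tBest, tg)

  depth <- round(tBest)
  depth[!is.finite(tBest) | tBest > farLimit] <- 0
  depthImage(depth)
}

#' Ground-truth keypoints of a rendered scene
#'
#' Projects the landmark anchors through the pinhole camera. Visibility is
#' 2 when the projection falls inside the frame and nothing stands in
#' front of the anchor (the rendered depth at its pixel is not more than
#' `occlusionTol` nearer than the anchor), 1 when occluded, and 0 when the
#' anchor is outside the frame or behind the camera.
#'
#' @param m a [CattleModel-class] object.
#' @param pose a [CameraPose-class] object.
#' @param K a [CameraIntrinsics-class] object.
#' @param img optional pre-rendered [DepthImage-class] of the same scene
#'   (rendered on demand otherwise).
#' @param occlusionTol depth margin (mm) before a nearer rendered surface
#'   counts as an occluder; the default absorbs the surface curvature
#'   within the rounded pixel at silhouette landmarks.
#' @return A [KeypointSet-class] object with the projected bounding box.
#' @export
groundTruthKeypoints <- function(m, pose, K, img = NULL, occlusionTol = 250) {
  if (is.null(img)) img <- renderDepth(m, pose, K)
  anc <- modelAnchorsCamera(m, pose)
  coords <- matrix(NA_real_, 7L, 2L, dimnames = list(landmarkNames(), c("u", "v")))
  vis <- stats::setNames(rep(0L, 7L), landmarkNames())
  for (nm in landmarkNames()) {
    p <- anc[nm, ]
    if (p[["Z"]] <= 0) next
    uv <- worldToPixel(p, K)[1, ]
    if (uv["u"] < 0 || uv["u"] >= K@width || uv["v"] < 0 || uv["v"] >= K@height) next
    coords[nm, ] <- uv[c("u", "v")]
    d <- depthAt(img, uv["u"], uv["v"])
    vis[nm] <- if (d > 0 && d < p[["Z"]] - occlusionTol) 1L else 2L
  }
  # projected body box: torso extent plus legs down to the ground
  top <- pose@height - (m@axisHeight + m@torsoSemiHeight + m@withersOffset)
  zAxis <- pose@distance + m@torsoSemiDepth
  corners <- rbind(c(-m@torsoLength / 2, top, zAxis),
                   c(m@torsoLength / 2, top, zAxis),
                   c(-m@torsoLength / 2, pose@height, zAxis),
                   c(m@torsoLength / 2, pose@height, zAxis))
  uvc <- worldToPixel(corners, K)
  bbox <- c(min(uvc[, "u"]), min(uvc[, "v"]),
            max(uvc[, "u"]) - min(uvc[, "u"]), max(uvc[, "v"]) - min(uvc[, "v"]))
  keypointSet(coords, visibility = vis, bbox = bbox, image = "")
}

#' Construct a depth-noise specification
#'
#' @param dropoutRate fraction of pixels zeroed at random.
#' @param jitterSd additive Gaussian depth noise, standard deviation (mm).
#' @param holeCount,holeRadius number and pixel radius of circular blob
#'   dropouts.
#' @param seed RNG seed for a reproducible noise field.
#' @return A [NoiseSpec-class] object.
#' @export
noiseSpec <- function(dropoutRate = 0, jitterSd = 0, holeCount = 0L,
                      holeRadius = 0, seed = 1L) {
  methods::new("NoiseSpec", dropoutRate = as.numeric(dropoutRate),
               jitterSd = as.numeric(jitterSd), holeCount = as.integer(holeCount),
               holeRadius = as.numeric(holeRadius), seed = as.integer(seed))
}

withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Inject depth-sensor noise into a depth image
#'
#' Applies, in order: random pixel dropout, circular blob holes, and
#' additive Gaussian depth jitter on the remaining valid pixels (rounded
#' and clamped to [0, 7000] mm). The noise field is a deterministic
#' function of the seed.
#'
#' @param img a [DepthImage-class] object.
#' @param spec a [NoiseSpec-class] object.
#' @return A noisy [DepthImage-class] object.
#' @export
injectDepthNoise <- function(img, spec) {
  withLocalSeed(spec@seed, {
    v <- img@values
    h <- nrow(v); w <- ncol(v)
    if (spec@dropoutRate > 0)
      v[stats::runif(h * w) < spec@dropoutRate] <- 0
    if (spec@holeCount > 0L && spec@holeRadius > 0) {
      cu <- stats::runif(spec@holeCount, 0, w - 1)
      cv <- stats::runif(spec@holeCount, 0, h - 1)
      cols <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
      rows <- matrix(seq_len(h) - 1, h, w)
      for (i in seq_len(spec@holeCount))
        v[(cols - cu[i])^2 + (rows - cv[i])^2 <= spec@holeRadius^2] <- 0
    }
    if (spec@jitterSd > 0) {
      valid <- v > 0
      v[valid] <- pmin(7000, pmax(0, round(v[valid] +
        stats::rnorm(sum(valid), 0, spec@jitterSd))))
    }
    depthImage(v)
  })
}

#' Draw a random cattle model from realistic ranges
#'
#' Samples torso and leg dimensions uniformly from adult-animal ranges
#' (torso length 1.3-1.7 m, semi-axes 380-480 x 300-400 mm, axis height
#' 0.8-1.0 m) using the current RNG state.
#'
#' @return A [CattleModel-class] object.
#' @export
randomCattleModel <- function() {
  cattleModel(torsoLength = stats::runif(1, 1300, 1700),
              torsoSemiHeight = stats::runif(1, 300, 400),
              torsoSemiDepth = stats::runif(1, 380, 480),
              axisHeight = stats::runif(1, 800, 1000),
              legRadius = stats::runif(1, 50, 70))
}

setMethod("show", "CattleModel", function(object) {
  cat(sprintf(paste0("CattleModel | torso %g mm x (%g, %g) mm, axis %g mm ",
                     "above ground\n"),
              object@torsoLength, object@torsoSemiDepth,
              object@torsoSemiHeight, object@axisHeight))
})
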