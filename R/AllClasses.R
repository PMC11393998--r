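#' The seven body landmarks
#'
#' Canonical landmark names, in the fixed order used by the COCO-style
#' flattened keypoint encoding: Withers, Sole, Shoulder, Pin, Chest1,
#' Chest2, Lumbar.
#'
#' @return Character vector of length 7.
#' @export
landmarkNames <- function() {
  c("Withers", "Sole", "Shoulder", "Pin", "Chest1", "Chest2", "Lumbar")
}

#' @title CameraIntrinsics: pinhole camera parameters
#'
#' @description Focal lengths and principal point of a rectified depth
#' camera, in pixels, plus the image size. These are the parameters of the
#' intrinsic matrix K used to move between pixel and camera-frame
#' coordinates.
#'
#' @slot fx,fy focal lengths in pixels (> 0).
#' @slot cx,cy principal point (column, row) in pixels, inside the image.
#' @slot width,height image size in pixels.
#' @export
setClass("CameraIntrinsics",
  representation(fx = "numeric", fy = "numeric", cx = "numeric",
                 cy = "numeric", width = "numeric", height = "numeric"),
  validity = function(object) {
    msg <- character()
    for (s in c("fx", "fy", "cx", "cy", "width", "height")) {
      v <- slot(object, s)
      if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste0(s, " must be a finite scalar"))
    }
    if (!length(msg)) {
      if (object@fx <= 0 || object@fy <= 0) msg <- c(msg, "fx and fy must be > 0")
      if (object@width < 1 || object@height < 1) msg <- c(msg, "image size must be at least 1x1")
      if (object@cx < 0 || object@cx >= object@width) msg <- c(msg, "cx must lie in [0, width)")
      if (object@cy < 0 || object@cy >= object@height) msg <- c(msg, "cy must lie in [0, height)")
    }
    if (length(msg)) msg else TRUE
  })

#' @title DepthImage: a millimeter-valued range map
#'
#' @description Single-channel depth image. Each sample is a depth in
#' integer millimeters (16-bit range); 0 encodes "no measurement". The
#' matrix is stored row-major in image orientation: `values[v + 1, u + 1]`
#' is the sample at zero-based pixel (u = column, v = row), origin top-left.
#'
#' @slot values numeric matrix (height x width) of non-negative integers.
#' @export
setClass("DepthImage",
  representation(values = "matrix"),
  validity = function(object) {
    v <- object@values
    if (!is.numeric(v)) return("values must be numeric")
    if (length(v) == 0L) return("image must have at least one pixel")
    if (anyNA(v)) return("depth values must not contain NA")
    if (any(v < 0)) return("depth values must be >= 0")
    if (any(v > 65535)) return("depth values exceed the 16-bit range")
    if (any(v != round(v))) return("depth values must be integer-valued millimeters")
    TRUE
  })

#' @title KeypointSet: the seven named 2-D landmarks
#'
#' @description Pixel positions and visibility flags for the seven body
#' landmarks. Visibility follows the COCO convention: 0 unmarked, 1 marked
#' but obscured, 2 marked and visible. Coordinates are zero-based
#' (column u, row v) and may be fractional.
#'
#' @slot coords 7 x 2 numeric matrix (columns u, v), rownames the landmark
#'   names; rows with visibility 0 may be NA.
#' @slot visibility named integer vector in \{0, 1, 2\}.
#' @slot bbox numeric(4) object box `c(x, y, w, h)` or numeric(0) if absent.
#' @slot image character id of the source image ("" if unknown).
#' @export
setClass("KeypointSet",
  representation(coords = "matrix", visibility = "integer",
                 bbox = "numeric", image = "character"),
  validity = function(object) {
    ln <- landmarkNames()
    if (!identical(rownames(object@coords), ln))
      return("coords must have exactly the seven landmark rows, in canonical order")
    if (ncol(object@coords) != 2L) return("coords must have two columns (u, v)")
    if (!identical(names(object@visibility), ln))
      return("visibility must be named by the seven landmarks")
    if (any(!object@visibility %in% 0:2)) return("visibility flags must be 0, 1 or 2")
    vis <- object@visibility > 0L
    if (any(vis & !stats::complete.cases(object@coords)))
      return("landmarks with visibility > 0 must have finite coordinates")
    if (!length(object@bbox) %in% c(0L, 4L)) return("bbox must be numeric(0) or c(x, y, w, h)")
    TRUE
  })

#' @title WorldKeypoints: landmarks lifted to 3-D camera coordinates
#'
#' @description Result of depth refinement and inverse projection. Only
#' landmarks that obtained a valid refined depth are present; the others
#' are recorded in `missing`.
#'
#' @slot points k x 3 numeric matrix (X, Y, Z in mm), rownames a subset of
#'   the landmark names.
#' @slot depths named numeric vector of the refined depths used (mm).
#' @slot pixels k x 2 matrix of the original (sub-pixel) keypoint positions.
#' @slot referenceDepth the Shoulder-Pin midpoint benchmark depth (mm).
#' @slot missing character vector of landmarks with no valid depth.
#' @export
setClass("WorldKeypoints",
  representation(points = "matrix", depths = "numeric", pixels = "matrix",
                 referenceDepth = "numeric", missing = "character"),
  validity = function(object) {
    nm <- rownames(object@points)
    if (ncol(object@points) != 3L) return("points must have three columns (X, Y, Z)")
    if (!all(nm %in% landmarkNames())) return("unknown landmark name in points")
    if (!identical(names(object@depths), nm) || !identical(rownames(object@pixels), nm))
      return("depths and pixels must align with points")
    if (any(object@depths <= 0)) return("refined depths must be positive")
    if (length(object@referenceDepth) != 1L || object@referenceDepth <= 0)
      return("referenceDepth must be a positive scalar")
    TRUE
  })

#' @title DepthFilterParams: conditional depth-filter settings
#'
#' @description Parameters of the keypoint depth refinement: the validity
#' band for raw depths, the tolerance around the Shoulder-Pin reference
#' depth, the reference-window half width, and the pixel search radius.
#'
#' @slot validMin exclusive lower bound on a valid depth (mm).
#' @slot validMax inclusive upper bound on a valid depth (mm).
#' @slot refTolerance max |depth - reference| accepted (mm).
#' @slot neighborhood half width of the reference window (1 = 3x3).
#' @slot maxRadius Chebyshev search radius in pixels.
#' @slot search "ring" (nearest-first) or "raster" (pseudo-code parity).
#' @slot growReference whether to enlarge an empty reference window.
#' @export
setClass("DepthFilterParams",
  representation(validMin = "numeric", validMax = "numeric",
                 refTolerance = "numeric", neighborhood = "integer",
                 maxRadius = "integer", search = "character",
                 growReference = "logical"),
  validity = function(object) {
    if (object@validMin < 0 || object@validMin >= object@validMax)
      return("need 0 <= validMin < validMax")
    if (object@refTolerance <= 0) return("refTolerance must be > 0")
    if (object@neighborhood < 1L) return("neighborhood must be >= 1")
    if (object@maxRadius < 1L) return("maxRadius must be >= 1")
    if (!object@search %in% c("ring", "raster")) return("search must be 'ring' or 'raster'")
    TRUE
  })

#' @title GirthConfig: chest-girth pipeline settings
#'
#' @slot numPoints intermediate samples between Chest1 and Chest2 (>= 3).
#' @slot smoothFactor RBF smoothing parameter (mm scale; 0 = interpolation).
#' @slot refineFactor densification multiplier at each resampling stage.
#' @slot profileMode "surface" (sample the depth map along the chest line)
#'   or "chord" (straight 3-D segment, pseudo-code parity).
#' @slot mirrorFrame "chord_local" (reflect across the chord plane) or
#'   "literal_y" (negate camera-frame Y, parity mode).
#' @slot splineClosure "periodic" or "open".
#' @slot rbfEpsilon multiquadric shape parameter on the index grid.
#' @export
setClass("GirthConfig",
  representation(numPoints = "integer", smoothFactor = "numeric",
                 refineFactor = "integer", profileMode = "character",
                 mirrorFrame = "character", splineClosure = "character",
                 rbfEpsilon = "numeric"),
  validity = function(object) {
    if (object@numPoints < 3L) return("numPoints must be >= 3")
    if (object@smoothFactor < 0) return("smoothFactor must be >= 0")
    if (object@refineFactor < 1L) return("refineFactor must be >= 1")
    if (!object@profileMode %in% c("surface", "chord")) return("profileMode must be 'surface' or 'chord'")
    if (!object@mirrorFrame %in% c("chord_local", "literal_y")) return("mirrorFrame must be 'chord_local' or 'literal_y'")
    if (!object@splineClosure %in% c("periodic", "open")) return("splineClosure must be 'periodic' or 'open'")
    if (object@rbfEpsilon <= 0) return("rbfEpsilon must be > 0")
    TRUE
  })

#' @title Curve3D: an ordered 3-D polyline
#'
#' @slot points n x 3 numeric matrix of camera-frame coordinates (mm).
#' @slot closed whether the last point connects back to the first.
#' @export
setClass("Curve3D",
  representation(points = "matrix", closed = "logical"),
  validity = function(object) {
    if (ncol(object@points) != 3L) return("points must have three columns")
    if (nrow(object@points) < 2L) return("a curve needs at least two points")
    if (any(!is.finite(object@points))) return("curve points must be finite")
    TRUE
  })

#' @title CattleModel: parametric synthetic animal
#'
#' @description Geometric stand-in for a standing animal seen from the
#' side: an elliptical-cylinder torso (axis horizontal along the body),
#' four vertical circular-cylinder legs, and a ground plane. All seven
#' landmark anchors are placed analytically on the model surface, so every
#' body dimension has a closed-form or quadrature ground truth.
#'
#' Model frame: x along the body (centered, head at +x), y height above
#' ground (up), z lateral offset from the torso-axis plane (positive toward
#' the camera).
#'
#' @slot torsoLength,torsoSemiHeight,torsoSemiDepth torso size (mm): length
#'   along the body, vertical semi-axis, horizontal (depth) semi-axis.
#' @slot axisHeight torso axis height above ground (mm).
#' @slot legRadius,legInset,legPairOffset leg cylinder radius, distance of
#'   leg centers from the torso ends, and lateral half-spacing of a leg
#'   pair (mm).
#' @slot withersOffset extra height of the Withers anchor above the torso
#'   top (mm).
#' @slot girthOffset distance of the girth plane behind the front-leg line
#'   (mm).
#' @slot anchors 7 x 3 matrix of landmark anchors in the model frame.
#' @export
setClass("CattleModel",
  representation(torsoLength = "numeric", torsoSemiHeight = "numeric",
                 torsoSemiDepth = "numeric", axisHeight = "numeric",
                 legRadius = "numeric", legInset = "numeric",
                 legPairOffset = "numeric", withersOffset = "numeric",
                 girthOffset = "numeric", anchors = "matrix"),
  validity = function(object) {
    msg <- character()
    pos <- c(torsoLength = object@torsoLength, torsoSemiHeight = object@torsoSemiHeight,
             torsoSemiDepth = object@torsoSemiDepth, axisHeight = object@axisHeight,
             legRadius = object@legRadius)
    bad <- names(pos)[pos <= 0]
    if (length(bad)) msg <- c(msg, paste0("dimensions must be positive: ", paste(bad, collapse = ", ")))
    if (object@withersOffset < 0) msg <- c(msg, "withersOffset must be >= 0")
    if (object@axisHeight <= object@torsoSemiHeight)
      msg <- c(msg, "torso must clear the ground (axisHeight > torsoSemiHeight)")
    if (object@legPairOffset + object@legRadius > object@torsoSemiDepth)
      msg <- c(msg, "legs must fit within the torso depth")
    if (object@legInset + object@legRadius > object@torsoLength / 2)
      msg <- c(msg, "legs must lie under the torso")
    if (object@girthOffset < 0) msg <- c(msg, "girthOffset must be >= 0")
    if (!identical(rownames(object@anchors), landmarkNames()))
      msg <- c(msg, "anchors must have the seven landmark rows")
    if (length(msg)) msg else TRUE
  })

#' @title CameraPose: synthetic camera placement
#'
#' @description The depth camera faces the animal's flank square-on:
#' optical axis horizontal, perpendicular to the body axis. Only the
#' stand-off distance and mounting height vary, emulating a tripod-mounted
#' side view.
#'
#' @slot distance camera to torso-axis plane, along the optical axis (mm).
#' @slot height camera height above ground (mm).
#' @export
setClass("CameraPose",
  representation(distance = "numeric", height = "numeric"),
  validity = function(object) {
    if (object@distance <= 0) return("distance must be positive")
    if (object@height <= 0) return("height must be positive")
    TRUE
  })

#' @title NoiseSpec: depth-sensor noise model
#'
#' @slot dropoutRate fraction of valid pixels zeroed at random.
#' @slot jitterSd standard deviation of additive Gaussian depth noise (mm).
#' @slot holeCount,holeRadius number and pixel radius of blob dropouts.
#' @slot seed RNG seed; a fixed seed reproduces the noise field exactly.
#' @export
setClass("NoiseSpec",
  representation(dropoutRate = "numeric", jitterSd = "numeric",
                 holeCount = "integer", holeRadius = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@dropoutRate < 0 || object@dropoutRate > 1) return("dropoutRate must be in [0, 1]")
    if (object@jitterSd < 0) return("jitterSd must be >= 0")
    if (object@holeCount < 0L) return("holeCount must be >= 0")
    if (object@holeRadius < 0) return("holeRadius must be >= 0")
    TRUE
  })

#' @title BodyMeasurements: the four body dimensions
#'
#' @description Measurement result for one animal. Dimensions that could
#' not be computed are NA (never zero) and the reason is recorded in
#' `notes`.
#'
#' @slot values named numeric: body_height_cm, lumbar_height_cm,
#'   body_length_cm, chest_girth_cm (NA when unavailable).
#' @slot depths named refined landmark depths (mm) for audit.
#' @slot notes named character vector of per-dimension failure messages.
#' @export
setClass("BodyMeasurements",
  representation(values = "numeric", depths = "numeric", notes = "character"),
  validity = function(object) {
    want <- c("body_height_cm", "lumbar_height_cm", "body_length_cm", "chest_girth_cm")
    if (!identical(names(object@values), want))
      return("values must be the four named dimensions")
    ok <- is.na(object@values) | object@values > 0
    if (!all(ok)) return("present measurements must be positive")
    TRUE
  })
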