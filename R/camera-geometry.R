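#' Construct camera intrinsics
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point (column, row) in pixels.
#' @param width,height image size in pixels.
#' @return A [CameraIntrinsics-class] object.
#' @examples
#' K <- cameraIntrinsics(700, 700, 640, 360, 1280, 720)
#' @export
cameraIntrinsics <- function(fx, fy, cx, cy, width, height) {
  methods::new("CameraIntrinsics", fx = as.numeric(fx), fy = as.numeric(fy),
               cx = as.numeric(cx), cy = as.numeric(cy),
               width = as.numeric(width), height = as.numeric(height))
}

#' Read camera intrinsics from a YAML or JSON config file
#'
#' The file must provide all six keys `fx, fy, cx, cy, width, height`; no
#' defaults are invented for a physical camera.
#'
#' @param path path to a YAML (or JSON) key-value file.
#' @return A [CameraIntrinsics-class] object.
#' @export
readIntrinsics <- function(path) {
  if (!file.exists(path)) stop("intrinsics file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("fx", "fy", "cx", "cy", "width", "height")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("intrinsics file is missing keys: ", paste(miss, collapse = ", "))
  cameraIntrinsics(cfg$fx, cfg$fy, cfg$cx, cfg$cy, cfg$width, cfg$height)
}

#' Write camera intrinsics to a YAML config file
#'
#' @param K a [CameraIntrinsics-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeIntrinsics <- function(K, path) {
  yaml::write_yaml(list(fx = K@fx, fy = K@fy, cx = K@cx, cy = K@cy,
                        width = K@width, height = K@height), path)
  invisible(path)
}

#' Back-project pixels with depth to 3-D camera coordinates
#'
#' Inverse pinhole projection: `X = (u - cx) * depth / fx`,
#' `Y = (v - cy) * depth / fy`, `Z = depth`. The camera frame is X right,
#' Y down, Z along the optical axis; pixel (u, v) = (column, row),
#' zero-based, origin top-left. Sub-pixel coordinates are accepted.
#'
#' @param u,v pixel coordinates (vectors of equal length).
#' @param depth depth(s) in mm, all > 0.
#' @param K a [CameraIntrinsics-class] object.
#' @return An n x 3 matrix with columns X, Y, Z (mm).
#' @examples
#' K <- cameraIntrinsics(700, 700, 640, 360, 1280, 720)
#' pixelToWorld(640, 360, 1000, K)  # on the optical axis
#' @export
pixelToWorld <- function(u, v, depth, K) {
  n <- max(length(u), length(v), length(depth))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  depth <- rep_len(as.numeric(depth), n)
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("pixel coordinates must be finite")
  if (any(!is.finite(depth)) || any(depth <= 0)) stop("invalid depth: depth must be > 0")
  cbind(X = (u - K@cx) * depth / K@fx,
        Y = (v - K@cy) * depth / K@fy,
        Z = depth)
}

#' Project 3-D camera-frame points to pixels
#'
#' Forward pinhole projection: `u = fx * X / Z + cx`,
#' `v = fy * Y / Z + cy`, depth = Z. Points must lie in front of the
#' camera (Z > 0).
#'
#' @param p an n x 3 matrix (or length-3 vector) of X, Y, Z in mm.
#' @param K a [CameraIntrinsics-class] object.
#' @return An n x 3 matrix with columns u, v, depth.
#' @export
worldToPixel <- function(p, K) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (ncol(p) != 3L) stop("p must have three columns (X, Y, Z)")
  if (any(p[, 3] <= 0)) stop("behind-camera point: Z must be > 0")
  cbind(u = K@fx * p[, 1] / p[, 3] + K@cx,
        v = K@fy * p[, 2] / p[, 3] + K@cy,
        depth = p[, 3])
}

#' Euclidean distance between two 3-D points
#'
#' @param a,b length-3 numeric vectors (mm).
#' @return Distance in mm.
#' @export
euclideanDistance <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("points must be finite")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics %gx%g px | fx=%g fy=%g cx=%g cy=%g\n",
              object@width, object@height, object@fx, object@fy,
              object@cx, object@cy))
})
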