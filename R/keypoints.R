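#' Construct a KeypointSet
#'
#' @param coords 7 x 2 matrix of zero-based (u, v) pixel coordinates with
#'   the landmark names as rownames, or a named list of `c(u, v)` pairs.
#' @param visibility named vector of visibility flags (0 unmarked,
#'   1 obscured, 2 visible); defaults to 2 for every supplied landmark.
#' @param bbox optional object box `c(x, y, w, h)`.
#' @param image optional image id.
#' @return A [KeypointSet-class] object.
#' @examples
#' kp <- keypointSet(list(Withers = c(500, 120), Sole = c(480, 600),
#'                        Shoulder = c(820, 300), Pin = c(180, 310),
#'                        Chest1 = c(700, 150), Chest2 = c(700, 460),
#'                        Lumbar = c(300, 140)))
#' @export
keypointSet <- function(coords, visibility = NULL, bbox = numeric(0), image = "") {
  ln <- landmarkNames()
  m <- matrix(NA_real_, 7L, 2L, dimnames = list(ln, c("u", "v")))
  if (is.list(coords)) {
    bad <- setdiff(names(coords), ln)
    if (length(bad)) stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
    for (nm in names(coords)) m[nm, ] <- as.numeric(coords[[nm]][1:2])
  } else {
    coords <- as.matrix(coords)
    bad <- setdiff(rownames(coords), ln)
    if (length(bad)) stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
    m[rownames(coords), ] <- coords[, 1:2]
  }
  vis <- stats::setNames(rep(0L, 7L), ln)
  present <- rownames(m)[stats::complete.cases(m)]
  vis[present] <- 2L
  if (!is.null(visibility)) vis[names(visibility)] <- as.integer(visibility)
  methods::new("KeypointSet", coords = m, visibility = vis,
               bbox = as.numeric(bbox), image = as.character(image))
}

#' @describeIn keypointSet coordinate matrix (7 x 2, NA where unmarked).
#' @param kps a [KeypointSet-class] object.
#' @export
keypointCoords <- function(kps) kps@coords

#' @describeIn keypointSet named visibility flags.
#' @export
keypointVisibility <- function(kps) kps@visibility

#' Read keypoints from JSON
#'
#' Two encodings are accepted:
#' \itemize{
#'   \item named: `{"image": ..., "bbox": [x,y,w,h], "keypoints":
#'     {"Withers": [u,v,vis], ...}}`
#'   \item COCO-style flattened: `"keypoints"` is a flat array of 21
#'     numbers, triples `(u, v, vis)` in the fixed landmark order
#'     Withers, Sole, Shoulder, Pin, Chest1, Chest2, Lumbar.
#' }
#'
#' @param path path to the JSON file.
#' @return A [KeypointSet-class] object.
#' @export
readKeypoints <- function(path) {
  if (!file.exists(path)) stop("keypoint file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kp <- obj$keypoints
  if (is.null(kp)) stop("keypoint file has no 'keypoints' entry: ", path)
  ln <- landmarkNames()
  if (is.numeric(kp)) {                      # COCO flattening
    if (length(kp) != 21L)
      stop("flattened keypoints must hold 21 numbers (7 x [u, v, vis])")
    m <- matrix(kp, ncol = 3L, byrow = TRUE, dimnames = list(ln, NULL))
  } else {
    kp <- lapply(kp, unlist)
    m <- matrix(NA_real_, 7L, 3L, dimnames = list(ln, NULL))
    bad <- setdiff(names(kp), ln)
    if (length(bad)) stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
    for (nm in names(kp)) m[nm, ] <- as.numeric(kp[[nm]])[1:3]
    m[is.na(m[, 3]), 3] <- 0
  }
  vis <- stats::setNames(as.integer(m[, 3]), ln)
  coords <- m[, 1:2, drop = FALSE]
  coords[vis == 0L, ] <- NA_real_
  keypointSet(coords, visibility = vis,
              bbox = if (!is.null(obj$bbox)) as.numeric(unlist(obj$bbox)) else numeric(0),
              image = if (!is.null(obj$image)) as.character(obj$image) else "")
}

#' Write keypoints to JSON (named encoding)
#'
#' @param kps a [KeypointSet-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeKeypoints <- function(kps, path) {
  ln <- landmarkNames()
  lst <- lapply(ln, function(nm) {
    uv <- kps@coords[nm, ]
    c(if (is.na(uv[1])) 0 else round(uv[1], 2),
      if (is.na(uv[2])) 0 else round(uv[2], 2),
      kps@visibility[[nm]])
  })
  names(lst) <- ln
  obj <- list(image = kps@image, keypoints = lst)
  if (length(kps@bbox)) obj$bbox <- round(kps@bbox, 2)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "KeypointSet", function(object) {
  vis <- object@visibility
  cat(sprintf("KeypointSet%s | %d/7 marked (%d visible)\n",
              if (nzchar(object@image)) paste0(" [", object@image, "]") else "",
              sum(vis > 0), sum(vis == 2L)))
})
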