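#' Construct depth-filter parameters
#'
#' Defaults follow the measurement protocol: depths are valid on
#' (0, 7000] mm, a refined depth must lie within 500 mm of the
#' Shoulder-Pin midpoint benchmark, the benchmark is averaged over a 3x3
#' window, and the pixel search extends to a Chebyshev radius of 20.
#'
#' @param validMin exclusive lower bound for a valid depth (mm).
#' @param validMax inclusive upper bound for a valid depth (mm).
#' @param refTolerance accepted |depth - reference| (mm).
#' @param neighborhood reference-window half width (1 = 3x3).
#' @param maxRadius maximum search radius in pixels.
#' @param search `"ring"` searches concentric Chebyshev rings outward so
#'   the nearest qualifying pixel wins (ties broken by scan order:
#'   increasing dy, then dx); `"raster"` replays the plain nested-loop
#'   scan over the whole square and returns its first hit.
#' @param growReference if TRUE, an empty reference window is doubled up
#'   to three times before failing.
#' @return A [DepthFilterParams-class] object.
#' @export
depthFilterParams <- function(validMin = 0, validMax = 7000, refTolerance = 500,
                              neighborhood = 1L, maxRadius = 20L,
                              search = c("ring", "raster"), growReference = FALSE) {
  methods::new("DepthFilterParams", validMin = as.numeric(validMin),
               validMax = as.numeric(validMax), refTolerance = as.numeric(refTolerance),
               neighborhood = as.integer(neighborhood), maxRadius = as.integer(maxRadius),
               search = match.arg(search), growReference = isTRUE(growReference))
}

isValidDepth <- function(d, params) {
  d > params@validMin & d <= params@validMax
}

#' Benchmark depth at the Shoulder-Pin midpoint
#'
#' Averages the valid depths inside a window centred on the (rounded)
#' arithmetic midpoint of the Shoulder and Pin pixels. Samples outside the
#' validity band are excluded; the mean is returned untruncated.
#'
#' @param img a [DepthImage-class] object.
#' @param shoulder,pin `c(u, v)` pixel coordinates of the two landmarks.
#' @param params a [DepthFilterParams-class] object.
#' @return The benchmark depth in mm.
#' @export
referenceDepth <- function(img, shoulder, pin, params = depthFilterParams()) {
  mid <- (as.numeric(shoulder[1:2]) + as.numeric(pin[1:2])) / 2
  mu <- roundHalfAway(mid[1]); mv <- roundHalfAway(mid[2])
  w <- imageWidth(img); h <- imageHeight(img)
  if (mu < 0 || mv < 0 || mu >= w || mv >= h)
    stop(sprintf("no-reference: Shoulder-Pin midpoint (%g, %g) outside the image", mu, mv))
  half <- params@neighborhood
  grows <- if (params@growReference) 3L else 0L
  for (g in 0:grows) {
    us <- max(0, mu - half):min(w - 1, mu + half)
    vs <- max(0, mv - half):min(h - 1, mv + half)
    win <- img@values[vs + 1L, us + 1L]
    ok <- isValidDepth(win, params)
    if (any(ok)) return(mean(win[ok]))
    half <- half * 2L
  }
  stop(sprintf("no-reference: no valid depth in the window around midpoint (%g, %g)", mu, mv))
}

ringOffsets <- function(r) {
  if (r == 0L) return(matrix(0L, 1L, 2L))
  # Chebyshev ring of radius r, ordered by increasing dy then dx
  dy <- rep(-r:r, each = 2L * r + 1L)
  dx <- rep(-r:r, times = 2L * r + 1L)
  keep <- pmax(abs(dx), abs(dy)) == r
  cbind(dx[keep], dy[keep])
}

#' Find the nearest valid depth around a pixel
#'
#' Searches around the (rounded) pixel for a depth that is valid and
#' within `refTolerance` of the benchmark depth. The default `"ring"`
#' search visits concentric Chebyshev rings of growing radius, so the
#' returned depth comes from a qualifying pixel at minimal ring distance;
#' `"raster"` mode reproduces a plain nested-loop scan of the square.
#' Pixels falling outside the image are skipped silently.
#'
#' @param img a [DepthImage-class] object.
#' @param u,v zero-based pixel coordinates (may be fractional).
#' @param ref benchmark depth in mm (> 0).
#' @param params a [DepthFilterParams-class] object.
#' @return The refined depth in mm, or `NA_real_` if no qualifying pixel
#'   exists within `maxRadius`.
#' @export
findNearestValidDepth <- function(img, u, v, ref, params = depthFilterParams()) {
  stopifnot(is.finite(ref), ref > 0)
  ui <- roundHalfAway(u); vi <- roundHalfAway(v)
  w <- imageWidth(img); h <- imageHeight(img)
  if (ui < 0 || vi < 0 || ui >= w || vi >= h)
    stop(sprintf("pixel (%g, %g) outside the %dx%d image", u, v, w, h))
  vals <- img@values
  qualifies <- function(d) {
    isValidDepth(d, params) && abs(d - ref) <= params@refTolerance
  }
  if (params@search == "raster") {
    r <- params@maxRadius
    for (dx in -r:r) for (dy in -r:r) {
      x <- ui + dx; y <- vi + dy
      if (x < 0 || y < 0 || x >= w || y >= h) next
      d <- vals[y + 1L, x + 1L]
      if (qualifies(d)) return(d)
    }
    return(NA_real_)
  }
  for (r in 0:params@maxRadius) {
    off <- ringOffsets(r)
    for (i in seq_len(nrow(off))) {
      x <- ui + off[i, 1L]; y <- vi + off[i, 2L]
      if (x < 0 || y < 0 || x >= w || y >= h) next
      d <- vals[y + 1L, x + 1L]
      if (qualifies(d)) return(d)
    }
  }
  NA_real_
}

#' Refine keypoint depths and lift the landmarks to 3-D
#'
#' Computes the Shoulder-Pin benchmark depth, refines the depth of every
#' marked landmark by conditional filtering
#' ([findNearestValidDepth()]), and back-projects each landmark to
#' camera-frame coordinates with its refined depth. Landmarks without a
#' qualifying depth are reported as missing, never fabricated.
#'
#' @param img a [DepthImage-class] object.
#' @param kps a [KeypointSet-class] object; Shoulder and Pin must be
#'   marked (visibility > 0).
#' @param K a [CameraIntrinsics-class] object.
#' @param params a [DepthFilterParams-class] object.
#' @return A [WorldKeypoints-class] object.
#' @export
localizeKeypoints <- function(img, kps, K, params = depthFilterParams()) {
  vis <- kps@visibility
  if (vis[["Shoulder"]] == 0L || vis[["Pin"]] == 0L)
    stop("missing-landmark: Shoulder and Pin are required for the reference depth")
  ref <- referenceDepth(img, kps@coords["Shoulder", ], kps@coords["Pin", ], params)
  marked <- names(vis)[vis > 0L]
  depths <- numeric(0); pts <- NULL; px <- NULL; missing <- character(0)
  for (nm in marked) {
    uv <- kps@coords[nm, ]
    d <- findNearestValidDepth(img, uv[1], uv[2], ref, params)
    if (is.na(d)) {
      missing <- c(missing, nm)
      next
    }
    depths[nm] <- d
    pts <- rbind(pts, pixelToWorld(uv[1], uv[2], d, K))
    px <- rbind(px, uv)
  }
  if (is.null(pts)) pts <- matrix(numeric(0), 0L, 3L)
  if (is.null(px)) px <- matrix(numeric(0), 0L, 2L)
  rownames(pts) <- names(depths); rownames(px) <- names(depths)
  colnames(pts) <- c("X", "Y", "Z"); colnames(px) <- c("u", "v")
  methods::new("WorldKeypoints", points = pts, depths = depths, pixels = px,
               referenceDepth = ref,
               missing = c(missing, names(vis)[vis == 0L]))
}

#' @describeIn localizeKeypoints 3-D positions of the localized landmarks.
#' @param wk a [WorldKeypoints-class] object.
#' @export
worldPoints <- function(wk) wk@points

#' @describeIn localizeKeypoints refined landmark depths in mm.
#' @export
refinedDepths <- function(wk) wk@depths

setMethod("show", "WorldKeypoints", function(object) {
  cat(sprintf("WorldKeypoints | %d landmark(s), reference depth %.1f mm%s\n",
              nrow(object@points), object@referenceDepth,
              if (length(object@missing))
                paste0(" | missing: ", paste(object@missing, collapse = ", "))
              else ""))
})
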