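requireLandmarks <- function(wk, need) {
  absent <- setdiff(need, rownames(wk@points))
  if (length(absent))
    stop("missing-landmark: ", paste(absent, collapse = ", "))
  invisible(TRUE)
}

#' Body height in cm
#'
#' Euclidean distance from the highest point of the withers to the bottom
#' of the hoof (Sole), mimicking the vertical measuring stick.
#'
#' @param wk a [WorldKeypoints-class] object with Withers and Sole present.
#' @return Body height in cm (mm / 10).
#' @export
bodyHeight <- function(wk) {
  requireLandmarks(wk, c("Withers", "Sole"))
  euclideanDistance(wk@points["Withers", ], wk@points["Sole", ]) / 10
}

#' Body oblique length in cm
#'
#' Euclidean distance from the shoulder endpoint to the outer edge of the
#' tuber ischium (Pin), mimicking the stretched tape measure.
#'
#' @param wk a [WorldKeypoints-class] object with Shoulder and Pin present.
#' @return Body oblique length in cm.
#' @export
bodyLength <- function(wk) {
  requireLandmarks(wk, c("Shoulder", "Pin"))
  euclideanDistance(wk@points["Shoulder", ], wk@points["Pin", ]) / 10
}

#' Lumbar height in cm
#'
#' Constructs a ground point directly beneath the lumbar landmark by
#' combining the lumbar pixel column with the sole pixel row, back-projected
#' at the sole's refined depth (the sole depth encodes the camera-to-ground
#' distance), then measures the Euclidean distance from the lumbar point to
#' that ground point.
#'
#' @param wk a [WorldKeypoints-class] object with Lumbar and Sole present.
#' @param K a [CameraIntrinsics-class] object.
#' @return Lumbar height in cm.
#' @export
lumbarHeight <- function(wk, K) {
  requireLandmarks(wk, c("Lumbar", "Sole"))
  gu <- wk@pixels["Lumbar", "u"]; gv <- wk@pixels["Sole", "v"]
  if (gu < 0 || gv < 0 || gu >= K@width || gv >= K@height)
    stop(sprintf("ground pixel (%g, %g) outside the image", gu, gv))
  G <- pixelToWorld(gu, gv, wk@depths[["Sole"]], K)[1, ]
  euclideanDistance(wk@points["Lumbar", ], G) / 10
}

#' Measure all four body dimensions of one animal
#'
#' Runs the full pipeline: depth refinement and 3-D lifting of the
#' landmarks, then body height, lumbar height, body oblique length, and
#' chest girth. Each dimension is computed independently: a landmark
#' missing for one measurement leaves that value NA (with the reason in
#' `notes`) without blocking the others.
#'
#' @param img a [DepthImage-class] object.
#' @param kps a [KeypointSet-class] object.
#' @param K a [CameraIntrinsics-class] object.
#' @param dparams a [DepthFilterParams-class] object.
#' @param gconf a [GirthConfig-class] object.
#' @return A [BodyMeasurements-class] object.
#' @export
measureAnimal <- function(img, kps, K, dparams = depthFilterParams(),
                          gconf = girthConfig()) {
  wk <- localizeKeypoints(img, kps, K, dparams)
  vals <- c(body_height_cm = NA_real_, lumbar_height_cm = NA_real_,
            body_length_cm = NA_real_, chest_girth_cm = NA_real_)
  notes <- character(0)
  tryOne <- function(nm, expr) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.numeric(res)) vals[nm] <<- res else notes[nm] <<- res
  }
  tryOne("body_height_cm", bodyHeight(wk))
  tryOne("lumbar_height_cm", lumbarHeight(wk, K))
  tryOne("body_length_cm", bodyLength(wk))
  tryOne("chest_girth_cm", chestGirth(img, kps, K, dparams, gconf, wk = wk))
  methods::new("BodyMeasurements", values = vals, depths = wk@depths, notes = notes)
}

#' @describeIn measureAnimal the four dimensions as a named numeric vector.
#' @param m a [BodyMeasurements-class] object.
#' @export
measurementValues <- function(m) m@values

#' Write measurement rows to CSV
#'
#' Fixed header `id, body_height_cm, lumbar_height_cm, body_length_cm,
#' chest_girth_cm`; values at 0.1 cm resolution, NA left empty.
#'
#' @param results named list of [BodyMeasurements-class] objects (names are
#'   the animal/image ids).
#' @param path output CSV path.
#' @return The data.frame written, invisibly.
#' @export
writeMeasurements <- function(results, path) {
  fmt <- function(x) if (is.na(x)) "" else sprintf("%.1f", x)
  rows <- lapply(names(results), function(id) {
    v <- results[[id]]@values
    data.frame(id = id,
               body_height_cm = fmt(v[["body_height_cm"]]),
               lumbar_height_cm = fmt(v[["lumbar_height_cm"]]),
               body_length_cm = fmt(v[["body_length_cm"]]),
               chest_girth_cm = fmt(v[["chest_girth_cm"]]))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), body_height_cm = character(0),
               lumbar_height_cm = character(0), body_length_cm = character(0),
               chest_girth_cm = character(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

setMethod("show", "BodyMeasurements", function(object) {
  v <- object@values
  fmt <- function(x) if (is.na(x)) "NA" else sprintf("%.1f", x)
  cat(sprintf(paste0("BodyMeasurements | height %s cm, lumbar %s cm, ",
                     "length %s cm, girth %s cm\n"),
              fmt(v[["body_height_cm"]]), fmt(v[["lumbar_height_cm"]]),
              fmt(v[["body_length_cm"]]), fmt(v[["chest_girth_cm"]])))
  if (length(object@notes))
    cat("  notes:", paste(names(object@notes), object@notes,
                          sep = ": ", collapse = "; "), "\n")
})
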