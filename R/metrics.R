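#' Object keypoint similarity parameters
#'
#' @param scale object scale S in pixels, conventionally the square root
#'   of the object bounding-box area.
#' @param sigmas per-landmark normalization factors; a single value is
#'   recycled to all seven landmarks.
#' @return A named list with `scale` and the 7 named `sigmas`.
#' @export
oksParams <- function(scale, sigmas = 0.05) {
  ln <- landmarkNames()
  if (length(sigmas) == 1L) sigmas <- rep(sigmas, 7L)
  if (is.null(names(sigmas))) names(sigmas) <- ln
  if (!identical(sort(names(sigmas)), sort(ln)))
    stop("sigmas must cover the seven landmarks")
  if (any(sigmas <= 0)) stop("sigmas must be > 0")
  if (length(scale) != 1L || scale <= 0) stop("scale must be a positive scalar")
  list(scale = as.numeric(scale), sigmas = sigmas[ln])
}

#' Scale from a bounding box
#'
#' The standard object scale for keypoint similarity: the square root of
#' the box area.
#'
#' @param bbox `c(x, y, w, h)`.
#' @return sqrt(w * h).
#' @export
bboxScale <- function(bbox) {
  if (length(bbox) != 4L || any(bbox[3:4] <= 0)) stop("bbox must be c(x, y, w, h) with w, h > 0")
  sqrt(bbox[3] * bbox[4])
}

#' Object keypoint similarity (OKS)
#'
#' Mean over the visible ground-truth landmarks of
#' `exp(-d^2 / (2 S^2 sigma^2))`, where d is the pixel distance between
#' the predicted and true landmark, S the object scale and sigma the
#' per-landmark normalization factor. Both visibility flags 1 and 2 count
#' as visible.
#'
#' @param pred,truth [KeypointSet-class] objects.
#' @param p parameters from [oksParams()]; if NULL the scale is taken from
#'   the truth bounding box with the default sigmas.
#' @return A similarity score in \[0, 1\].
#' @export
oks <- function(pred, truth, p = NULL) {
  if (is.null(p)) p <- oksParams(bboxScale(truth@bbox))
  vis <- truth@visibility > 0L
  if (!any(vis)) stop("undefined OKS: no visible ground-truth landmark")
  nm <- names(vis)[vis]
  d2 <- rowSums((pred@coords[nm, , drop = FALSE] -
                 truth@coords[nm, , drop = FALSE])^2)
  if (anyNA(d2)) stop("predicted position missing for visible landmark(s): ",
                      paste(nm[is.na(d2)], collapse = ", "))
  mean(exp(-d2 / (2 * p$scale^2 * p$sigmas[nm]^2)))
}

#' Average precision at an OKS threshold
#'
#' Fraction of detections whose OKS strictly exceeds the threshold
#' (a detection at exactly the threshold counts as a false positive).
#'
#' @param oksValues numeric vector of OKS scores.
#' @param threshold decision threshold (default 0.5).
#' @return Fraction in \[0, 1\].
#' @export
averagePrecision <- function(oksValues, threshold = 0.5) {
  if (!length(oksValues)) stop("no OKS values supplied")
  mean(oksValues > threshold)
}

#' Mean average precision over categories
#'
#' @param perClassAp numeric vector of per-category AP values.
#' @return Their arithmetic mean.
#' @export
meanAP <- function(perClassAp) {
  if (!length(perClassAp)) stop("no AP values supplied")
  mean(perClassAp)
}

#' Precision and recall from detection counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts.
#' @return Named numeric `c(precision, recall)`.
#' @export
precisionRecall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be >= 0")
  if (tp + fp == 0) stop("undefined precision: TP + FP = 0")
  if (tp + fn == 0) stop("undefined recall: TP + FN = 0")
  c(precision = tp / (tp + fp), recall = tp / (tp + fn))
}

#' Mean absolute error
#'
#' @param estimated,reference paired measurement vectors (same units).
#' @return MAE in the input units.
#' @export
mae <- function(estimated, reference) {
  if (length(estimated) != length(reference)) stop("length mismatch")
  if (!length(estimated)) stop("need at least one pair")
  mean(abs(estimated - reference))
}

#' Mean relative error in percent
#'
#' Mean of `|estimated - reference| / reference`, expressed in percent of
#' the reference (manual) measurement.
#'
#' @param estimated,reference paired measurement vectors; all reference
#'   values must be > 0.
#' @return MRE in percent.
#' @export
mre <- function(estimated, reference) {
  if (length(estimated) != length(reference)) stop("length mismatch")
  if (!length(estimated)) stop("need at least one pair")
  if (any(reference <= 0)) stop("reference values must be > 0")
  100 * mean(abs(estimated - reference) / reference)
}

#' Per-dimension measurement error table
#'
#' Compares automatic with manual measurements and reports MAE, MRE and
#' the maximum relative error for each of the four body dimensions.
#'
#' @param manual,automatic data.frames sharing an `id` column and the four
#'   dimension columns `body_height_cm, lumbar_height_cm, body_length_cm,
#'   chest_girth_cm`.
#' @return A data.frame with rows `mae_cm`, `mre_pct`, `max_rel_err_pct`
#'   and one column per dimension.
#' @export
measurementErrorTable <- function(manual, automatic) {
  dims <- c("body_height_cm", "lumbar_height_cm", "body_length_cm", "chest_girth_cm")
  if (!"id" %in% names(manual) || !"id" %in% names(automatic))
    stop("both tables need an 'id' column")
  un <- union(setdiff(manual$id, automatic$id), setdiff(automatic$id, manual$id))
  if (length(un)) stop("unmatched ids: ", paste(un, collapse = ", "))
  automatic <- automatic[match(manual$id, automatic$id), ]
  out <- sapply(dims, function(d) {
    x <- as.numeric(manual[[d]]); xh <- as.numeric(automatic[[d]])
    ok <- !is.na(x) & !is.na(xh)
    if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_))
    c(mae(xh[ok], x[ok]), mre(xh[ok], x[ok]),
      100 * max(abs(xh[ok] - x[ok]) / x[ok]))
  })
  df <- as.data.frame(out)
  df <- cbind(metric = c("mae_cm", "mre_pct", "max_rel_err_pct"), df)
  rownames(df) <- NULL
  df
}
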