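#' Construct a DepthImage from a matrix
#'
#' @param values numeric matrix (height x width) of integer millimeter
#'   depths; 0 encodes "no measurement".
#' @return A [DepthImage-class] object.
#' @export
depthImage <- function(values) {
  methods::new("DepthImage", values = matrix(as.numeric(values), nrow = nrow(values)))
}

#' @describeIn depthImage image width in pixels.
#' @param img a [DepthImage-class] object.
#' @export
imageWidth <- function(img) ncol(img@values)

#' @describeIn depthImage image height in pixels.
#' @export
imageHeight <- function(img) nrow(img@values)

#' @describeIn depthImage the raw millimeter matrix (height x width).
#' @export
depthValues <- function(img) img@values

#' Depth sample at a pixel
#'
#' Returns the raw millimeter sample at zero-based pixel (u, v); fractional
#' coordinates are rounded half away from zero, matching the integral image
#' indexing of the keypoint refinement.
#'
#' @param img a [DepthImage-class] object.
#' @param u,v zero-based pixel coordinates.
#' @return Depth in mm (0 = no measurement).
#' @export
depthAt <- function(img, u, v) {
  ui <- roundHalfAway(u); vi <- roundHalfAway(v)
  if (ui < 0 || vi < 0 || ui >= imageWidth(img) || vi >= imageHeight(img))
    stop(sprintf("pixel (%g, %g) outside the %dx%d image", u, v,
                 imageWidth(img), imageHeight(img)))
  img@values[vi + 1L, ui + 1L]
}

# round half away from zero (base round() rounds half to even)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read a depth image from PNG
#'
#' Accepts 8- or 16-bit grayscale or multi-channel PNG; for multi-channel
#' files the first channel is taken. Stored sample values are interpreted
#' directly as millimeters (a 16-bit sample of 3000 is a depth of 3 m).
#'
#' @param path path to the PNG file.
#' @return A [DepthImage-class] object.
#' @export
readDepthImage <- function(path) {
  if (!file.exists(path)) stop("cannot load depth image, file not found: ", path)
  x <- tryCatch(png::readPNG(path, info = TRUE),
                error = function(e) stop("cannot decode depth image '", path, "': ",
                                         conditionMessage(e)))
  info <- attr(x, "info")
  bits <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  if (length(x) == 0L) stop("zero-sized depth image: ", path)
  depthImage(round(x * (2^bits - 1)))
}

#' Write a depth image as 16-bit grayscale PNG
#'
#' One sample = 1 mm, stored as big-endian 16-bit grayscale (the format
#' depth cameras commonly export).
#'
#' @param img a [DepthImage-class] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeDepthImage <- function(img, path) {
  writePNG16(img@values, path)
  invisible(path)
}

## --- minimal 16-bit grayscale PNG encoder -------------------------------
## png::writePNG emits 8-bit samples only, which would truncate millimeter
## depths; PNG itself is simple enough to emit directly: IHDR + one
## zlib-compressed IDAT (memCompress emits an RFC-1950 zlib stream) + IEND,
## each chunk carrying a CRC-32.

crc32Table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256L)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) != 0L)
            bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
          else bitwShiftR(bitwAnd(c, -2L), 1)
        }
        t[n + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32Table()
  c <- -1L # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    idx <- bitwAnd(bitwXor(c, b[i]), 255L)
    c <- bitwXor(tab[idx + 1L], bitwShiftR(bitwAnd(c, -256L), 8))
  }
  bitwXor(c, -1L)
}

u32Bytes <- function(x) {
  # unsigned 32-bit big-endian from a (possibly negative) R integer
  xx <- as.numeric(x)
  if (xx < 0) xx <- xx + 4294967296
  as.raw(c(xx %/% 16777216, (xx %/% 65536) %% 256, (xx %/% 256) %% 256, xx %% 256))
}

pngChunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32Bytes(length(data)), body, u32Bytes(crc32(body)))
}

writePNG16 <- function(values, path) {
  h <- nrow(values); w <- ncol(values)
  v <- as.integer(round(t(values)))     # row-major scanlines
  if (any(v < 0 | v > 65535)) stop("depth values outside the 16-bit range")
  hi <- v %/% 256L; lo <- v %% 256L
  samples <- as.raw(as.vector(rbind(hi, lo)))           # big-endian pairs
  dim(samples) <- NULL
  scan <- matrix(samples, nrow = 2L * w, ncol = h)      # one column per row
  raw0 <- as.raw(0L)                                    # filter type None
  idat <- memCompress(as.raw(rbind(matrix(raw0, 1L, h), scan)), "gzip")
  ihdr <- c(u32Bytes(w), u32Bytes(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))             # 16-bit grayscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           pngChunk("IHDR", ihdr), pngChunk("IDAT", idat),
           pngChunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

setMethod("show", "DepthImage", function(object) {
  v <- object@values
  valid <- v[v > 0]
  cat(sprintf("DepthImage %dx%d px | %.1f%% valid | depth range %s mm\n",
              ncol(v), nrow(v), 100 * length(valid) / length(v),
              if (length(valid)) paste0(min(valid), "-", max(valid)) else "none"))
})
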