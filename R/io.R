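# Reading and writing the image formats used by the polarization pipeline.
#
# Raw camera frames are single-plane grayscale TIFFs whose left and right
# halves carry the two emission polarizations recorded side by side on one
# chip. Anisotropy maps are written as 32-bit float TIFF so that masked
# (NaN) pixels and fractional r values survive a round trip bit-exactly.

#' Read a raw dual-view camera frame
#'
#' Reads a single-plane grayscale TIFF without any rescaling and records
#' its bit depth.
#'
#' @param path path to a TIFF file.
#' @return A `RawDualViewFrame`: list with `pixels` (numeric matrix in
#'   camera counts), `width`, `height` and `bit_depth`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE, all = TRUE),
                  error = function(e) stop("unreadable TIFF: ", path, " (", conditionMessage(e), ")"))
  if (is.list(img)) {
    if (length(img) != 1L) stop("multi-plane TIFF not supported: ", path)
    img <- img[[1L]]
  }
  if (length(dim(img)) == 3L) stop("RGB/multi-channel TIFF not supported: ", path)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  frame <- list(pixels = matrix(as.numeric(img), nrow(img), ncol(img)),
                width = ncol(img), height = nrow(img),
                bit_depth = as.integer(bits))
  class(frame) <- "RawDualViewFrame"
  frame
}

#' Construct a raw dual-view frame from a matrix
#'
#' @param pixels numeric matrix of camera counts.
#' @param bit_depth camera bit depth (values must fit in it).
#' @return A `RawDualViewFrame`.
#' @export
dual_view_frame <- function(pixels, bit_depth = 16L) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0, na.rm = TRUE) || any(pixels > 2^bit_depth - 1, na.rm = TRUE))
    stop("pixel values outside the ", bit_depth, "-bit range")
  structure(list(pixels = pixels, width = ncol(pixels), height = nrow(pixels),
                 bit_depth = as.integer(bit_depth)),
            class = "RawDualViewFrame")
}

#' Split a dual-view frame into its two polarization halves
#'
#' The detector records both emission polarizations side by side; by
#' default the left half is the perpendicular channel and the right half
#' the parallel channel. The split moves pixels without changing any
#' value; the pair is unregistered until a channel transform is applied.
#'
#' @param frame a `RawDualViewFrame`.
#' @param left_is_perpendicular if `FALSE` the convention is flipped.
#' @return A `PolarizedFramePair`: list with `parallel`, `perpendicular`
#'   (matrices of equal shape) and `registered = FALSE`.
#' @export
split_dual_view <- function(frame, left_is_perpendicular = TRUE) {
  px <- frame$pixels
  w <- ncol(px)
  if (w %% 2L != 0L) stop("frame width must be even to split into halves")
  left <- px[, seq_len(w / 2L), drop = FALSE]
  right <- px[, (w / 2L + 1L):w, drop = FALSE]
  if (left_is_perpendicular) {
    pair <- list(parallel = right, perpendicular = left, registered = FALSE)
  } else {
    pair <- list(parallel = left, perpendicular = right, registered = FALSE)
  }
  class(pair) <- "PolarizedFramePair"
  pair
}

#' Reassemble a frame from its two halves (inverse of the split)
#' @param pair a `PolarizedFramePair`.
#' @inheritParams split_dual_view
#' @return numeric matrix of the full dual-view frame.
#' @export
join_dual_view <- function(pair, left_is_perpendicular = TRUE) {
  if (left_is_perpendicular) cbind(pair$perpendicular, pair$parallel)
  else cbind(pair$parallel, pair$perpendicular)
}

#' Write a 2D map as a 32-bit float grayscale TIFF
#'
#' Values (including NaN used for masked pixels) round-trip bit-exactly.
#' The writer emits a minimal uncompressed single-strip little-endian
#' TIFF with IEEE float samples; [read_map()] reads it back.
#'
#' @param map numeric matrix.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  stopifnot(is.matrix(map))
  h <- nrow(map); w <- ncol(map)
  con <- tryCatch(file(path, "wb"), error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeChar("II", con, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")       # first IFD offset
  # tag id, field type (3 = short, 4 = long), count, value
  tags <- list(
    c(256L, 4L, 1L, w),            # ImageWidth
    c(257L, 4L, 1L, h),            # ImageLength
    c(258L, 3L, 1L, 32L),          # BitsPerSample
    c(259L, 3L, 1L, 1L),           # no compression
    c(262L, 3L, 1L, 1L),           # black is zero
    c(273L, 4L, 1L, 0L),           # StripOffsets (patched below)
    c(277L, 3L, 1L, 1L),           # one sample per pixel
    c(278L, 4L, 1L, h),            # RowsPerStrip
    c(279L, 4L, 1L, 4L * w * h),   # StripByteCounts
    c(339L, 3L, 1L, 3L))           # SampleFormat = IEEE float
  n <- length(tags)
  tags[[6]][4] <- 8L + 2L + n * 12L + 4L               # data follows the IFD
  writeBin(as.integer(n), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(as.integer(tg[1]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[2]), con, size = 2, endian = "little")
    writeBin(as.integer(tg[3]), con, size = 4, endian = "little")
    if (tg[2] == 3L) {
      writeBin(as.integer(tg[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(tg[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")       # no further IFD
  writeBin(as.numeric(t(map)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a float or integer grayscale TIFF map
#'
#' @param path path to the TIFF.
#' @return numeric matrix (float TIFFs as stored; integer TIFFs as counts).
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) tiff::readTIFF(path))  # float TIFFs reject as.is
  matrix(as.numeric(img), nrow(img), ncol(img))
}

#' Construct an ROI mask from label images
#'
#' @param labels integer matrix; 0 = background, k > 0 = cell k.
#' @param nucleus_labels optional integer matrix of nuclear labels; nucleus
#'   pixels of cell k must be a subset of cell-k pixels.
#' @return A `RoiMask`.
#' @export
roi_mask <- function(labels, nucleus_labels = NULL) {
  stopifnot(is.matrix(labels))
  if (!is.null(nucleus_labels)) {
    stopifnot(identical(dim(labels), dim(nucleus_labels)))
    bad <- nucleus_labels > 0 & labels != nucleus_labels
    if (any(bad)) stop("nucleus pixels fall outside their cell mask")
  }
  structure(list(labels = labels, nucleus_labels = nucleus_labels),
            class = "RoiMask")
}
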