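#' Read a raster image as an 8-bit-scale RGB array
#'
#' Reads a PNG, TIFF or JPEG file and returns an `H x W x 3` numeric array of
#' intensities on the `[0, 255]` scale. Single-channel (grayscale) files are
#' replicated to three identical channels; an alpha channel, if present, is
#' dropped; 16-bit inputs are rescaled to `[0, 255]`.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return Numeric array `H x W x 3` with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stop("'path' must be a single file path", call. = FALSE)
  if (!file.exists(path))
    stop(sprintf("cannot read image: file does not exist: '%s'", path),
         call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  dat <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = jpeg::readJPEG(path),
      bmp  = stop("BMP input is not supported; convert to PNG or TIFF"),
      stop(sprintf("unsupported image format '.%s'", ext))
    ),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  as_rgb_array(dat)
}

# Normalize decoder output ([0,1] scale, 2d or 3d) to an H x W x 3 array on
# the [0,255] scale.
as_rgb_array <- function(dat) {
  if (is.matrix(dat)) dat <- array(dat, c(dim(dat), 1L))
  nc <- dim(dat)[3]
  if (nc == 2L) dat <- dat[, , 1L, drop = FALSE]        # gray + alpha
  if (nc == 4L) dat <- dat[, , 1:3, drop = FALSE]       # rgb + alpha
  if (dim(dat)[3] == 1L) dat <- dat[, , c(1L, 1L, 1L), drop = FALSE]
  img <- dat * 255
  validate_rgb_image(img)
  img
}

validate_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("image must have positive dimensions", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("RGB intensities must lie within [0, 255]", call. = FALSE)
  invisible(img)
}

validate_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric H x W grayscale matrix", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("grayscale intensities must lie within [0, 255]", call. = FALSE)
  invisible(img)
}

#' Convert an RGB image to grayscale
#'
#' Collapses the three channels with the weighted sum
#' `0.299 R + 0.583 G + 0.116 B`. These are the detector's native channel
#' weights; note that they differ slightly from the ITU-R BT.601 luma weights
#' (0.299, 0.587, 0.114), which are available via `variant = "bt601"`. Output
#' values are kept real-valued: no integer rounding is applied, so block
#' statistics downstream do not accumulate quantization error.
#'
#' @param img `H x W x 3` numeric array on the `[0, 255]` scale.
#' @param variant `"printed"` (default) for the native weights, `"bt601"`
#'   for ITU-R BT.601.
#' @return Numeric `H x W` matrix with values in `[0, 254.49]`
#'   (`"printed"`; the coefficient sum is 0.998) or `[0, 255]` (`"bt601"`).
#' @export
to_gray <- function(img, variant = c("printed", "bt601")) {
  validate_rgb_image(img)
  variant <- match.arg(variant)
  w <- switch(variant,
    printed = c(0.299, 0.583, 0.116),
    bt601   = c(0.299, 0.587, 0.114))
  g <- img[, , 1] * w[1] + img[, , 2] * w[2] + img[, , 3] * w[3]
  dim(g) <- dim(img)[1:2]
  g
}

#' Write a binary forgery mask as a lossless PNG
#'
#' Tampered pixels (value 1) are written as 255, authentic pixels (0) as 0,
#' in a single-channel 8-bit PNG. The write/read round trip through
#' [read_mask()] is bit-exact.
#'
#' @param mask Binary (`0`/`1`) integer or logical `H x W` matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  mask <- validate_mask(mask)
  ok <- tryCatch({
    png::writePNG(matrix(as.double(mask), nrow(mask)), target = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write mask '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  invisible(path)
}

#' Read a binary forgery mask from a PNG
#'
#' @param path PNG path written by [write_mask()] (or any image whose first
#'   channel encodes tampered pixels as bright values).
#' @return Integer `0`/`1` matrix, 1 = tampered.
#' @export
read_mask <- function(path) {
  img <- read_image(path)
  m <- matrix(0L, nrow = dim(img)[1], ncol = dim(img)[2])
  m[img[, , 1] >= 127.5] <- 1L
  m
}

validate_mask <- function(mask) {
  if (is.logical(mask)) mask <- mask + 0L
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("mask must be a binary 0/1 matrix", call. = FALSE)
  storage.mode(mask) <- "integer"
  mask
}
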