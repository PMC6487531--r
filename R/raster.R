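#' @importFrom stats fft rnorm runif sd quantile
#' @importFrom utils head write.csv
NULL

# Image carrier convention used throughout the package:
#   * a grayscale image is a numeric matrix [height, width],
#   * a color image is a numeric array [height, width, 3],
#   * intensities lie in [0, 1],
#   * pixel coordinates are 0-based with x = column, y = row and the origin at
#     the top-left pixel center; geometric transforms act on (x, y).

img_height <- function(img) dim(img)[1L]
img_width  <- function(img) dim(img)[2L]
img_channels <- function(img) if (length(dim(img)) == 3L) dim(img)[3L] else 1L

assert_image <- function(img, what = "image") {
  if (!is.numeric(img) || !(length(dim(img)) %in% c(2L, 3L)))
    stop(what, " must be a numeric matrix or a height x width x 3 array", call. = FALSE)
  if (length(dim(img)) == 3L && dim(img)[3L] != 3L)
    stop(what, " must have 1 or 3 channels, got ", dim(img)[3L], call. = FALSE)
  if (!all(is.finite(img)))
    stop(what, " contains non-finite intensities", call. = FALSE)
  invisible(img)
}

#' Read a raster image and normalize intensities to [0, 1]
#'
#' Reads PNG, TIFF or JPEG via EBImage and returns the package's plain-array
#' carrier: a `[height, width]` matrix for grayscale input or a
#' `[height, width, 3]` array for color input. Integer sample formats are
#' already divided by their type maximum by the underlying readers, so 8- and
#' 16-bit files map onto `[0, 1]` without further scaling.
#'
#' @param path path to a PNG, TIFF or JPEG file.
#' @param drop_alpha if `TRUE` (default) an alpha channel is silently dropped;
#'   if `FALSE` a 4-channel input is an error.
#' @return numeric matrix or `[h, w, 3]` array with intensities in `[0, 1]`.
#' @export
load_image <- function(path, drop_alpha = TRUE) {
  if (!file.exists(path)) stop("image file does not exist: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("unreadable image file: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  a <- EBImage::imageData(img)
  # EBImage stores [x, y(, channel)]; transpose to [row = y, col = x].
  if (length(dim(a)) == 2L) {
    out <- t(a)
  } else {
    nc <- dim(a)[3L]
    if (nc == 4L) {
      if (!drop_alpha) stop("4-channel (RGBA) input unsupported for: ", path, call. = FALSE)
      a <- a[, , 1:3, drop = FALSE]
      nc <- 3L
    }
    if (nc == 2L) { # gray + alpha
      if (!drop_alpha) stop("2-channel (gray+alpha) input unsupported for: ", path, call. = FALSE)
      a <- a[, , 1L, drop = TRUE]
      return(pmin(pmax(t(a), 0), 1))
    }
    if (nc != 3L) stop("unsupported channel count (", nc, ") in: ", path, call. = FALSE)
    out <- array(0, dim = c(dim(a)[2L], dim(a)[1L], 3L))
    for (k in 1:3) out[, , k] <- t(a[, , k])
  }
  pmin(pmax(out, 0), 1)
}

#' Write an image or binary mask as 8-bit PNG
#'
#' @param img image matrix/array in `[0, 1]` (logical masks are coerced).
#' @param path output path; the PNG format is forced regardless of extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  if (is.logical(img)) img <- img * 1
  assert_image(img)
  if (length(dim(img)) == 2L) {
    a <- t(img)
  } else {
    a <- array(0, dim = c(dim(img)[2L], dim(img)[1L], 3L))
    for (k in 1:3) a[, , k] <- t(img[, , k])
  }
  EBImage::writeImage(EBImage::Image(pmin(pmax(a, 0), 1),
                                     colormode = if (length(dim(img)) == 2L) "Grayscale" else "Color"),
                      path, type = "png", bits = 8L)
  invisible(path)
}
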