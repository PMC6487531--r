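# Preprocessing chain: grayscale / color-edge representations, FLU->VIS
# prescaling, anti-aliased downscaling and background-mat removal.

#' Convert a color image to weighted-luminance grayscale
#'
#' @param img `[h, w, 3]` array (a 1-channel matrix is returned unchanged).
#' @param weights luminance weights for (R, G, B); default ITU-R BT.601.
#' @return grayscale matrix in `[0, 1]`.
#' @export
to_grayscale <- function(img, weights = c(0.299, 0.587, 0.114)) {
  assert_image(img)
  if (img_channels(img) == 1L) return(img)
  stopifnot(length(weights) == 3L, all(weights >= 0))
  g <- img[, , 1L] * weights[1L] + img[, , 2L] * weights[2L] + img[, , 3L] * weights[3L]
  pmin(pmax(g, 0), 1)
}

# central-difference gradients with replicated borders, 0 outside a 1px stencil
grad_xy <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3L || w < 3L) stop("image smaller than the gradient stencil (3x3)", call. = FALSE)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gx[, 1] <- m[, 2] - m[, 1]; gx[, w] <- m[, w] - m[, w - 1]
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  gy[1, ] <- m[2, ] - m[1, ]; gy[h, ] <- m[h, ] - m[h - 1, ]
  list(gx = gx, gy = gy)
}

#' Color-edge (CE) magnitude representation
#'
#' Multi-channel edge magnitude: per pixel, the square root of the largest
#' eigenvalue of the color structure tensor built from per-channel
#' finite-difference gradients (Di Zenzo). For a 1-channel image this reduces
#' to the ordinary gradient magnitude. The result is max-normalized to
#' `[0, 1]`, so it is invariant to global intensity offsets and scalings.
#'
#' @param img 1- or 3-channel image.
#' @return grayscale edge-magnitude matrix in `[0, 1]`.
#' @export
color_edge_magnitude <- function(img) {
  assert_image(img)
  h <- img_height(img); w <- img_width(img)
  j11 <- matrix(0, h, w); j22 <- matrix(0, h, w); j12 <- matrix(0, h, w)
  nch <- img_channels(img)
  for (k in seq_len(nch)) {
    g <- grad_xy(if (nch == 1L) img else img[, , k])
    j11 <- j11 + g$gx^2
    j22 <- j22 + g$gy^2
    j12 <- j12 + g$gx * g$gy
  }
  tr2 <- (j11 + j22) / 2
  lam_max <- tr2 + sqrt(pmax(tr2^2 - (j11 * j22 - j12^2), 0))
  mag <- sqrt(pmax(lam_max, 0))
  mx <- max(mag)
  if (mx > 0) mag <- mag / mx
  mag
}

# Bilinear resampling to an explicit output size; source location of an output
# pixel center is area-consistent: src = (dst + 0.5) * (in/out) - 0.5.
resample_bilinear <- function(img, out_h, out_w) {
  h <- img_height(img); w <- img_width(img)
  sx <- (seq_len(out_w) - 0.5) * (w / out_w) - 0.5
  sy <- (seq_len(out_h) - 0.5) * (h / out_h) - 0.5
  sx <- pmin(pmax(sx, 0), w - 1); sy <- pmin(pmax(sy, 0), h - 1)
  x0 <- pmin(floor(sx), w - 2); y0 <- pmin(floor(sy), h - 2)
  fx <- sx - x0; fy <- sy - y0
  one_channel <- function(m) {
    m00 <- m[y0 + 1, x0 + 1, drop = FALSE]; m01 <- m[y0 + 1, x0 + 2, drop = FALSE]
    m10 <- m[y0 + 2, x0 + 1, drop = FALSE]; m11 <- m[y0 + 2, x0 + 2, drop = FALSE]
    wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
    m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx + m10 * wy * (1 - wx) + m11 * wy * wx
  }
  if (img_channels(img) == 1L) return(one_channel(img))
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (k in 1:3) out[, , k] <- one_channel(img[, , k])
  out
}

round_half_up <- function(x) floor(x + 0.5)

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  if (img_channels(img) == 1L) return(EBImage::gblur(img, sigma = sigma))
  out <- img
  for (k in 1:3) out[, , k] <- EBImage::gblur(img[, , k], sigma = sigma)
  out
}

#' Downscale an image with a Gaussian anti-alias prefilter
#'
#' Output dimensions are `round(dim * factor)` (half-up). A Gaussian prefilter
#' with `sigma = 0.5 * sqrt(1/factor^2 - 1)` suppresses frequencies above the
#' new Nyquist limit before bilinear resampling, so downscaling acts as
#' progressive low-pass smoothing.
#'
#' @param img image to downscale.
#' @param factor scalar in `(0, 1]`; `1` returns a copy of the input.
#' @return resampled image.
#' @export
downscale <- function(img, factor) {
  assert_image(img)
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1)
    stop("downscale factor must be a scalar in (0, 1]", call. = FALSE)
  if (factor == 1) return(img)
  out_h <- max(1L, as.integer(round_half_up(img_height(img) * factor)))
  out_w <- max(1L, as.integer(round_half_up(img_width(img) * factor)))
  sigma <- 0.5 * sqrt(1 / factor^2 - 1)
  resample_bilinear(gaussian_smooth(img, sigma), out_h, out_w)
}

#' Prescale a FLU image to the height of a VIS image
#'
#' The FLU (moving) image is resampled by the single factor
#' `vis_height / flu_height` applied to both dimensions, preserving its aspect
#' ratio; the VIS image is untouched. The factor is returned for provenance so
#' transforms estimated on the prescaled grid can be mapped back to the
#' original FLU grid.
#'
#' @param flu fluorescence image (any channel count).
#' @param vis visible-light image.
#' @return `list(image = resampled flu, factor = vis_height / flu_height)`.
#' @export
prescale_flu_to_vis <- function(flu, vis) {
  assert_image(flu, "flu"); assert_image(vis, "vis")
  if (img_height(flu) < 1L || img_height(vis) < 1L)
    stop("zero-height input", call. = FALSE)
  f <- img_height(vis) / img_height(flu)
  if (f == 1) return(list(image = flu, factor = 1))
  out_h <- as.integer(round_half_up(img_height(flu) * f))
  out_w <- as.integer(round_half_up(img_width(flu) * f))
  pre <- if (f < 1) gaussian_smooth(flu, 0.5 * sqrt(1 / f^2 - 1)) else flu
  list(image = resample_bilinear(pre, out_h, out_w), factor = f)
}

#' Zero out a uniformly colored background mat
#'
#' Default predicate targets the blue carrier mat of top-view acquisitions:
#' a pixel is mat if its blue channel exceeds both red and green by `margin`.
#'
#' @param img `[h, w, 3]` color image (1-channel input is returned unchanged
#'   with a warning).
#' @param margin channel-dominance margin in intensity units (default 0.1);
#'   a margin above 1 makes the predicate unsatisfiable.
#' @param predicate optional replacement rule: function taking the `[h, w, 3]`
#'   array, returning a logical `[h, w]` matrix of mat pixels.
#' @return image with mat pixels set to 0 in all channels.
#' @export
remove_background_mat <- function(img, margin = 0.1, predicate = NULL) {
  assert_image(img)
  if (img_channels(img) == 1L) {
    warning("remove_background_mat: 1-channel input, no-op")
    return(img)
  }
  mat <- if (is.null(predicate)) {
    (img[, , 3L] > img[, , 1L] + margin) & (img[, , 3L] > img[, , 2L] + margin)
  } else {
    predicate(img)
  }
  out <- img
  for (k in 1:3) {
    ch <- out[, , k]; ch[mat] <- 0; out[, , k] <- ch
  }
  out
}

#' Build a registration input representation
#'
#' `"GS"` converts to grayscale; `"CE"` computes the color-edge magnitude
#' (from the full color information when available).
#'
#' @param img 1- or 3-channel image.
#' @param representation `"GS"` or `"CE"`.
#' @return grayscale matrix in `[0, 1]`.
#' @export
build_representation <- function(img, representation = c("GS", "CE")) {
  representation <- match.arg(representation)
  if (representation == "GS") to_grayscale(img) else color_edge_magnitude(img)
}
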