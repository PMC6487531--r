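# Similarity-transform algebra shared by all registration engines.
#
# A similarity transform is a 3x3 homogeneous map on 0-based (x, y) pixel
# coordinates whose top-left 2x2 block is s * R(alpha):
#
#   [ s cos a   -s sin a   tx ]
#   [ s sin a    s cos a   ty ]
#   [ 0          0          1 ]
#
# All engines produce transforms mapping MOVING-image coordinates into
# FIXED-image coordinates.

#' Construct a similarity transform
#'
#' @param s isotropic scale, `> 0`.
#' @param alpha rotation angle in radians (counter-clockwise in the y-down
#'   pixel coordinate frame).
#' @param tx,ty translations in pixels.
#' @return object of class `similarity_transform` with fields `matrix`
#'   (3x3), `s`, `alpha`, `tx`, `ty`.
#' @export
make_similarity <- function(s = 1, alpha = 0, tx = 0, ty = 0) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)
    stop("scale s must be a positive finite scalar", call. = FALSE)
  stopifnot(is.finite(alpha), is.finite(tx), is.finite(ty))
  m <- matrix(c(s * cos(alpha), s * sin(alpha), 0,
                -s * sin(alpha), s * cos(alpha), 0,
                tx, ty, 1), 3L, 3L)
  structure(list(matrix = m, s = s, alpha = alpha, tx = tx, ty = ty),
            class = "similarity_transform")
}

#' Build a similarity transform from a 3x3 matrix
#'
#' Validates the similarity invariants (orthogonal equal-norm columns of the
#' 2x2 block, positive determinant, last row (0, 0, 1)) to tolerance `tol`.
#'
#' @param m 3x3 numeric matrix.
#' @param tol invariant tolerance (default 1e-9, relative to the block norm).
#' @return `similarity_transform`.
#' @export
similarity_from_matrix <- function(m, tol = 1e-9) {
  stopifnot(is.matrix(m), all(dim(m) == 3L), all(is.finite(m)))
  if (max(abs(m[3, ] - c(0, 0, 1))) > tol)
    stop("not a similarity transform: last row must be (0, 0, 1)", call. = FALSE)
  b <- m[1:2, 1:2]
  n1 <- sqrt(sum(b[, 1]^2)); n2 <- sqrt(sum(b[, 2]^2))
  sc <- max(n1, n2, 1)
  if (abs(n1 - n2) > tol * sc || abs(sum(b[, 1] * b[, 2])) > tol * sc^2)
    stop("not a similarity transform: 2x2 block is not a scaled rotation", call. = FALSE)
  if (det(b) <= 0)
    stop("not a similarity transform: det of 2x2 block must be positive", call. = FALSE)
  s <- n1
  alpha <- atan2(m[2, 1], m[1, 1])
  make_similarity(s, alpha, m[1, 3], m[2, 3])
}

#' Decompose a similarity transform into scale, rotation and translations
#'
#' Inverse of [make_similarity()]: `s` is the norm of the first column of the
#' 2x2 block, `alpha = atan2(m[2,1], m[1,1])`, and `(tx, ty)` the third
#' column. Round-trips through [make_similarity()] to within 1e-9.
#'
#' @param t `similarity_transform`.
#' @return named list `(s, alpha, tx, ty)`.
#' @export
decompose_similarity <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  list(s = t$s, alpha = t$alpha, tx = t$tx, ty = t$ty)
}

#' Compose two similarity transforms (matrix product `a %*% b`)
#'
#' The result applies `b` first, then `a`; scales multiply and angles add.
#'
#' @param a,b `similarity_transform` objects.
#' @return `similarity_transform`.
#' @export
compose_transforms <- function(a, b) {
  stopifnot(inherits(a, "similarity_transform"), inherits(b, "similarity_transform"))
  similarity_from_matrix(a$matrix %*% b$matrix, tol = 1e-6)
}

#' Invert a similarity transform
#' @param t `similarity_transform`.
#' @return `similarity_transform` such that composing with `t` yields identity.
#' @export
invert_transform <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  make_similarity(1 / t$s, -t$alpha,
                  -(cos(t$alpha) * t$tx + sin(t$alpha) * t$ty) / t$s,
                  -(-sin(t$alpha) * t$tx + cos(t$alpha) * t$ty) / t$s)
}

#' Similarity transform that rotates/scales about a pixel center
#'
#' Convenience wrapper: scale by `s` and rotate by `alpha` about the point
#' `(cx, cy)`, then translate by `(tx, ty)`.
#'
#' @param s,alpha,tx,ty similarity parameters as in [make_similarity()].
#' @param cx,cy center of rotation/scaling in pixels.
#' @return `similarity_transform`.
#' @export
similarity_about <- function(s, alpha, cx, cy, tx = 0, ty = 0) {
  core <- make_similarity(s, alpha, 0, 0)
  shift_in <- make_similarity(1, 0, -cx, -cy)
  shift_out <- make_similarity(1, 0, cx + tx, cy + ty)
  compose_transforms(shift_out, compose_transforms(core, shift_in))
}

#' Warp an image by a similarity transform
#'
#' The transform maps moving-image coordinates into fixed-image coordinates;
#' the output is sampled on the fixed grid by inverse mapping. Bilinear
#' interpolation is used for intensity images; `interpolation = "nearest"`
#' keeps binary masks binary. Out-of-bounds samples are filled with `fill`.
#'
#' @param img moving image (matrix or `[h, w, 3]` array).
#' @param t `similarity_transform` (moving -> fixed).
#' @param out_height,out_width output (fixed grid) dimensions in pixels;
#'   default: input dimensions.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fill fill value for out-of-bounds samples (default 0).
#' @return warped image on the fixed grid.
#' @export
warp_image <- function(img, t, out_height = img_height(img),
                       out_width = img_width(img),
                       interpolation = c("bilinear", "nearest"), fill = 0) {
  assert_image(img)
  stopifnot(inherits(t, "similarity_transform"))
  interpolation <- match.arg(interpolation)
  inv <- invert_transform(t)$matrix
  h <- img_height(img); w <- img_width(img)
  # column-major traversal of the [out_height, out_width] output
  gx <- rep(0:(out_width - 1L), each = out_height)
  gy <- rep.int(0:(out_height - 1L), out_width)
  sx <- inv[1, 1] * gx + inv[1, 2] * gy + inv[1, 3]
  sy <- inv[2, 1] * gx + inv[2, 2] * gy + inv[2, 3]
  one <- function(m) {
    out <- rep(as.numeric(fill), out_height * out_width)
    if (interpolation == "nearest") {
      xi <- round_half_up(sx); yi <- round_half_up(sy)
      ok <- xi >= 0 & xi <= w - 1 & yi >= 0 & yi <= h - 1
      out[ok] <- m[yi[ok] + 1 + xi[ok] * h]
    } else {
      x0 <- floor(sx); y0 <- floor(sy)
      ok <- x0 >= -1 & x0 <= w - 1 & y0 >= -1 & y0 <= h - 1
      fx <- sx - x0; fy <- sy - y0
      get_px <- function(yy, xx) {
        v <- rep(as.numeric(fill), length(yy))
        ins <- xx >= 0 & xx <= w - 1 & yy >= 0 & yy <= h - 1
        v[ins] <- m[yy[ins] + 1 + xx[ins] * h]
        v
      }
      xo <- x0[ok]; yo <- y0[ok]; fxo <- fx[ok]; fyo <- fy[ok]
      out[ok] <- get_px(yo, xo) * (1 - fyo) * (1 - fxo) +
        get_px(yo, xo + 1) * (1 - fyo) * fxo +
        get_px(yo + 1, xo) * fyo * (1 - fxo) +
        get_px(yo + 1, xo + 1) * fyo * fxo
    }
    matrix(out, out_height, out_width)
  }
  if (img_channels(img) == 1L) return(one(img))
  out <- array(0, dim = c(out_height, out_width, 3L))
  for (k in 1:3) out[, , k] <- one(img[, , k])
  out
}

#' Warp a binary mask (nearest-neighbor, stays binary)
#'
#' @param mask binary matrix (0/1 or logical).
#' @inheritParams warp_image
#' @return 0/1 numeric matrix on the fixed grid.
#' @export
warp_mask <- function(mask, t, out_height = img_height(mask),
                      out_width = img_width(mask)) {
  if (is.logical(mask)) mask <- mask * 1
  w <- warp_image(mask, t, out_height, out_width, interpolation = "nearest")
  (w >= 0.5) * 1
}

#' Conjugate a transform estimated on downscaled grids back to full resolution
#'
#' For a transform `t` estimated between a moving image downscaled by
#' `factor_moving` and a fixed image downscaled by `factor_fixed`, returns
#' `D(1/factor_fixed) %*% t %*% D(factor_moving)` where `D(f)` is pure
#' coordinate scaling. With equal factors `f`, rotation and scale are
#' unchanged and translations are multiplied by `1/f`.
#'
#' @param t `similarity_transform` on the downscaled grids.
#' @param factor_fixed,factor_moving positive downscale factors.
#' @return `similarity_transform` on the full-resolution grids.
#' @export
rescale_transform <- function(t, factor_fixed, factor_moving = factor_fixed) {
  stopifnot(inherits(t, "similarity_transform"))
  if (factor_fixed <= 0 || factor_moving <= 0)
    stop("rescale factors must be positive", call. = FALSE)
  compose_transforms(make_similarity(1 / factor_fixed, 0, 0, 0),
                     compose_transforms(t, make_similarity(factor_moving, 0, 0, 0)))
}

#' Admissibility gate configuration
#'
#' Thresholds defining when an estimated transform counts as a successful
#' registration: translation norm below `max_translation` pixels, rotation
#' with `|sin(alpha)|` below `rotation_bound`, scale inside `scale_interval`
#' (inclusive), and - for phase correlation - peak height above
#' `min_pc_peak`. `rotation_gate = "cos"` switches to the literal bound
#' `|cos(alpha)| < rotation_bound`, which admits only near-90-degree
#' rotations; the default `"sin"` bound admits near-identity rotations
#' (about +-8.6 degrees at 0.15).
#'
#' @param max_translation maximum translation norm in pixels (strict `<`).
#' @param rotation_bound bound on the rotation gate quantity (strict `<`).
#' @param scale_interval inclusive `[low, high]` interval for the scale.
#' @param min_pc_peak phase-correlation peak-height threshold (strict `>`).
#' @param rotation_gate `"sin"` (default) or `"cos"`.
#' @param translation_norm `"euclidean"` (default) or `"per_component"`.
#' @return object of class `gate_config`.
#' @export
gate_config <- function(max_translation = 300, rotation_bound = 0.15,
                        scale_interval = c(0.75, 1.25), min_pc_peak = 0.03,
                        rotation_gate = c("sin", "cos"),
                        translation_norm = c("euclidean", "per_component")) {
  rotation_gate <- match.arg(rotation_gate)
  translation_norm <- match.arg(translation_norm)
  stopifnot(max_translation > 0, rotation_bound > 0, rotation_bound < 1,
            length(scale_interval) == 2L, scale_interval[1] > 0,
            scale_interval[1] <= 1, scale_interval[2] >= 1)
  structure(list(max_translation = max_translation,
                 rotation_bound = rotation_bound,
                 scale_interval = scale_interval,
                 min_pc_peak = min_pc_peak,
                 rotation_gate = rotation_gate,
                 translation_norm = translation_norm),
            class = "gate_config")
}

#' Test a transform against the admissibility gates
#'
#' @param t `similarity_transform`.
#' @param gate `gate_config`.
#' @return list with `flag` (`TRUE` iff every gate passes) and `reasons`
#'   (character vector naming each violated gate: `"translation"`,
#'   `"rotation"`, `"scale"`).
#' @export
is_admissible <- function(t, gate = gate_config()) {
  stopifnot(inherits(t, "similarity_transform"), inherits(gate, "gate_config"))
  reasons <- character(0)
  tn <- if (gate$translation_norm == "euclidean") sqrt(t$tx^2 + t$ty^2)
        else max(abs(t$tx), abs(t$ty))
  if (!(tn < gate$max_translation)) reasons <- c(reasons, "translation")
  rq <- if (gate$rotation_gate == "sin") abs(sin(t$alpha)) else abs(cos(t$alpha))
  if (!(rq < gate$rotation_bound)) reasons <- c(reasons, "rotation")
  if (!(t$s >= gate$scale_interval[1] && t$s <= gate$scale_interval[2]))
    reasons <- c(reasons, "scale")
  list(flag = length(reasons) == 0L, reasons = reasons)
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity_transform: s = %.6g, alpha = %.4g deg, t = (%.4g, %.4g) px\n",
              x$s, x$alpha * 180 / pi, x$tx, x$ty))
  invisible(x)
}

#' Serialize a similarity transform to a JSON-ready list
#'
#' @param t `similarity_transform`.
#' @return list with the row-major 3x3 matrix and decomposed parameters
#'   (`alpha` in degrees), suitable for `jsonlite::write_json`.
#' @export
transform_to_list <- function(t) {
  stopifnot(inherits(t, "similarity_transform"))
  list(matrix = as.vector(t(t$matrix)),
       s = t$s, alpha_degrees = t$alpha * 180 / pi, tx = t$tx, ty = t$ty)
}

#' Deserialize a similarity transform from [transform_to_list()] output
#' @param x list as produced by [transform_to_list()].
#' @return `similarity_transform`.
#' @export
transform_from_list <- function(x) {
  similarity_from_matrix(matrix(as.numeric(x$matrix), 3L, 3L, byrow = TRUE),
                         tol = 1e-6)
}
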