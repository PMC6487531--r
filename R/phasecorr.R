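# Fourier-Mellin phase-correlation registration.
#
# Translation is recovered from the peak of the inverse transform of the
# normalized cross-power spectrum (Fourier shift theorem); rotation and
# isotropic scale are recovered by phase-correlating log-polar resamplings of
# the two magnitude spectra, where rotation becomes a cyclic column shift and
# scaling a row shift.

wrap_shift <- function(d, n) {
  d <- d %% n
  ifelse(d > n / 2, d - n, d)
}

# parabolic 3-point refinement around a 1-D peak (offset in [-0.5, 0.5])
parabolic_offset <- function(l, c, r) {
  den <- l - 2 * c + r
  if (!is.finite(den) || abs(den) < .Machine$double.eps) return(0)
  off <- 0.5 * (l - r) / den
  max(-0.5, min(0.5, off))
}

#' Translation estimation by phase correlation
#'
#' Computes the normalized cross-power spectrum of `a` (reference) and `b`
#' (shifted), inverse-transforms it and locates the global correlation peak
#' with subpixel parabolic refinement over the wrapped 3x3 neighborhood.
#' A cyclic shift of `b` relative to `a` by `(dx, dy)` yields exactly that
#' shift. The peak height `H` of the normalized correlation surface is 1 for
#' a pure cyclic shift and near 0 for unrelated images.
#'
#' @param a fixed (reference) grayscale image.
#' @param b moving grayscale image of identical dimensions.
#' @param subpixel apply parabolic subpixel refinement (default `TRUE`).
#' @return list `(dx, dy, H)`; shifts are wrapped to `(-dim/2, dim/2]`.
#' @export
phase_correlate_translation <- function(a, b, subpixel = TRUE) {
  assert_image(a, "a"); assert_image(b, "b")
  if (img_channels(a) != 1L || img_channels(b) != 1L)
    stop("phase correlation requires 1-channel images", call. = FALSE)
  if (!all(dim(a) == dim(b)))
    stop("phase correlation requires equal image dimensions", call. = FALSE)
  if (nrow(a) < 16L || ncol(a) < 16L)
    stop("images must be at least 16 px per side", call. = FALSE)
  if (all(a == 0) || all(b == 0))
    stop("degenerate all-zero image in phase correlation", call. = FALSE)
  h <- nrow(a); w <- ncol(a)
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fb * Conj(Fa)
  mag <- Mod(R)
  # regularized whitening: bins with negligible energy carry meaningless
  # phase on band-limited images and are damped instead of amplified
  eps <- 1e-6 * max(mag)
  corr <- Re(stats::fft(R / (mag + eps), inverse = TRUE)) / (h * w)
  pk <- which.max(corr)
  H <- corr[pk]
  r0 <- (pk - 1L) %% h           # 0-based row (dy)
  c0 <- (pk - 1L) %/% h          # 0-based col (dx)
  at <- function(r, c) corr[(r %% h) + 1L, (c %% w) + 1L]
  dy <- r0; dx <- c0
  if (isTRUE(subpixel)) {
    dy <- dy + parabolic_offset(at(r0 - 1L, c0), H, at(r0 + 1L, c0))
    dx <- dx + parabolic_offset(at(r0, c0 - 1L), H, at(r0, c0 + 1L))
  }
  list(dx = wrap_shift(dx, w), dy = wrap_shift(dy, h), H = H)
}

# reliability gate on the translation-stage peak height (strict, as printed)
pc_peak_ok <- function(H, gate) H > gate$min_pc_peak

hann2d <- function(h, w) {
  wy <- 0.5 - 0.5 * cos(2 * pi * (0:(h - 1)) / (h - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  outer(wy, wx)
}

fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)), c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

# high-pass emphasized, windowed log-magnitude spectrum, DC at the center
magnitude_spectrum <- function(img, hp_sigma_frac = 0.08) {
  m <- img * hann2d(nrow(img), ncol(img))
  A <- fftshift2(Mod(stats::fft(m)))
  h <- nrow(A); w <- ncol(A)
  cy <- floor(h / 2); cx <- floor(w / 2)
  r2 <- outer(((0:(h - 1)) - cy)^2, rep(1, w)) + outer(rep(1, h), ((0:(w - 1)) - cx)^2)
  rn2 <- r2 / (min(h, w) / 2)^2
  hp <- 1 - exp(-rn2 / (2 * hp_sigma_frac^2))
  log1p(A) * hp
}

#' Log-polar resampling of a (square) image about its center
#'
#' Rows index log-radius over `[log 1, log r_max]` and columns index angle
#' over `[0, pi)` (magnitude spectra of real images are point-symmetric, so
#' half the circle suffices). A rotation of the input becomes a cyclic column
#' shift; a scaling becomes a row shift.
#'
#' @param img square 1-channel image (center = `floor(dim/2)`).
#' @param n_rho,n_theta output grid size; default: the image side length.
#' @return `[n_rho, n_theta]` matrix, bilinearly sampled, 0 outside.
#' @export
logpolar_resample <- function(img, n_rho = nrow(img), n_theta = nrow(img)) {
  assert_image(img)
  if (nrow(img) != ncol(img)) stop("log-polar resampling requires a square image", call. = FALSE)
  n <- nrow(img)
  cy <- floor(n / 2); cx <- floor(n / 2)
  r_max <- n / 2
  rho <- exp(seq(0, log(r_max), length.out = n_rho))
  theta <- seq(0, pi, length.out = n_theta + 1L)[1:n_theta]
  sx <- outer(rho, cos(theta)) + cx
  sy <- outer(rho, sin(theta)) + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get_px <- function(yy, xx) {
    v <- numeric(length(yy))
    ins <- xx >= 0 & xx <= n - 1 & yy >= 0 & yy <= n - 1
    v[ins] <- img[yy[ins] + 1 + xx[ins] * n]
    v
  }
  out <- get_px(y0, x0) * (1 - fy) * (1 - fx) +
    get_px(y0, x0 + 1) * (1 - fy) * fx +
    get_px(y0 + 1, x0) * fy * (1 - fx) +
    get_px(y0 + 1, x0 + 1) * fy * fx
  matrix(out, n_rho, n_theta)
}

#' Phase-correlation engine configuration
#'
#' @param hp_sigma_frac width of the radial high-pass on the magnitude
#'   spectrum, as a fraction of the Nyquist radius.
#' @param n_rho,n_theta log-polar grid size (`NULL` = padded side length).
#' @param refine_iterations number of estimate-and-compose refinement passes
#'   of the full Fourier-Mellin pipeline (default 2).
#' @return list of class `pc_config`.
#' @export
pc_config <- function(hp_sigma_frac = 0.08, n_rho = NULL, n_theta = NULL,
                      refine_iterations = 2L) {
  structure(list(hp_sigma_frac = hp_sigma_frac, n_rho = n_rho,
                 n_theta = n_theta, refine_iterations = as.integer(refine_iterations)),
            class = "pc_config")
}

pad_to <- function(img, h, w) {
  out <- matrix(0, h, w)
  hh <- min(nrow(img), h); ww <- min(ncol(img), w)
  out[1:hh, 1:ww] <- img[1:hh, 1:ww]
  out
}

# single Fourier-Mellin pass on equal-size square images; returns the
# estimated similarity (moving -> fixed) and both stage peak heights
fm_single_pass <- function(moving, fixed, cfg) {
  n <- nrow(fixed)
  sp_f <- magnitude_spectrum(fixed, cfg$hp_sigma_frac)
  sp_m <- magnitude_spectrum(moving, cfg$hp_sigma_frac)
  n_rho <- if (is.null(cfg$n_rho)) n else cfg$n_rho
  n_theta <- if (is.null(cfg$n_theta)) n else cfg$n_theta
  lp_f <- logpolar_resample(sp_f, n_rho, n_theta)
  lp_m <- logpolar_resample(sp_m, n_rho, n_theta)
  pc_rs <- phase_correlate_translation(lp_f, lp_m)
  # moving(x) = fixed(sR(alpha) x + b) makes the moving log-polar magnitude
  # spectrum a copy of the fixed one shifted by +log(s) rows and -alpha
  # columns, so the measured (dy, dx) shift of moving relative to fixed gives
  # s = exp(dy * drho_step) and alpha = -dx * theta_step.
  drho_step <- log(n / 2) / (n_rho - 1)
  alpha <- -pc_rs$dx * pi / n_theta
  s <- exp(pc_rs$dy * drho_step)
  ctr <- (n - 1) / 2
  best <- NULL
  for (cand in c(alpha, alpha + pi)) {
    t_rs <- similarity_about(s, cand, ctr, ctr)
    warped <- warp_image(moving, t_rs, n, n)
    # residual translation d satisfies T(d) o t_rs = full map, i.e. the fixed
    # image is the corrected moving image shifted by +d
    pc_t <- tryCatch(phase_correlate_translation(warped, fixed),
                     error = function(e) NULL)
    if (is.null(pc_t)) next
    if (is.null(best) || pc_t$H > best$H) {
      best <- list(H = pc_t$H, alpha = cand, t_rs = t_rs, pc_t = pc_t)
    }
  }
  if (is.null(best)) return(NULL)
  t_full <- compose_transforms(make_similarity(1, 0, best$pc_t$dx, best$pc_t$dy),
                               best$t_rs)
  list(transform = t_full, H_translation = best$H, H_rotation = pc_rs$H,
       s = s, alpha = best$alpha)
}

#' Fourier-Mellin phase-correlation registration
#'
#' Recovers a full similarity transform (moving -> fixed): rotation and scale
#' from the log-polar phase correlation of the two high-pass-emphasized
#' magnitude spectra (with the 180-degree ambiguity of spectral rotation
#' resolved by trying both candidates and keeping the higher translation-stage
#' peak), then translation from a final Cartesian phase correlation of the
#' rotation/scale-corrected moving image. The estimate is refined by
#' `refine_iterations` compose-and-re-correlate passes. The success flag
#' requires the translation-stage peak height `H` to exceed
#' `gate$min_pc_peak` and the transform to pass the admissibility gate.
#'
#' @param moving,fixed 1-channel images (any sizes; internally zero-padded to
#'   a common FFT-friendly square).
#' @param gate `gate_config` (supplies `min_pc_peak`).
#' @param config `pc_config`.
#' @return `registration_result` with `method = "PC"`, `quality = H`
#'   (translation stage) and the rotation-stage peak in `extra$H_rotation`.
#' @export
register_pc <- function(moving, fixed, gate = gate_config(), config = pc_config()) {
  assert_image(moving, "moving"); assert_image(fixed, "fixed")
  if (img_channels(moving) != 1L || img_channels(fixed) != 1L)
    stop("register_pc requires 1-channel (preprocessed) images", call. = FALSE)
  n <- stats::nextn(max(dim(moving), dim(fixed)), c(2, 3, 5))
  mov <- pad_to(moving, n, n); fix <- pad_to(fixed, n, n)
  if (all(mov == 0) || all(fix == 0))
    return(failed_result("PC", "degenerate input"))
  acc <- make_similarity(1, 0, 0, 0)
  cur <- mov
  best <- NULL
  iters <- max(1L, config$refine_iterations)
  for (i in seq_len(iters)) {
    est <- tryCatch(fm_single_pass(cur, fix, config), error = function(e) NULL)
    if (is.null(est)) break
    acc_new <- compose_transforms(est$transform, acc)
    cand <- list(transform = acc_new, H = est$H_translation,
                 H_rotation = est$H_rotation)
    if (is.null(best) || cand$H >= best$H) {
      best <- cand
      acc <- acc_new
      cur <- warp_image(mov, acc, n, n)
    } else break
  }
  if (is.null(best))
    return(failed_result("PC", "phase correlation failed"))
  adm <- is_admissible(best$transform, gate)
  reasons <- adm$reasons
  if (!pc_peak_ok(best$H, gate)) reasons <- c("peak below threshold", reasons)
  registration_result(best$transform, "PC",
                      success = length(reasons) == 0L,
                      quality = best$H, reasons = reasons,
                      extra = list(H_translation = best$H,
                                   H_rotation = best$H_rotation,
                                   padded_size = n))
}
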