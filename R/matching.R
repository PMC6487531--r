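# Descriptor extraction, ratio-test + cross-check matching, and robust
# similarity estimation from point correspondences (2-point RANSAC with
# closed-form least-squares refit).

# evaluate RNG-dependent code under a local seed, restoring global state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# bilinear patch sampler centered at (x, y) with pixel spacing `step`
sample_patch <- function(img, x, y, half = 6L, step = 1) {
  g <- seq(-half, half) * step
  sx <- outer(rep(1, length(g)), g) + x
  sy <- outer(g, rep(1, length(g))) + y
  h <- nrow(img); w <- ncol(img)
  sx <- pmin(pmax(sx, 0), w - 1); sy <- pmin(pmax(sy, 0), h - 1)
  x0 <- pmin(floor(sx), w - 2); y0 <- pmin(floor(sy), h - 2)
  fx <- sx - x0; fy <- sy - y0
  img[y0 + 1 + x0 * h] * (1 - fy) * (1 - fx) +
    img[y0 + 1 + (x0 + 1) * h] * (1 - fy) * fx +
    img[y0 + 2 + x0 * h] * fy * (1 - fx) +
    img[y0 + 2 + (x0 + 1) * h] * fy * fx
}

descriptor_patch <- function(img, pts, half = 6L) {
  n <- nrow(pts)
  out <- matrix(0, n, (2L * half + 1L)^2)
  for (i in seq_len(n)) {
    step <- max(1, pts$scale[i] / 3)
    p <- sample_patch(img, pts$x[i], pts$y[i], half, step)
    p <- p - mean(p)
    nrm <- sqrt(sum(p^2))
    if (nrm > 1e-12) p <- p / nrm
    out[i, ] <- as.vector(p)
  }
  out
}

descriptor_gradhist <- function(img, pts, cells = 4L, bins = 8L) {
  half <- 8L
  g <- grad_xy(img)
  n <- nrow(pts)
  out <- matrix(0, n, cells * cells * bins)
  h <- nrow(img); w <- ncol(img)
  for (i in seq_len(n)) {
    step <- max(1, pts$scale[i] / 4)
    gxp <- sample_patch(g$gx, pts$x[i], pts$y[i], half, step)
    gyp <- sample_patch(g$gy, pts$x[i], pts$y[i], half, step)
    mag <- sqrt(gxp^2 + gyp^2)
    ang <- (atan2(gyp, gxp) + pi) / (2 * pi) # [0,1]
    side <- 2L * half + 1L
    cell_ix <- pmin(cells - 1L, floor((col(mag) - 1L) / side * cells))
    cell_iy <- pmin(cells - 1L, floor((row(mag) - 1L) / side * cells))
    bin <- pmin(bins - 1L, floor(ang * bins))
    idx <- 1L + bin + bins * (cell_ix + cells * cell_iy)
    v <- numeric(cells * cells * bins)
    acc <- rowsum(as.vector(mag), as.vector(idx))
    v[as.integer(rownames(acc))] <- acc
    nrm <- sqrt(sum(v^2))
    if (nrm > 1e-12) v <- v / nrm
    out[i, ] <- v
  }
  out
}

#' Describe feature points and match them across two images
#'
#' Computes local descriptors at every point (`"patch"`: normalized image
#' patch sampled at the point's characteristic scale; `"gradhist"`:
#' gradient-orientation histogram), then matches moving to fixed descriptors
#' by nearest neighbor with a Lowe ratio test and a mutual cross-check.
#'
#' @param moving_pts,fixed_pts feature `data.frame`s from
#'   [detect_features()] / [multifeature_detect()].
#' @param moving_img,fixed_img the 1-channel images the points came from.
#' @param descriptor `"patch"` (default) or `"gradhist"`.
#' @param ratio Lowe ratio-test threshold (default 0.8).
#' @return `data.frame` with columns `moving` and `fixed` (row indices into
#'   the point sets) and `distance`; zero rows if nothing survives.
#' @export
describe_and_match <- function(moving_pts, fixed_pts, moving_img, fixed_img,
                               descriptor = c("patch", "gradhist"), ratio = 0.8) {
  descriptor <- match.arg(descriptor)
  empty <- data.frame(moving = integer(0), fixed = integer(0), distance = numeric(0))
  if (nrow(moving_pts) == 0L || nrow(fixed_pts) == 0L) return(empty)
  desc_fun <- if (descriptor == "patch") descriptor_patch else descriptor_gradhist
  dm <- desc_fun(moving_img, moving_pts)
  df <- desc_fun(fixed_img, fixed_pts)
  # squared euclidean distance matrix (moving x fixed)
  d2 <- outer(rowSums(dm^2), rowSums(df^2), "+") - 2 * dm %*% t(df)
  d2 <- pmax(d2, 0)
  nf <- ncol(d2)
  best_f <- max.col(-d2, ties.method = "first")
  best_d <- d2[cbind(seq_len(nrow(d2)), best_f)]
  if (nf >= 2L) {
    second <- vapply(seq_len(nrow(d2)), function(i) {
      v <- d2[i, ]; v[best_f[i]] <- Inf; min(v)
    }, 0)
    pass_ratio <- sqrt(best_d) <= ratio * sqrt(second)
  } else pass_ratio <- rep(TRUE, nrow(d2))
  # mutual cross-check
  best_m_for_f <- max.col(-t(d2), ties.method = "first")
  mutual <- best_m_for_f[best_f] == seq_len(nrow(d2))
  keep <- which(pass_ratio & mutual)
  data.frame(moving = keep, fixed = best_f[keep],
             distance = sqrt(best_d[keep]))
}

# closed-form similarity q ~= z p + t on complex coordinates; returns NULL
# for degenerate (coincident) configurations
fit_similarity_ls <- function(px, py, qx, qy) {
  p <- complex(real = px, imaginary = py)
  q <- complex(real = qx, imaginary = qy)
  pm <- mean(p); qm <- mean(q)
  den <- sum(Mod(p - pm)^2)
  if (den < 1e-12) return(NULL)
  z <- sum(Conj(p - pm) * (q - qm)) / den
  if (Mod(z) < 1e-12) return(NULL)
  tr <- qm - z * pm
  make_similarity(Mod(z), Arg(z), Re(tr), Im(tr))
}

#' Robust similarity estimation from matched feature points
#'
#' Random-sample consensus over minimal two-point samples, each solved in
#' closed form on complex coordinates, followed by a least-squares refit on
#' the largest inlier set. Deterministic for a fixed `seed`.
#'
#' @param matches match `data.frame` from [describe_and_match()].
#' @param moving_pts,fixed_pts the point sets the match indices refer to.
#' @param inlier_threshold inlier residual threshold in pixels (default 3).
#' @param max_iterations consensus iteration cap (default 2000); iterations
#'   stop early once 99% confidence of having seen an outlier-free sample is
#'   reached.
#' @param confidence early-exit confidence (default 0.99).
#' @param seed RNG seed for sampling (default 1).
#' @return list with `transform` (`similarity_transform` or `NULL`),
#'   `inliers` (logical vector over matches), `n_inliers`, and `ok`.
#' @export
estimate_similarity_robust <- function(matches, moving_pts, fixed_pts,
                                       inlier_threshold = 3,
                                       max_iterations = 2000L,
                                       confidence = 0.99, seed = 1L) {
  n <- nrow(matches)
  fail <- list(transform = NULL, inliers = logical(0), n_inliers = 0L, ok = FALSE)
  if (is.null(matches) || n < 2L) return(fail)
  px <- moving_pts$x[matches$moving]; py <- moving_pts$y[matches$moving]
  qx <- fixed_pts$x[matches$fixed]; qy <- fixed_pts$y[matches$fixed]
  if (n == 2L) {
    t2 <- fit_similarity_ls(px, py, qx, qy)
    # the 2-point problem is exactly determined; degenerate if coincident
    if (is.null(t2)) return(fail)
    return(list(transform = t2, inliers = rep(TRUE, 2L), n_inliers = 2L, ok = TRUE))
  }
  thr2 <- inlier_threshold^2
  best_inl <- NULL; best_n <- 1L
  with_seed(seed, {
    it <- 0L; needed <- max_iterations
    while (it < min(needed, max_iterations)) {
      it <- it + 1L
      s <- sample.int(n, 2L)
      tc <- fit_similarity_ls(px[s], py[s], qx[s], qy[s])
      if (is.null(tc)) next
      m <- tc$matrix
      rx <- m[1, 1] * px + m[1, 2] * py + m[1, 3] - qx
      ry <- m[2, 1] * px + m[2, 2] * py + m[2, 3] - qy
      inl <- (rx^2 + ry^2) <= thr2
      ni <- sum(inl)
      if (ni > best_n) {
        best_n <- ni; best_inl <- inl
        w <- ni / n
        needed <- ceiling(log(1 - confidence) / log(1 - w^2))
      }
    }
  })
  if (is.null(best_inl) || best_n < 2L) return(fail)
  tf <- fit_similarity_ls(px[best_inl], py[best_inl], qx[best_inl], qy[best_inl])
  if (is.null(tf)) return(fail)
  # refreshed inlier set under the refit transform
  m <- tf$matrix
  rx <- m[1, 1] * px + m[1, 2] * py + m[1, 3] - qx
  ry <- m[2, 1] * px + m[2, 2] * py + m[2, 3] - qy
  inl <- (rx^2 + ry^2) <= thr2
  if (sum(inl) >= 2L) {
    tf2 <- fit_similarity_ls(px[inl], py[inl], qx[inl], qy[inl])
    if (!is.null(tf2)) { tf <- tf2; best_inl <- inl; best_n <- sum(inl) }
  }
  list(transform = tf, inliers = best_inl, n_inliers = best_n, ok = TRUE)
}

#' Feature-point registration engine
#'
#' Chains [multifeature_detect()], [describe_and_match()] and
#' [estimate_similarity_robust()]. The success flag requires both a
#' successful estimation and an admissible transform.
#'
#' @param moving,fixed preprocessed 1-channel images (GS or CE).
#' @param gate `gate_config`.
#' @param detectors detector tags for the multifeature generator.
#' @param descriptor,ratio passed to [describe_and_match()].
#' @param inlier_threshold,max_iterations,seed passed to
#'   [estimate_similarity_robust()].
#' @param merge_radius multifeature merge radius in pixels.
#' @return `registration_result` with `method = "FP"` and
#'   `quality = inlier count`.
#' @export
register_fp <- function(moving, fixed, gate = gate_config(),
                        detectors = c("harris", "fast", "blob_dog"),
                        descriptor = "patch", ratio = 0.8,
                        inlier_threshold = 3, max_iterations = 2000L,
                        seed = 1L, merge_radius = 2) {
  assert_image(moving, "moving"); assert_image(fixed, "fixed")
  if (img_channels(moving) != 1L || img_channels(fixed) != 1L)
    stop("register_fp requires 1-channel (preprocessed) images", call. = FALSE)
  mp <- multifeature_detect(moving, detectors, merge_radius = merge_radius)
  fp <- multifeature_detect(fixed, detectors, merge_radius = merge_radius)
  if (nrow(mp) < 2L || nrow(fp) < 2L)
    return(failed_result("FP", "insufficient features"))
  matches <- describe_and_match(mp, fp, moving, fixed,
                                descriptor = descriptor, ratio = ratio)
  if (nrow(matches) < 2L)
    return(failed_result("FP", "insufficient matches",
                         extra = list(n_moving = nrow(mp), n_fixed = nrow(fp))))
  est <- estimate_similarity_robust(matches, mp, fp,
                                    inlier_threshold = inlier_threshold,
                                    max_iterations = max_iterations, seed = seed)
  if (!est$ok)
    return(failed_result("FP", "estimation failed",
                         extra = list(n_matches = nrow(matches))))
  adm <- is_admissible(est$transform, gate)
  registration_result(est$transform, "FP",
                      success = adm$flag, quality = est$n_inliers,
                      reasons = adm$reasons,
                      extra = list(n_moving = nrow(mp), n_fixed = nrow(fp),
                                   n_matches = nrow(matches),
                                   inlier_fraction = est$n_inliers / nrow(matches),
                                   seed = seed))
}
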