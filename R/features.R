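# Feature-point detection: corner (Harris, Shi-Tomasi, FAST, multi-scale),
# region (MSER-like) and blob (DoG, DoH) detectors, plus the integrative
# multifeature merger that pools detections across detectors.

#' Supported feature detector tags
#' @export
FEATURE_DETECTORS <- c("harris", "shi_tomasi", "fast", "brisk_like",
                       "mser", "blob_dog", "blob_doh")

# 3x3-neighborhood local maxima of a response matrix (strict against ties
# resolved by first occurrence), excluding a border margin
local_maxima <- function(r, threshold, border = 3L) {
  h <- nrow(r); w <- ncol(r)
  if (h < 2L * border + 3L || w < 2L * border + 3L) return(cbind(x = integer(0), y = integer(0)))
  p <- matrix(-Inf, h + 2L, w + 2L)
  p[2:(h + 1L), 2:(w + 1L)] <- r
  ok <- r >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ok <- ok & (r >= p[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx])
  }
  # strictness against at least one neighbor avoids plateaus firing everywhere
  strict <- r > pmin(p[(2:(h + 1L)), (2:(w + 1L)) + 1L], p[(2:(h + 1L)) + 1L, 2:(w + 1L)])
  ok <- ok & strict
  ok[c(seq_len(border), h - seq_len(border) + 1L), ] <- FALSE
  ok[, c(seq_len(border), w - seq_len(border) + 1L)] <- FALSE
  idx <- which(ok)
  cbind(x = (idx - 1L) %/% h, y = (idx - 1L) %% h)
}

feature_frame <- function(x, y, scale, response, detector) {
  data.frame(x = as.numeric(x), y = as.numeric(y),
             scale = as.numeric(scale), response = as.numeric(response),
             detector = rep_len(detector, length(x)),
             stringsAsFactors = FALSE)
}

structure_tensor <- function(img, sigma = 1.5) {
  g <- grad_xy(img)
  list(jxx = EBImage::gblur(g$gx^2, sigma = sigma),
       jyy = EBImage::gblur(g$gy^2, sigma = sigma),
       jxy = EBImage::gblur(g$gx * g$gy, sigma = sigma))
}

detect_harris <- function(img, k = 0.04, rel_threshold = 0.01, sigma = 1.5,
                          max_points = 500L) {
  st <- structure_tensor(img, sigma)
  r <- (st$jxx * st$jyy - st$jxy^2) - k * (st$jxx + st$jyy)^2
  mx <- max(r)
  # floor guards against numerical noise on (near-)constant images
  if (mx <= 1e-12) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), "harris"))
  pts <- local_maxima(r, rel_threshold * mx)
  feature_frame(pts[, "x"], pts[, "y"], sigma, r[pts[, "y"] + 1 + pts[, "x"] * nrow(r)], "harris")
}

detect_shi_tomasi <- function(img, rel_threshold = 0.01, sigma = 1.5) {
  st <- structure_tensor(img, sigma)
  tr2 <- (st$jxx + st$jyy) / 2
  r <- tr2 - sqrt(pmax(tr2^2 - (st$jxx * st$jyy - st$jxy^2), 0))
  mx <- max(r)
  if (mx <= 1e-12) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), "shi_tomasi"))
  pts <- local_maxima(r, rel_threshold * mx)
  feature_frame(pts[, "x"], pts[, "y"], sigma, r[pts[, "y"] + 1 + pts[, "x"] * nrow(r)], "shi_tomasi")
}

# segment-test corner detector (FAST-9 style) on a radius-3 Bresenham circle
detect_fast <- function(img, threshold = 0.06, arc = 9L) {
  h <- nrow(img); w <- ncol(img)
  off <- cbind(dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
               dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3))
  pad <- 3L
  p <- matrix(0, h + 2L * pad, w + 2L * pad)
  p[(pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- img
  ring <- array(0, dim = c(h, w, 16L))
  for (i in 1:16) {
    ring[, , i] <- p[(pad + 1L):(pad + h) + off[i, "dy"], (pad + 1L):(pad + w) + off[i, "dx"]]
  }
  brighter <- sweep(ring, c(1, 2), img + threshold, ">")
  darker <- sweep(ring, c(1, 2), img - threshold, "<")
  has_arc <- function(b) {
    any_run <- matrix(FALSE, h, w)
    for (s in 1:16) {
      run <- matrix(TRUE, h, w)
      for (j in 0:(arc - 1L)) run <- run & b[, , ((s + j - 1L) %% 16L) + 1L]
      any_run <- any_run | run
      if (all(any_run)) break
    }
    any_run
  }
  corner <- has_arc(brighter) | has_arc(darker)
  # response: summed absolute ring contrast
  resp <- apply(abs(sweep(ring, c(1, 2), img, "-")), c(1, 2), sum)
  resp[!corner] <- 0
  pts <- local_maxima(resp, threshold = .Machine$double.eps, border = 3L)
  if (nrow(pts) == 0L) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), "fast"))
  feature_frame(pts[, "x"], pts[, "y"], 3, resp[pts[, "y"] + 1 + pts[, "x"] * h], "fast")
}

# multi-scale corner detector: Harris response over a downscale pyramid
detect_brisk_like <- function(img, octaves = c(1, 0.7, 0.5), rel_threshold = 0.02) {
  out <- list()
  for (f in octaves) {
    lvl <- if (f == 1) img else downscale(img, f)
    if (nrow(lvl) < 16L || ncol(lvl) < 16L) next
    d <- detect_harris(lvl, rel_threshold = rel_threshold)
    if (nrow(d) == 0L) next
    d$x <- d$x / f; d$y <- d$y / f; d$scale <- d$scale / f
    d$detector <- "brisk_like"
    out[[length(out) + 1L]] <- d
  }
  if (length(out) == 0L) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), "brisk_like"))
  do.call(rbind, out)
}

# maximally-stable-extremal-region-style detector: centroids of connected
# bright/dark regions whose area is stable across consecutive thresholds
detect_mser <- function(img, levels = seq(0.15, 0.85, by = 0.1),
                        min_area = 20L, max_area_frac = 0.25,
                        stability = 0.25, match_dist = 3) {
  h <- nrow(img); w <- ncol(img)
  max_area <- max_area_frac * h * w
  regions_at <- function(bin) {
    lbl <- EBImage::bwlabel(bin)
    n <- max(lbl)
    if (n == 0L) return(NULL)
    idx <- which(lbl > 0)
    lab <- lbl[idx]
    area <- tabulate(lab, n)
    ys <- (idx - 1L) %% h; xs <- (idx - 1L) %/% h
    cx <- tapply(xs, lab, mean); cy <- tapply(ys, lab, mean)
    keep <- area >= min_area & area <= max_area
    if (!any(keep)) return(NULL)
    data.frame(x = as.numeric(cx[keep]), y = as.numeric(cy[keep]),
               area = area[keep])
  }
  found <- list()
  for (polarity in c(1, -1)) {
    prev <- NULL
    for (t in levels) {
      cur <- regions_at(if (polarity > 0) (img > t) * 1 else (img < t) * 1)
      if (!is.null(prev) && !is.null(cur)) {
        for (i in seq_len(nrow(cur))) {
          dd <- sqrt((prev$x - cur$x[i])^2 + (prev$y - cur$y[i])^2)
          j <- which.min(dd)
          if (length(j) == 1L && dd[j] <= match_dist &&
              abs(prev$area[j] - cur$area[i]) <= stability * pmax(prev$area[j], cur$area[i])) {
            found[[length(found) + 1L]] <-
              feature_frame(cur$x[i], cur$y[i], sqrt(cur$area[i] / pi),
                            1 / (1e-6 + abs(prev$area[j] - cur$area[i]) / cur$area[i]),
                            "mser")
          }
        }
      }
      prev <- cur
    }
  }
  if (length(found) == 0L) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), "mser"))
  d <- do.call(rbind, found)
  # collapse duplicates of the same region found at several threshold pairs
  merge_nearby_points(d, radius = match_dist)
}

dog_sigmas <- function(min_sigma = 1.6, max_sigma = 16, ratio = 1.35) {
  n <- ceiling(log(max_sigma / min_sigma) / log(ratio)) + 1L
  min_sigma * ratio^(0:(n - 1L))
}

# scale-normalized difference-of-Gaussians blob detector
detect_blob_dog <- function(img, min_sigma = 1.6, max_sigma = 16,
                            ratio = 1.35, rel_threshold = 0.1) {
  # Gaussian brush must fit inside the image
  max_sigma <- max(min_sigma, min(max_sigma, (min(dim(img)) - 3) / 8))
  sig <- dog_sigmas(min_sigma, max_sigma, ratio)
  gs <- lapply(sig, function(s) EBImage::gblur(img, sigma = s))
  n_l <- length(sig) - 1L
  dogs <- vector("list", n_l)
  for (i in seq_len(n_l)) {
    # normalization by sigma/(delta sigma) approximates scale-normalized LoG
    dogs[[i]] <- (gs[[i]] - gs[[i + 1L]]) * sig[i] / (sig[i + 1L] - sig[i])
  }
  blob_scale_space_maxima(dogs, sqrt(sig[-length(sig)] * sig[-1L]), rel_threshold, "blob_dog")
}

# scale-normalized determinant-of-Hessian blob detector
detect_blob_doh <- function(img, min_sigma = 1.6, max_sigma = 16,
                            ratio = 1.35, rel_threshold = 0.05) {
  max_sigma <- max(min_sigma, min(max_sigma, (min(dim(img)) - 3) / 8))
  sig <- dog_sigmas(min_sigma, max_sigma, ratio)
  dets <- lapply(sig, function(s) {
    g <- EBImage::gblur(img, sigma = s)
    d1 <- grad_xy(g)
    dxx <- grad_xy(d1$gx)$gx
    dyy <- grad_xy(d1$gy)$gy
    dxy <- grad_xy(d1$gx)$gy
    s^4 * (dxx * dyy - dxy^2)
  })
  blob_scale_space_maxima(dets, sig, rel_threshold, "blob_doh")
}

blob_scale_space_maxima <- function(layers, scales, rel_threshold, tag) {
  n_l <- length(layers)
  mx <- max(vapply(layers, max, 0))
  if (mx <= 1e-12) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), tag))
  thr <- rel_threshold * mx
  out <- list()
  for (i in seq_len(n_l)) {
    pts <- local_maxima(layers[[i]], thr, border = 3L)
    if (nrow(pts) == 0L) next
    v <- layers[[i]][pts[, "y"] + 1 + pts[, "x"] * nrow(layers[[i]])]
    keep <- rep(TRUE, nrow(pts))
    for (j in c(i - 1L, i + 1L)) {
      if (j < 1L || j > n_l) next
      keep <- keep & v >= layers[[j]][pts[, "y"] + 1 + pts[, "x"] * nrow(layers[[j]])]
    }
    if (!any(keep)) next
    out[[length(out) + 1L]] <- feature_frame(pts[keep, "x"], pts[keep, "y"],
                                             scales[i], v[keep], tag)
  }
  if (length(out) == 0L) return(feature_frame(numeric(0), numeric(0), numeric(0), numeric(0), tag))
  merge_nearby_points(do.call(rbind, out), radius = 2)
}

# greedy highest-response-first deduplication of points within `radius` px
merge_nearby_points <- function(d, radius = 2) {
  if (nrow(d) <= 1L) return(d)
  d <- d[order(-d$response), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(d)) > i)
    if (length(later) == 0L) next
    dd <- sqrt((d$x[later] - d$x[i])^2 + (d$y[later] - d$y[i])^2)
    keep[later[dd < radius]] <- FALSE
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Detect feature points with a single detector
#'
#' Supported detectors: `"harris"`, `"shi_tomasi"` (minimum-eigenvalue
#' corners), `"fast"` (segment-test corners), `"brisk_like"` (multi-scale
#' corners over a downscale pyramid), `"mser"` (stable extremal regions),
#' `"blob_dog"` (scale-normalized difference of Gaussians) and `"blob_doh"`
#' (scale-normalized determinant of Hessian).
#'
#' @param img 1-channel image in `[0, 1]`.
#' @param detector detector tag (see [FEATURE_DETECTORS]).
#' @param ... detector-specific parameters (thresholds, sigmas).
#' @return `data.frame` with columns `x`, `y` (0-based pixel coordinates),
#'   `scale` (characteristic radius, px), `response` and `detector`,
#'   sorted by descending response.
#' @export
detect_features <- function(img, detector = "harris", ...) {
  assert_image(img)
  if (img_channels(img) != 1L) stop("detect_features requires a grayscale image", call. = FALSE)
  d <- switch(detector,
              harris = detect_harris(img, ...),
              shi_tomasi = detect_shi_tomasi(img, ...),
              fast = detect_fast(img, ...),
              brisk_like = detect_brisk_like(img, ...),
              mser = detect_mser(img, ...),
              blob_dog = detect_blob_dog(img, ...),
              blob_doh = detect_blob_doh(img, ...),
              stop("unknown detector tag: ", detector, call. = FALSE))
  d <- d[order(-d$response), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Integrative multifeature detection
#'
#' Pools the outputs of several detectors and collapses detections closer
#' than `merge_radius` pixels to the highest-response one, keeping each
#' point's detector tag for provenance.
#'
#' @param img 1-channel image.
#' @param detectors nonempty character vector of detector tags.
#' @param merge_radius deduplication radius in pixels (default 2).
#' @param max_points keep at most this many highest-response points per
#'   detector before merging (default 300).
#' @return feature `data.frame` as in [detect_features()].
#' @export
multifeature_detect <- function(img, detectors = c("harris", "fast", "blob_dog"),
                                merge_radius = 2, max_points = 300L) {
  if (length(detectors) == 0L) stop("at least one detector tag required", call. = FALSE)
  parts <- lapply(detectors, function(tag) {
    d <- detect_features(img, tag)
    head(d, max_points)
  })
  d <- do.call(rbind, parts)
  if (nrow(d) == 0L) return(d)
  # responses of different detectors are not commensurable: rank-normalize
  # within detector before cross-detector deduplication
  d$response_raw <- d$response
  for (tag in unique(d$detector)) {
    i <- d$detector == tag
    d$response[i] <- rank(d$response_raw[i]) / sum(i)
  }
  d <- merge_nearby_points(d, radius = merge_radius)
  d[order(-d$response), , drop = FALSE]
}
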