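# Seeded generator of multimodal plant phantoms: one silhouette rendered as a
# high-contrast grayscale fluorescence (FLU) image and as a cluttered color
# visible-light (VIS) image, with known ground-truth transforms and exact
# masks. Canvas defaults preserve the aspect ratios and FLU/VIS height ratio
# of the top-view acquisition geometry (VIS 2454x2056, FLU 1624x1234 h x w)
# at 1/8 linear scale, so the full pipeline runs at desk scale.

#' Phantom pair specification
#'
#' @param seed integer seed; every random choice derives from it.
#' @param vis_canvas,flu_canvas `(height, width)` in pixels per modality.
#' @param n_leaves number of leaves around the stem (default 7).
#' @param leaf_length range of leaf lengths as fractions of the smaller VIS
#'   canvas dimension.
#' @param leaf_width_frac leaf half-width as a fraction of its length.
#' @param curvature range of leaf bending coefficients (unitless).
#' @param truth ground-truth similarity parameters `(s, alpha_rad, tx, ty)`
#'   applied about the plant center: the transform mapping prescaled-FLU
#'   coordinates into VIS coordinates.
#' @param leaf_offsets optional per-leaf residual rigid offsets: a list of
#'   `(dx, dy, dtheta_rad)` vectors of length `n_leaves`, composed with
#'   `truth` per leaf (nonuniform motion).
#' @param flu_noise,vis_noise Gaussian noise standard deviations.
#' @param n_clutter number of background clutter blobs in the VIS rendering
#'   (a third of them with plant-like color).
#' @param use_mat add a uniformly colored blue background mat to VIS.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         vis_canvas = c(307L, 257L), flu_canvas = c(203L, 154L),
                         n_leaves = 7L,
                         leaf_length = c(0.18, 0.34), leaf_width_frac = 0.5,
                         curvature = c(-0.25, 0.25),
                         truth = c(s = 1, alpha = 0, tx = 0, ty = 0),
                         leaf_offsets = NULL,
                         flu_noise = 0.02, vis_noise = 0.02,
                         n_clutter = 18L, use_mat = FALSE) {
  stopifnot(length(vis_canvas) == 2L, length(flu_canvas) == 2L, n_leaves >= 1L)
  if (min(vis_canvas) < 64L || min(flu_canvas) < 48L)
    stop("canvas too small for a plant phantom", call. = FALSE)
  if (!is.null(leaf_offsets) && length(leaf_offsets) != n_leaves)
    stop("leaf_offsets must have one entry per leaf", call. = FALSE)
  structure(list(seed = as.integer(seed), vis_canvas = as.integer(vis_canvas),
                 flu_canvas = as.integer(flu_canvas), n_leaves = as.integer(n_leaves),
                 leaf_length = leaf_length, leaf_width_frac = leaf_width_frac,
                 curvature = curvature,
                 truth = c(s = unname(truth[1]), alpha = unname(truth[2]),
                           tx = unname(truth[3]), ty = unname(truth[4])),
                 leaf_offsets = leaf_offsets,
                 flu_noise = flu_noise, vis_noise = vis_noise,
                 n_clutter = as.integer(n_clutter), use_mat = use_mat),
            class = "phantom_spec")
}

# leaf geometry sampled from a spec (deterministic under the spec seed)
sample_leaf_params <- function(spec, cx, cy) {
  n <- spec$n_leaves
  base <- runif(1, 0, 2 * pi)
  phis <- base + 2 * pi * (0:(n - 1)) / n + rnorm(n, 0, 0.12)
  lmin <- min(spec$vis_canvas)
  lens <- runif(n, spec$leaf_length[1], spec$leaf_length[2]) * lmin
  widths <- lens * spec$leaf_width_frac * runif(n, 0.8, 1.1)
  kappas <- runif(n, spec$curvature[1], spec$curvature[2])
  list(cx = cx, cy = cy, phi = phis, len = lens, wid = widths, kappa = kappas,
       stem_r = 0.035 * lmin)
}

# analytic membership of VIS-frame points (x, y) in leaf `l` (or stem l = 0)
leaf_member <- function(leaves, l, x, y) {
  if (l == 0L) {
    return((x - leaves$cx)^2 + (y - leaves$cy)^2 <= leaves$stem_r^2)
  }
  u <- cos(leaves$phi[l]) * (x - leaves$cx) + sin(leaves$phi[l]) * (y - leaves$cy)
  v <- -sin(leaves$phi[l]) * (x - leaves$cx) + cos(leaves$phi[l]) * (y - leaves$cy)
  L <- leaves$len[l]
  v <- v - leaves$kappa[l] * u^2 / L
  tt <- pmin(pmax(u / L, 0), 1)
  inside <- u >= 0 & u <= L & abs(v) <= leaves$wid[l] * 0.5 * sin(pi * tt)^0.7
  inside
}

# binary mask of the whole plant on an arbitrary grid: point (x, y) on that
# grid maps into the VIS frame through `to_vis` (a similarity transform)
render_mask <- function(leaves, n_leaves, h, w, to_vis = NULL, per_leaf = NULL) {
  gx <- rep(0:(w - 1L), each = h)
  gy <- rep.int(0:(h - 1L), w)
  if (!is.null(to_vis)) {
    m <- to_vis$matrix
    bx <- m[1, 1] * gx + m[1, 2] * gy + m[1, 3]
    by <- m[2, 1] * gx + m[2, 2] * gy + m[2, 3]
  } else { bx <- gx; by <- gy }
  mask <- matrix(0, h, w)
  leaf_id <- matrix(0L, h, w)
  for (l in 0:n_leaves) {
    if (is.null(per_leaf)) {
      px <- bx; py <- by
    } else {
      # per-leaf placement: invert that leaf's own VIS-frame transform
      tl <- per_leaf[[max(l, 1L)]]
      inv <- invert_transform(tl)$matrix
      px <- inv[1, 1] * bx + inv[1, 2] * by + inv[1, 3]
      py <- inv[2, 1] * bx + inv[2, 2] * by + inv[2, 3]
    }
    inside <- leaf_member(leaves, l, px, py)
    mask[inside] <- 1
    leaf_id[inside & leaf_id == 0L] <- l
  }
  list(mask = mask, leaf_id = leaf_id)
}

smooth_field <- function(h, w, sigma = 8) {
  f <- EBImage::gblur(matrix(rnorm(h * w), h, w), sigma = sigma)
  f / max(abs(f), 1e-12)
}

draw_clutter <- function(img, n_blobs, h, w, plantlike_color) {
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1)
    ax <- runif(1, 3, 0.08 * w); ay <- runif(1, 3, 0.08 * h)
    th <- runif(1, 0, pi)
    col <- if (i %% 3 == 0L) plantlike_color * runif(1, 0.8, 1.2)
           else runif(3, 0.1, 0.6)
    gx <- rep(0:(w - 1L), each = h); gy <- rep.int(0:(h - 1L), w)
    u <- cos(th) * (gx - cx) + sin(th) * (gy - cy)
    v <- -sin(th) * (gx - cx) + cos(th) * (gy - cy)
    inside <- (u / ax)^2 + (v / ay)^2 <= 1
    for (k in 1:3) {
      ch <- img[, , k]
      ch[inside] <- pmin(pmax(col[k], 0), 1)
      img[, , k] <- ch
    }
  }
  img
}

#' Generate a multimodal phantom pair with known ground truth
#'
#' Builds a rosette-like plant silhouette (tapered, curved leaves around a
#' stem) and renders it twice: FLU, a bright plant on a dark background with
#' Gaussian noise; VIS, a 3-channel moderate-contrast rendering over a
#' cluttered background (random blobs, a third with plant-like color,
#' optional blue mat) with independent noise. The VIS plant is placed at the
#' spec's ground-truth transform (composed with per-leaf offsets when
#' present); masks are exact analytic silhouettes.
#'
#' @param spec `phantom_spec`.
#' @return list with `flu`, `vis` (images), `flu_mask`, `vis_mask` (binary),
#'   `truth` (`similarity_transform`, prescaled-FLU -> VIS), `per_leaf_truth`
#'   (list of per-leaf transforms; equals `truth` replicated when no offsets),
#'   `leaf_id_vis` (per-pixel leaf provenance on the VIS grid) and `spec`.
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  hv <- spec$vis_canvas[1]; wv <- spec$vis_canvas[2]
  hf <- spec$flu_canvas[1]; wf <- spec$flu_canvas[2]
  with_seed(spec$seed, {
    cx <- (wv - 1) / 2 + runif(1, -0.03, 0.03) * wv
    cy <- (hv - 1) / 2 + runif(1, -0.03, 0.03) * hv
    leaves <- sample_leaf_params(spec, cx, cy)
    tr <- spec$truth
    truth <- similarity_about(tr["s"], tr["alpha"], cx, cy, tr["tx"], tr["ty"])
    per_leaf <- lapply(seq_len(spec$n_leaves), function(l) {
      if (is.null(spec$leaf_offsets)) return(truth)
      off <- spec$leaf_offsets[[l]]
      compose_transforms(truth,
                         similarity_about(1, off[3], cx, cy, off[1], off[2]))
    })
    # FLU grid -> VIS frame: pure height-ratio scaling (center-consistent)
    f_pre <- hv / hf
    to_vis_flu <- make_similarity(f_pre, 0, (f_pre - 1) / 2, (f_pre - 1) / 2)
    flu_r <- render_mask(leaves, spec$n_leaves, hf, wf, to_vis = to_vis_flu)
    vis_r <- render_mask(leaves, spec$n_leaves, hv, wv, per_leaf = per_leaf)
    flu_mask <- flu_r$mask; vis_mask <- vis_r$mask
    # FLU rendering: bright plant, dark background
    tex_f <- smooth_field(hf, wf, sigma = 6)
    flu <- 0.05 + 0.02 * tex_f
    flu[flu_mask == 1] <- 0.78 + 0.12 * tex_f[flu_mask == 1]
    flu <- pmin(pmax(flu + rnorm(hf * wf, 0, spec$flu_noise), 0), 1)
    # VIS rendering: textured color plant over cluttered background
    plant_col <- c(0.25, 0.45, 0.18)
    bg_col <- c(0.33, 0.29, 0.23)
    vis <- array(0, dim = c(hv, wv, 3L))
    tex_v <- smooth_field(hv, wv, sigma = 10)
    for (k in 1:3) vis[, , k] <- bg_col[k] * (1 + 0.25 * tex_v)
    if (isTRUE(spec$use_mat)) {
      mat_col <- c(0.12, 0.18, 0.55)
      for (k in 1:3) { ch <- vis[, , k]; ch[] <- mat_col[k]; vis[, , k] <- ch }
    }
    vis <- draw_clutter(vis, spec$n_clutter, hv, wv, plant_col)
    leaf_jit <- runif(spec$n_leaves + 1L, 0.85, 1.15)
    tex_p <- smooth_field(hv, wv, sigma = 4)
    for (k in 1:3) {
      ch <- vis[, , k]
      on <- vis_mask == 1
      ch[on] <- plant_col[k] * leaf_jit[vis_r$leaf_id[on] + 1L] * (1 + 0.2 * tex_p[on])
      vis[, , k] <- ch
    }
    vis <- pmin(pmax(vis + array(rnorm(hv * wv * 3L, 0, spec$vis_noise),
                                 dim = dim(vis)), 0), 1)
    list(flu = flu, vis = vis, flu_mask = flu_mask, vis_mask = vis_mask,
         truth = truth, per_leaf_truth = per_leaf,
         leaf_id_vis = vis_r$leaf_id, spec = spec)
  })
}

#' Generate a batch of phantom pairs with sampled ground truths
#'
#' @param n number of pairs.
#' @param base_spec template `phantom_spec`; per-pair seeds are
#'   `base_spec$seed + 1000 * i`.
#' @param s_range,alpha_range,t_range uniform sampling ranges for the
#'   ground-truth scale, rotation (radians) and per-axis translation (px).
#' @return list of `n` outputs of [generate_phantom_pair()]; the manifest of
#'   sampled truths is in `attr(, "manifest")`.
#' @export
generate_batch <- function(n, base_spec = phantom_spec(),
                           s_range = c(0.95, 1.05),
                           alpha_range = c(-5, 5) * pi / 180,
                           t_range = c(-10, 10)) {
  stopifnot(n >= 1L)
  manifest <- data.frame(seed = integer(n), s = numeric(n), alpha = numeric(n),
                         tx = numeric(n), ty = numeric(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- base_spec$seed + 1000L * i
    truth_i <- with_seed(seed_i, c(s = runif(1, s_range[1], s_range[2]),
                                   alpha = runif(1, alpha_range[1], alpha_range[2]),
                                   tx = runif(1, t_range[1], t_range[2]),
                                   ty = runif(1, t_range[1], t_range[2])))
    sp <- base_spec
    sp$seed <- seed_i
    sp$truth <- truth_i
    out[[i]] <- generate_phantom_pair(sp)
    manifest[i, ] <- c(seed_i, truth_i)
  }
  attr(out, "manifest") <- manifest
  out
}

#' Phantom pair with nonuniform (per-leaf) motion
#'
#' Each leaf's VIS instance is displaced by its own rigid offset, so no
#' single similarity transform aligns all leaves; the per-leaf ground-truth
#' transforms are recorded for evaluation.
#'
#' @param spec `phantom_spec` with `n_leaves >= 2`.
#' @param offsets list of `(dx, dy, dtheta_rad)` per leaf.
#' @return as [generate_phantom_pair()].
#' @export
split_motion_phantom <- function(spec, offsets) {
  if (spec$n_leaves < 2L) stop("split-motion phantom needs at least 2 leaves", call. = FALSE)
  if (length(offsets) != spec$n_leaves)
    stop("offsets list length must equal n_leaves", call. = FALSE)
  spec$leaf_offsets <- offsets
  generate_phantom_pair(spec)
}
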