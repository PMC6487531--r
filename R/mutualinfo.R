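# Intensity-based registration by maximization of Mattes-style mutual
# information over similarity-transform parameters, with a coarse-to-fine
# pyramid and a seeded (1+1) evolutionary or finite-difference optimizer.

#' Mutual-information engine configuration
#'
#' @param n_bins joint-histogram bins per axis (default 50, minimum 8).
#' @param sample_fraction fraction of fixed-image pixels sampled per metric
#'   evaluation (default 0.3), capped at `max_samples` with a floor of 2000.
#' @param max_samples cap on spatial samples (default 20000).
#' @param pyramid_levels number of resolution levels (default 3; level `k`
#'   is downscaled by `0.5^(pyramid_levels - k)`).
#' @param optimizer `"evolutionary"` ((1+1) strategy with adaptive step,
#'   default - robust for multimodal pairs) or `"gradient"`
#'   (finite-difference ascent with step halving).
#' @param max_iterations optimizer iterations per pyramid level: scalar or
#'   coarse-to-fine vector (default `c(240, 160, 80)`; most of the search
#'   runs at the cheap coarse levels, the fine level only polishes).
#' @param seed RNG seed controlling spatial sampling and mutation draws.
#' @param oob handling of samples mapping outside the moving canvas:
#'   `"fill"` (default) assigns them `oob_fill`, keeping the sample set
#'   constant over transform space - this avoids the classic overlap
#'   artifact where discarding background-heavy bands spuriously raises MI;
#'   `"discard"` drops them (overlap-only estimation).
#' @param oob_fill moving-image fill intensity for `oob = "fill"` (default
#'   0, appropriate for dark-background fluorescence images).
#' @return list of class `mi_config`.
#' @export
mi_config <- function(n_bins = 50L, sample_fraction = 0.4, max_samples = 30000L,
                      pyramid_levels = 3L, optimizer = c("evolutionary", "gradient"),
                      max_iterations = c(240L, 160L, 80L), seed = 1L,
                      oob = c("fill", "discard"), oob_fill = 0) {
  optimizer <- match.arg(optimizer)
  oob <- match.arg(oob)
  stopifnot(n_bins >= 8L, pyramid_levels >= 1L, sample_fraction > 0,
            all(max_iterations >= 1L))
  structure(list(n_bins = as.integer(n_bins), sample_fraction = sample_fraction,
                 max_samples = as.integer(max_samples),
                 pyramid_levels = as.integer(pyramid_levels),
                 optimizer = optimizer, max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), oob = oob, oob_fill = oob_fill),
            class = "mi_config")
}

# cubic B-spline kernel weights for fractional bin position u in [0,1):
# support over bins {-1, 0, 1, 2} relative to floor
bspline3_weights <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# joint Parzen histogram: linear window on the fixed intensities, cubic
# B-spline on the moving intensities (Mattes-style asymmetry)
joint_histogram <- function(fv, mv, n_bins) {
  nb <- as.integer(n_bins)
  # map [0,1] into bin space leaving one bin of cubic support on each side
  fpos <- fv * (nb - 3L) + 1
  mpos <- mv * (nb - 3L) + 1
  f0 <- floor(fpos); fu <- fpos - f0
  m0 <- floor(mpos); mu <- mpos - m0
  fw <- cbind(1 - fu, fu)                 # bins f0, f0+1
  mw <- bspline3_weights(mu)              # bins m0-1 .. m0+2
  hist <- matrix(0, nb, nb)
  for (a in 1:2) {
    fb <- pmin(pmax(f0 + (a - 1L), 0), nb - 1L)
    for (b in 1:4) {
      mb <- pmin(pmax(m0 + (b - 2L), 0), nb - 1L)
      wgt <- fw[, a] * mw[, b]
      idx <- fb + nb * mb + 1L
      acc <- rowsum(wgt, idx)
      hist[as.integer(rownames(acc))] <- hist[as.integer(rownames(acc))] + acc
    }
  }
  hist / sum(hist)
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# deterministic random sample of fixed-grid coordinates; at coarse pyramid
# levels the floor of 2000 effectively covers the whole grid
mi_sample_coords <- function(h, w, cfg, seed_offset = 0L) {
  n <- min(cfg$max_samples, max(2000L, round(cfg$sample_fraction * h * w)))
  with_seed(cfg$seed + seed_offset, {
    cbind(x = runif(n, 0, w - 1), y = runif(n, 0, h - 1))
  })
}

mi_at <- function(fixed, moving, t, cfg, coords = NULL) {
  h <- nrow(fixed); w <- ncol(fixed)
  if (is.null(coords)) coords <- mi_sample_coords(h, w, cfg)
  inv <- invert_transform(t)$matrix
  sx <- inv[1, 1] * coords[, "x"] + inv[1, 2] * coords[, "y"] + inv[1, 3]
  sy <- inv[2, 1] * coords[, "x"] + inv[2, 2] * coords[, "y"] + inv[2, 3]
  hm <- nrow(moving); wm <- ncol(moving)
  ok <- sx >= 0 & sx <= wm - 1 & sy >= 0 & sy <= hm - 1
  if (sum(ok) < 16L) return(0)
  if (cfg$oob == "discard") {
    coords <- coords[ok, , drop = FALSE]
    sx <- sx[ok]; sy <- sy[ok]
    ok <- rep(TRUE, nrow(coords))
  }
  # moving intensities; samples mapping outside the moving canvas take the
  # fill value, which keeps the sample set constant over transform space and
  # avoids the overlap artifact of discarding whole image bands
  mv <- rep(cfg$oob_fill, nrow(coords))
  x0 <- pmin(floor(sx[ok]), wm - 2); y0 <- pmin(floor(sy[ok]), hm - 2)
  fx <- sx[ok] - x0; fy <- sy[ok] - y0
  mv[ok] <- moving[y0 + 1 + x0 * hm] * (1 - fy) * (1 - fx) +
    moving[y0 + 1 + (x0 + 1) * hm] * (1 - fy) * fx +
    moving[y0 + 2 + x0 * hm] * fy * (1 - fx) +
    moving[y0 + 2 + (x0 + 1) * hm] * fy * fx
  # fixed intensities at the (non-integer) sampled positions
  xf0 <- pmin(floor(coords[, "x"]), w - 2); yf0 <- pmin(floor(coords[, "y"]), h - 2)
  ffx <- coords[, "x"] - xf0; ffy <- coords[, "y"] - yf0
  fv <- fixed[yf0 + 1 + xf0 * h] * (1 - ffy) * (1 - ffx) +
    fixed[yf0 + 1 + (xf0 + 1) * h] * (1 - ffy) * ffx +
    fixed[yf0 + 2 + xf0 * h] * ffy * (1 - ffx) +
    fixed[yf0 + 2 + (xf0 + 1) * h] * ffy * ffx
  if (sd(mv) < 1e-12 || sd(fv) < 1e-12) return(0)
  jh <- joint_histogram(pmin(pmax(fv, 0), 1), pmin(pmax(mv, 0), 1), cfg$n_bins)
  hf <- entropy_nats(rowSums(jh))
  hm_ <- entropy_nats(colSums(jh))
  hj <- entropy_nats(jh)
  max(hf + hm_ - hj, 0)
}

#' Mutual information between a fixed image and a transformed moving image
#'
#' `MI = H(fixed) + H(moving o t) - H(joint)`, estimated in nats from a
#' Parzen-windowed joint histogram (linear window on fixed, cubic B-spline
#' on moving intensities) over a seeded random sample of overlap pixels.
#' Returns 0 when the overlap is empty or either marginal is degenerate.
#'
#' @param fixed,moving 1-channel images in `[0, 1]`.
#' @param t `similarity_transform` mapping moving into fixed coordinates
#'   (default identity).
#' @param cfg `mi_config`.
#' @return mutual information in nats (`>= 0`).
#' @export
mutual_information <- function(fixed, moving, t = make_similarity(), cfg = mi_config()) {
  assert_image(fixed, "fixed"); assert_image(moving, "moving")
  if (img_channels(fixed) != 1L || img_channels(moving) != 1L)
    stop("mutual_information requires 1-channel images", call. = FALSE)
  stopifnot(inherits(t, "similarity_transform"))
  mi_at(fixed, moving, t, cfg)
}

# (1+1) evolutionary strategy on (log s, alpha, tx, ty) with roughly
# 1/5-success-rule step adaptation, followed by a fine-step restart from the
# incumbent; returns the accepted parameter vector and its MI trace
es_one_plus_one <- function(objective, theta, step, max_iter, seed) {
  best <- objective(theta)
  trace <- numeric(0)
  with_seed(seed, {
    for (phase in 1:2) {
      st <- if (phase == 1L) step else step / 4
      n_it <- if (phase == 1L) max_iter else ceiling(max_iter / 2)
      for (i in seq_len(n_it)) {
        cand <- theta + rnorm(4L) * st
        v <- objective(cand)
        if (v > best) {
          theta <- cand; best <- v
          st <- st * 1.6
        } else {
          st <- st * 0.96
        }
        trace[length(trace) + 1L] <- best
      }
    }
  })
  list(theta = theta, value = best, trace = trace)
}

gradient_ascent <- function(objective, theta, step, max_iter) {
  eps <- c(0.002, 0.002, 0.25, 0.25)
  best <- objective(theta)
  trace <- numeric(0)
  for (i in seq_len(max_iter)) {
    g <- vapply(1:4, function(j) {
      e <- numeric(4L); e[j] <- eps[j]
      (objective(theta + e) - objective(theta - e)) / (2 * eps[j])
    }, 0)
    gn <- sqrt(sum((g * step)^2))
    if (gn < 1e-12) break
    improved <- FALSE
    sl <- 1
    for (k in 1:6) {
      cand <- theta + sl * step * g / max(abs(g * step)) * max(abs(step))
      v <- objective(cand)
      if (v > best) { theta <- cand; best <- v; improved <- TRUE; break }
      sl <- sl / 2
    }
    trace[i] <- best
    if (!improved) { step <- step / 2; if (max(abs(step)) < 1e-4) break }
  }
  list(theta = theta, value = best, trace = trace)
}

#' Mutual-information registration engine
#'
#' Coarse-to-fine maximization of [mutual_information()] over the similarity
#' parameters `(log s, alpha, tx, ty)`. Following the observation that a
#' formally admissible intensity-based registration is no guarantee of
#' alignment quality, the success flag reflects transform admissibility
#' only; the final MI value is reported as `quality`.
#'
#' @param moving,fixed preprocessed 1-channel images.
#' @param cfg `mi_config`.
#' @param gate `gate_config`.
#' @param init optional `similarity_transform` initialization (e.g., another
#'   engine's estimate); default identity.
#' @return `registration_result` with `method = "INT"`, `quality` = final MI
#'   (nats) and the per-level MI traces in `extra$trace`.
#' @export
register_mi <- function(moving, fixed, cfg = mi_config(), gate = gate_config(),
                        init = make_similarity()) {
  assert_image(moving, "moving"); assert_image(fixed, "fixed")
  if (img_channels(moving) != 1L || img_channels(fixed) != 1L)
    stop("register_mi requires 1-channel (preprocessed) images", call. = FALSE)
  if (sd(moving) < 1e-12 || sd(fixed) < 1e-12)
    return(failed_result("INT", "degenerate (constant) input"))
  theta <- c(log(init$s), init$alpha, init$tx, init$ty)
  # divergence sanity box: twice the admissibility ranges
  box_lo <- c(log(gate$scale_interval[1]) * 2, -2 * asin(min(1, gate$rotation_bound)),
              -2 * gate$max_translation, -2 * gate$max_translation)
  box_hi <- c(log(gate$scale_interval[2]) * 2, 2 * asin(min(1, gate$rotation_bound)),
              2 * gate$max_translation, 2 * gate$max_translation)
  traces <- list()
  # candidate set: the coarsest level explores with restarts and several
  # hypotheses survive to the mid levels, where the less noisy metric
  # arbitrates between basins; a single candidate is polished at the end
  candidates <- list(theta)
  for (lvl in seq_len(cfg$pyramid_levels)) {
    f <- 0.5^(cfg$pyramid_levels - lvl)
    mov_l <- if (f < 1) downscale(moving, f) else moving
    fix_l <- if (f < 1) downscale(fixed, f) else fixed
    if (nrow(fix_l) < 16L || ncol(fix_l) < 16L || nrow(mov_l) < 16L || ncol(mov_l) < 16L) next
    coords <- mi_sample_coords(nrow(fix_l), ncol(fix_l), cfg, seed_offset = lvl)
    objective <- function(th) {
      t <- make_similarity(exp(th[1]), th[2], th[3], th[4])
      mi_at(fix_l, mov_l, t, cfg, coords)
    }
    # broad basin search at the coarsest level; small polish steps above
    step <- if (lvl == 1L) c(0.03, 0.03, 2.5, 2.5) else c(0.008, 0.008, 0.75, 0.75)
    n_iter <- cfg$max_iterations[min(lvl, length(cfg$max_iterations))]
    last <- lvl == cfg$pyramid_levels
    opts <- list()
    for (ci in seq_along(candidates)) {
      th0 <- candidates[[ci]]
      theta_l <- c(th0[1], th0[2], th0[3] * f, th0[4] * f)
      if (cfg$optimizer == "evolutionary") {
        n_starts <- if (lvl == 1L) 3L else 1L
        for (k in seq_len(n_starts)) {
          opts[[length(opts) + 1L]] <-
            es_one_plus_one(objective, theta_l, step, n_iter,
                            cfg$seed + lvl + 97L * k + 991L * ci)
        }
      } else {
        opts[[length(opts) + 1L]] <- gradient_ascent(objective, theta_l, step, n_iter)
      }
    }
    vals <- vapply(opts, function(o) o$value, 0)
    keep <- if (last || cfg$optimizer == "gradient") which.max(vals)
            else order(-vals)[seq_len(min(2L, length(opts)))]
    candidates <- lapply(opts[keep], function(o)
      c(o$theta[1], o$theta[2], o$theta[3] / f, o$theta[4] / f))
    traces[[lvl]] <- opts[[keep[1L]]]$trace
    inbox <- vapply(candidates, function(th) all(th >= box_lo & th <= box_hi), TRUE)
    if (!any(inbox))
      return(failed_result("INT", "diverged", extra = list(theta = candidates[[1L]])))
    candidates <- candidates[inbox]
  }
  theta <- candidates[[1L]]
  t_final <- make_similarity(exp(theta[1]), theta[2], theta[3], theta[4])
  mi_final <- mi_at(fixed, moving, t_final, cfg,
                    mi_sample_coords(nrow(fixed), ncol(fixed), cfg, seed_offset = 0L))
  adm <- is_admissible(t_final, gate)
  registration_result(t_final, "INT", success = adm$flag, quality = mi_final,
                      reasons = adm$reasons,
                      extra = list(trace = traces, optimizer = cfg$optimizer,
                                   seed = cfg$seed))
}
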