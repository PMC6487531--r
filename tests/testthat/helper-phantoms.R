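# Shared fixtures, all generated in code.

# structured grayscale test image: Gaussian blobs + noise floor
blob_image <- function(n = 128, n_blobs = 10, seed = 1, noise = 0.01) {
  plantalign:::with_seed(seed, {
    X <- matrix(rep(0:(n - 1), each = n), n, n)
    Y <- matrix(rep(0:(n - 1), n), n, n)
    img <- matrix(0, n, n)
    for (i in seq_len(n_blobs)) {
      cx <- runif(1, 0.15 * n, 0.85 * n); cy <- runif(1, 0.15 * n, 0.85 * n)
      sg <- runif(1, 0.015 * n, 0.05 * n)
      img <- img + runif(1, 0.4, 1) * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    }
    img <- img / max(img) + noise * matrix(rnorm(n * n), n, n)
    pmin(pmax(img, 0), 1)
  })
}

# cyclic shift by integer (dy, dx)
cyclic_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((0:(h - 1) - dy) %% h) + 1, ((0:(w - 1) - dx) %% w) + 1]
}

# small phantom spec for fast tests
small_spec <- function(seed = 1, ...) {
  phantom_spec(seed = seed, vis_canvas = c(192L, 160L), flu_canvas = c(127L, 96L), ...)
}

# moving/fixed grayscale pair + prescaled mask from a phantom
phantom_pair_gs <- function(ph) {
  pre <- prescale_flu_to_vis(ph$flu, ph$vis)
  list(moving = pre$image, fixed = to_grayscale(ph$vis),
       moving_mask = (prescale_flu_to_vis(ph$flu_mask, ph$vis)$image >= 0.5) * 1,
       factor = pre$factor)
}

expect_transform_close <- function(t, truth, tol_t = 2, tol_deg = 1, tol_s = 0.02) {
  d <- decompose_similarity(t); td <- decompose_similarity(truth)
  expect_lt(abs(d$s - td$s) / td$s, tol_s)
  expect_lt(abs(d$alpha - td$alpha) * 180 / pi, tol_deg)
  expect_lt(sqrt((d$tx - td$tx)^2 + (d$ty - td$ty)^2), tol_t)
}
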