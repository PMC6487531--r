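# Feature detection, matching and robust similarity estimation.

test_that("all detectors return empty on a constant image", {
  flat <- matrix(0.5, 64, 64)
  for (d in FEATURE_DETECTORS) {
    expect_equal(nrow(detect_features(flat, d)), 0L, info = d)
  }
  expect_error(detect_features(flat, "no_such_detector"), "unknown")
})

test_that("harris finds the corners of a bright square", {
  img <- matrix(0, 64, 64)
  img[30:34, 30:34] <- 1
  pts <- detect_features(img, "harris")
  expect_gte(nrow(pts), 4L)
  # the four strongest detections sit near the square corners
  corners <- rbind(c(29, 29), c(29, 33), c(33, 29), c(33, 33))
  top4 <- pts[1:4, ]
  for (i in 1:4) {
    dd <- sqrt((corners[, 1] - top4$x[i])^2 + (corners[, 2] - top4$y[i])^2)
    expect_lt(min(dd), 2.5)
  }
})

test_that("blob_dog localizes an isolated Gaussian blob and its scale", {
  n <- 96
  X <- matrix(rep(0:(n - 1), each = n), n, n); Y <- matrix(rep(0:(n - 1), n), n, n)
  sigma_blob <- 5
  img <- exp(-((X - 47)^2 + (Y - 51)^2) / (2 * sigma_blob^2))
  pts <- detect_features(img, "blob_dog")
  expect_gte(nrow(pts), 1L)
  expect_lt(sqrt((pts$x[1] - 47)^2 + (pts$y[1] - 51)^2), 2)
  expect_lt(abs(pts$scale[1] - sigma_blob) / sigma_blob, 0.25)
})

test_that("detectors are equivariant to integer translation", {
  img <- blob_image(96, 8, seed = 21, noise = 0)
  shifted <- matrix(0, 96, 96)
  shifted[11:96, 6:96] <- img[1:86, 1:91] # shift by (dx=5, dy=10)
  for (d in c("harris", "shi_tomasi", "fast", "blob_dog", "blob_doh")) {
    p1 <- head(detect_features(img, d), 15)
    p2 <- detect_features(shifted, d)
    if (nrow(p1) == 0L) next
    matched <- 0
    for (i in seq_len(nrow(p1))) {
      dd <- sqrt((p2$x - (p1$x[i] + 5))^2 + (p2$y - (p1$y[i] + 10))^2)
      if (length(dd) && min(dd) <= 1.5) matched <- matched + 1
    }
    # most points away from the border move with the image
    inner <- p1$x > 12 & p1$x < 80 & p1$y > 12 & p1$y < 76
    expect_gte(matched, 0.7 * sum(inner))
  }
})

test_that("multifeature_detect merges nearby detections and keeps provenance", {
  img <- blob_image(96, 8, seed = 22, noise = 0)
  single <- detect_features(img, "harris")
  multi1 <- multifeature_detect(img, "harris")
  expect_equal(nrow(multi1), min(nrow(single), 300L))
  expect_setequal(multi1$x, head(single, 300)$x)
  # harris and shi_tomasi fire on the same corners: merged points are fewer
  # than the concatenation, and no two survivors are closer than the radius
  both <- multifeature_detect(img, c("harris", "shi_tomasi"))
  expect_lt(nrow(both), nrow(detect_features(img, "harris")) +
                        nrow(detect_features(img, "shi_tomasi")))
  if (nrow(both) > 1) {
    dmat <- as.matrix(dist(both[, c("x", "y")]))
    diag(dmat) <- Inf
    expect_gte(min(dmat), 2)
  }
  expect_true(all(both$detector %in% c("harris", "shi_tomasi")))
  expect_error(multifeature_detect(img, character(0)), "detector")
})

test_that("describe_and_match matches identical and translated images", {
  img <- blob_image(96, 10, seed = 23, noise = 0)
  pts <- head(detect_features(img, "harris"), 40)
  m_self <- describe_and_match(pts, pts, img, img)
  expect_equal(nrow(m_self), nrow(pts))
  expect_true(all(m_self$moving == m_self$fixed))
  expect_true(all(m_self$distance < 1e-5))
  # translated copy: matched displacement = (7, 0) within 1 px
  fixed <- matrix(0, 96, 96)
  fixed[, 8:96] <- img[, 1:89]
  fpts <- detect_features(fixed, "harris")
  m <- describe_and_match(pts, fpts, img, fixed)
  expect_gte(nrow(m), 5)
  dx <- fpts$x[m$fixed] - pts$x[m$moving]
  dy <- fpts$y[m$fixed] - pts$y[m$moving]
  expect_true(mean(abs(dx - 7) <= 1 & abs(dy) <= 1) >= 0.8)
})

test_that("matching against unrelated noise is mostly rejected", {
  survived <- numeric(20)
  for (s in 1:20) {
    img <- blob_image(64, 6, seed = 300 + s, noise = 0.01)
    noise <- plantalign:::with_seed(400 + s, matrix(runif(64 * 64), 64, 64))
    pts <- head(detect_features(img, "harris"), 30)
    npts <- detect_features(noise, "harris")
    if (nrow(pts) == 0L || nrow(npts) == 0L) next
    m <- describe_and_match(pts, npts, img, noise)
    survived[s] <- nrow(m) / nrow(pts)
  }
  expect_lt(mean(survived), 0.10)
})

test_that("two exact correspondences recover a similarity in closed form", {
  truth <- make_similarity(1.23, 0.31, 14, -6)
  p <- cbind(x = c(10, 50), y = c(20, 35))
  q <- t(truth$matrix %*% rbind(t(p), 1))[, 1:2]
  matches <- data.frame(moving = 1:2, fixed = 1:2, distance = 0)
  est <- estimate_similarity_robust(matches, as.data.frame(p), data.frame(x = q[, 1], y = q[, 2]))
  expect_true(est$ok)
  expect_equal(est$transform$matrix, truth$matrix, tolerance = 1e-9)
  # coincident points are degenerate
  bad <- estimate_similarity_robust(matches, data.frame(x = c(5, 5), y = c(5, 5)),
                                    data.frame(x = c(1, 2), y = c(3, 4)))
  expect_false(bad$ok)
  expect_false(estimate_similarity_robust(matches[0, ], as.data.frame(p),
                                          as.data.frame(p))$ok)
})

test_that("consensus estimation resists 30% gross outliers across 20 seeds", {
  for (s in 1:20) {
    truth <- plantalign:::with_seed(s, make_similarity(runif(1, 0.9, 1.1),
                                                       runif(1, -0.2, 0.2),
                                                       runif(1, -30, 30),
                                                       runif(1, -30, 30)))
    n_in <- 20; n_out <- 9 # 31% outliers
    pts <- plantalign:::with_seed(1000 + s,
      cbind(x = runif(n_in + n_out, 0, 200), y = runif(n_in + n_out, 0, 200)))
    q <- t(truth$matrix %*% rbind(t(pts), 1))[, 1:2]
    q[(n_in + 1):(n_in + n_out), ] <- plantalign:::with_seed(2000 + s,
      cbind(runif(n_out, 0, 200), runif(n_out, 0, 200)))
    matches <- data.frame(moving = seq_len(n_in + n_out),
                          fixed = seq_len(n_in + n_out), distance = 0)
    est <- estimate_similarity_robust(matches, as.data.frame(pts),
                                      data.frame(x = q[, 1], y = q[, 2]), seed = s)
    expect_true(est$ok)
    d <- decompose_similarity(est$transform); td <- decompose_similarity(truth)
    expect_lt(sqrt((d$tx - td$tx)^2 + (d$ty - td$ty)^2), 0.5)
    expect_lt(abs(d$alpha - td$alpha) * 180 / pi, 0.5)
    expect_lt(abs(d$s - td$s) / td$s, 0.01)
  }
})

test_that("zero-outlier consensus equals the least-squares fit", {
  truth <- make_similarity(1.05, 0.12, 8, -3)
  pts <- plantalign:::with_seed(5, cbind(x = runif(15, 0, 100), y = runif(15, 0, 100)))
  q <- t(truth$matrix %*% rbind(t(pts), 1))[, 1:2]
  matches <- data.frame(moving = 1:15, fixed = 1:15, distance = 0)
  est <- estimate_similarity_robust(matches, as.data.frame(pts),
                                    data.frame(x = q[, 1], y = q[, 2]), seed = 2)
  ls <- plantalign:::fit_similarity_ls(pts[, 1], pts[, 2], q[, 1], q[, 2])
  expect_equal(est$transform$matrix, ls$matrix, tolerance = 1e-6)
})

test_that("register_fp recovers a small rotation and fails gracefully", {
  img <- to_grayscale(generate_phantom_pair(small_spec(seed = 31))$vis)
  r_self <- register_fp(img, img, seed = 3)
  expect_true(r_self$success)
  expect_transform_close(r_self$transform, make_similarity(), tol_t = 1, tol_deg = 0.5, tol_s = 0.01)
  truth <- similarity_about(1, 5 * pi / 180, (ncol(img) - 1) / 2, (nrow(img) - 1) / 2)
  mov <- warp_image(img, invert_transform(truth), nrow(img), ncol(img))
  r <- register_fp(mov, img, seed = 3)
  expect_true(r$success)
  d <- decompose_similarity(r$transform)
  expect_lt(abs(d$alpha - 5 * pi / 180) * 180 / pi, 1)
  # featureless input: failed result, not an error
  rf <- register_fp(matrix(0.5, 64, 64), img)
  expect_false(rf$success)
  expect_match(rf$reasons, "features|matches")
})
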