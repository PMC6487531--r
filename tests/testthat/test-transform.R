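# Similarity-transform algebra, warping and admissibility gating.

test_that("make_similarity builds the closed-form matrix", {
  expect_equal(make_similarity(1, 0, 0, 0)$matrix, diag(3))
  t2 <- make_similarity(2, pi / 2, 0, 0)
  expect_equal(t2$matrix[1:2, 1:2], matrix(c(0, 2, -2, 0), 2, 2), tolerance = 1e-12)
  t3 <- make_similarity(1, 0, 5, -3)
  expect_equal(t3$matrix[1:2, 1:2], diag(2))
  expect_equal(c(t3$matrix[1, 3], t3$matrix[2, 3]), c(5, -3))
  expect_error(make_similarity(-1, 0, 0, 0), "positive")
  expect_error(make_similarity(0, 0, 0, 0), "positive")
})

test_that("decompose and make_similarity are mutually inverse", {
  d <- decompose_similarity(make_similarity(1.1, 0.2, 10, 20))
  expect_equal(unlist(d), c(s = 1.1, alpha = 0.2, tx = 10, ty = 20), tolerance = 1e-9)
  m <- matrix(c(0, 2, 0, -2, 0, 0, 0, 0, 1), 3, 3)
  d2 <- decompose_similarity(similarity_from_matrix(m))
  expect_equal(d2$s, 2, tolerance = 1e-12)
  expect_equal(d2$alpha, pi / 2, tolerance = 1e-12)
  # property: round trip over random parameters
  plantalign:::with_seed(7, {
    for (i in 1:25) {
      p <- c(runif(1, 0.2, 3), runif(1, -pi, pi), runif(1, -100, 100), runif(1, -100, 100))
      t <- make_similarity(p[1], p[2], p[3], p[4])
      d <- decompose_similarity(similarity_from_matrix(t$matrix))
      expect_equal(unlist(d), c(s = p[1], alpha = p[2], tx = p[3], ty = p[4]),
                   tolerance = 1e-9)
    }
  })
})

test_that("similarity_from_matrix rejects non-similarity matrices", {
  shear <- diag(3); shear[1, 2] <- 0.1
  expect_error(similarity_from_matrix(shear), "scaled rotation")
  refl <- diag(3); refl[1, 1] <- -1
  expect_error(similarity_from_matrix(refl), "positive")
  proj <- diag(3); proj[3, 1] <- 0.01
  expect_error(similarity_from_matrix(proj), "last row")
})

test_that("compose_transforms multiplies scales, adds angles, and is associative", {
  id <- make_similarity()
  t <- make_similarity(1.3, 0.4, 7, -2)
  expect_equal(compose_transforms(t, id)$matrix, t$matrix, tolerance = 1e-12)
  expect_equal(compose_transforms(id, t)$matrix, t$matrix, tolerance = 1e-12)
  two <- compose_transforms(make_similarity(2, 0, 0, 0), make_similarity(0.5, 0, 0, 0))
  expect_equal(two$matrix, diag(3), tolerance = 1e-12)
  r60 <- compose_transforms(make_similarity(1, pi / 6, 0, 0), make_similarity(1, pi / 6, 0, 0))
  expect_equal(decompose_similarity(r60)$alpha, pi / 3, tolerance = 1e-12)
  a <- make_similarity(0.9, 0.1, 3, 4); b <- make_similarity(1.2, -0.3, -5, 1)
  cc <- make_similarity(1.05, 0.2, 0, -9)
  expect_equal(compose_transforms(compose_transforms(a, b), cc)$matrix,
               compose_transforms(a, compose_transforms(b, cc))$matrix,
               tolerance = 1e-9)
  # inverse composes to identity
  expect_equal(compose_transforms(t, invert_transform(t))$matrix, diag(3),
               tolerance = 1e-9)
})

test_that("warp_image obeys the moving-to-fixed convention", {
  img <- matrix(0, 32, 32); img[17, 11] <- 1 # delta at x=10, y=16
  # identity is pixel-exact
  expect_equal(warp_image(img, make_similarity()), img)
  # integer translation moves the delta by (+5, 0)
  w <- warp_image(img, make_similarity(1, 0, 5, 0))
  expect_equal(w[17, 16], 1)
  expect_equal(sum(w), 1)
  # large translation pushes content off-canvas; fill is 0
  ones <- matrix(1, 16, 16)
  w2 <- warp_image(ones, make_similarity(1, 0, 100, 0), 16, 16)
  expect_true(all(w2 == 0))
  # inverse warp restores a smooth phantom away from borders
  ph <- blob_image(96, 8, seed = 3, noise = 0)
  t <- make_similarity(1.05, 0.1, 4, -6)
  back <- warp_image(warp_image(ph, t, 96, 96), invert_transform(t), 96, 96)
  inner <- 20:76
  expect_lt(mean(abs(back[inner, inner] - ph[inner, inner])), 0.02)
})

test_that("warp_mask stays strictly binary", {
  m <- matrix(0, 24, 24); m[8:16, 8:16] <- 1
  w <- warp_mask(m, make_similarity(1.1, 0.2, 1.5, -0.7))
  expect_true(all(w %in% c(0, 1)))
})

test_that("rescale_transform conjugates translations by the scale factors", {
  id <- make_similarity()
  expect_equal(rescale_transform(id, 0.5, 0.5)$matrix, diag(3), tolerance = 1e-12)
  t <- rescale_transform(make_similarity(1, 0, 10, 0), 0.5, 0.5)
  expect_equal(c(t$tx, t$ty), c(20, 0), tolerance = 1e-12)
  expect_equal(t$s, 1, tolerance = 1e-12)
  rot <- rescale_transform(make_similarity(1, 0.3, 0, 0), 0.25, 0.25)
  expect_equal(decompose_similarity(rot)$alpha, 0.3, tolerance = 1e-12)
  expect_error(rescale_transform(id, -1, 1), "positive")
})

test_that("is_admissible reproduces the printed gate thresholds exactly", {
  g <- gate_config()
  expect_true(is_admissible(make_similarity(), g)$flag)
  # translation gate strict at 300 px
  expect_true(is_admissible(make_similarity(1, 0, 299.9, 0), g)$flag)
  r <- is_admissible(make_similarity(1, 0, 300, 0), g)
  expect_false(r$flag); expect_equal(r$reasons, "translation")
  # euclidean norm, not per-component
  expect_false(is_admissible(make_similarity(1, 0, 250, 250), g)$flag)
  # scale interval inclusive at both ends
  expect_true(is_admissible(make_similarity(0.75, 0, 0, 0), g)$flag)
  expect_true(is_admissible(make_similarity(1.25, 0, 0, 0), g)$flag)
  expect_equal(is_admissible(make_similarity(0.749, 0, 0, 0), g)$reasons, "scale")
  expect_equal(is_admissible(make_similarity(1.251, 0, 0, 0), g)$reasons, "scale")
  expect_equal(is_admissible(make_similarity(0.5, 0, 0, 0), g)$reasons, "scale")
  # rotation gate: |sin(alpha)| < 0.15 admits ~8.6 deg, rejects 30 deg
  expect_true(is_admissible(make_similarity(1, 8 * pi / 180, 0, 0), g)$flag)
  r30 <- is_admissible(make_similarity(1, 30 * pi / 180, 0, 0), g)
  expect_false(r30$flag); expect_equal(r30$reasons, "rotation")
  # literal printed rule available behind the config switch
  gc <- gate_config(rotation_gate = "cos")
  expect_false(is_admissible(make_similarity(), gc)$flag)
  expect_true("rotation" %in% is_admissible(make_similarity(), gc)$reasons)
  # multiple violations are all reported
  bad <- is_admissible(make_similarity(0.5, pi / 4, 400, 0), g)
  expect_setequal(bad$reasons, c("translation", "rotation", "scale"))
})

test_that("gate monotonicity: tightening never converts inadmissible to admissible", {
  plantalign:::with_seed(11, {
    for (i in 1:30) {
      t <- make_similarity(runif(1, 0.5, 1.5), runif(1, -0.4, 0.4),
                           runif(1, -400, 400), runif(1, -400, 400))
      loose <- gate_config()
      tight <- gate_config(max_translation = 150, rotation_bound = 0.08,
                           scale_interval = c(0.9, 1.1))
      if (!is_admissible(t, loose)$flag) expect_false(is_admissible(t, tight)$flag)
    }
  })
})

test_that("transforms serialize through JSON round-trip", {
  t <- make_similarity(1.07, -0.12, 33.5, -8.25)
  j <- jsonlite::toJSON(transform_to_list(t), auto_unbox = TRUE, digits = NA)
  back <- transform_from_list(jsonlite::fromJSON(j))
  expect_equal(back$matrix, t$matrix, tolerance = 1e-12)
})
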