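# Scale-sweep combiner, best-entry selection and integrated-mask fusion.

test_that("the default scale grid is the inclusive 0.30..1.00 sequence", {
  sc <- default_sweep_scales()
  expect_equal(sc[1], 0.3)
  expect_equal(sc[length(sc)], 1.0)
  expect_equal(length(sc), 36L)
  expect_equal(diff(sc), rep(0.02, 35), tolerance = 1e-9)
  cfg <- sweep_config()
  expect_equal(cfg$scales, sc)
})

test_that("a degenerate grid reduces to the direct engine call", {
  ph <- generate_phantom_pair(small_spec(seed = 81))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = 1.0, methods = "PC", representations = "GS", seed = 5)
  sr <- run_sweep(p$moving, p$fixed, cfg)
  expect_length(sr$entries, 1L)
  direct <- register_pc(p$moving, p$fixed)
  e <- sr$entries[[1]]$result
  expect_equal(e$success, direct$success)
  if (!is.null(e$transform) && !is.null(direct$transform)) {
    expect_equal(e$transform$matrix, direct$transform$matrix, tolerance = 1e-9)
  }
})

test_that("entry count equals the grid cardinality and failures never abort", {
  ph <- generate_phantom_pair(small_spec(seed = 82))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = c(0.5, 1.0), methods = c("FP", "PC"),
                      representations = c("GS", "CE"), seed = 2)
  sr <- run_sweep(p$moving, p$fixed, cfg, flu_mask = p$moving_mask,
                  vis_mask = ph$vis_mask)
  expect_length(sr$entries, 2L * 2L * 2L)
  tb <- sweep_table(sr)
  expect_equal(nrow(tb), 8L)
  expect_setequal(unique(tb$method), c("FP", "PC"))
  # entries are expressed at full resolution: successful scale-0.5 entries
  # carry translations on the full grid (same order of magnitude as scale 1)
  expect_true(all(is.finite(tb$or[tb$success]) | is.na(tb$or)))
})

test_that("transforms estimated at reduced scale agree with full resolution", {
  ph <- generate_phantom_pair(small_spec(seed = 83, flu_noise = 0, vis_noise = 0,
                                         truth = c(s = 1, alpha = 0.03, tx = 8, ty = -5)))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = c(0.5, 1.0), methods = "PC",
                      representations = "CE", seed = 3)
  sr <- run_sweep(p$moving, p$fixed, cfg)
  tb <- sweep_table(sr)
  expect_true(all(tb$success))
  t_half <- sr$entries[[1]]$result$transform
  t_full <- sr$entries[[2]]$result$transform
  # compare by warping the moving mask: boundary displacement within 2 px
  m_half <- warp_mask(p$moving_mask, t_half, nrow(ph$vis_mask), ncol(ph$vis_mask))
  m_full <- warp_mask(p$moving_mask, t_full, nrow(ph$vis_mask), ncol(ph$vis_mask))
  sym_diff <- sum(abs(m_half - m_full))
  boundary <- sum(abs(diff(m_full)) > 0) + sum(abs(t(diff(t(m_full)))) > 0)
  expect_lt(sym_diff, 2 * boundary)
})

test_that("select_best honors the oracle and quality criteria", {
  ph <- generate_phantom_pair(small_spec(seed = 84))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = c(0.6, 1.0), methods = c("FP", "PC"),
                      representations = "CE", seed = 4)
  sr <- run_sweep(p$moving, p$fixed, cfg, flu_mask = p$moving_mask,
                  vis_mask = ph$vis_mask)
  adm <- Filter(function(e) e$result$success, sr$entries)
  expect_gt(length(adm), 0)
  best <- select_best(sr, "oracle_or")
  ors <- vapply(adm, function(e) e$or, 0)
  expect_equal(best$or, max(ors))
  bq <- select_best(sr, "quality")
  expect_true(bq$result$success)
  # all entries inadmissible -> selection failure
  none <- sr
  none$entries <- lapply(none$entries, function(e) {
    e$result$success <- FALSE; e
  })
  expect_error(select_best(none, "oracle_or"), "admissible")
})

test_that("integrated mask is the union of contributors and dominates each", {
  ph <- generate_phantom_pair(small_spec(seed = 85))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = c(0.6, 1.0), methods = c("FP", "PC"),
                      representations = "CE", seed = 6)
  sr <- run_sweep(p$moving, p$fixed, cfg, flu_mask = p$moving_mask,
                  vis_mask = ph$vis_mask)
  adm <- Filter(function(e) e$result$success, sr$entries)
  expect_gt(length(adm), 0)
  im <- build_integrated_mask(sr, p$moving_mask, nrow(ph$vis_mask), ncol(ph$vis_mask))
  # brute-force union oracle
  u <- matrix(0, nrow(ph$vis_mask), ncol(ph$vis_mask))
  for (e in adm) {
    u <- pmax(u, warp_mask(p$moving_mask, e$result$transform,
                           nrow(ph$vis_mask), ncol(ph$vis_mask)))
  }
  expect_identical(im$mask, u)
  expect_true(all(im$provenance >= im$mask))
  expect_equal(nrow(im$contributors), length(adm))
  # OR dominance is exact by union monotonicity
  or_im <- sum(im$mask == 1 & ph$vis_mask == 1) / sum(ph$vis_mask == 1)
  for (e in adm) expect_gte(or_im + 1e-12, e$or)
  # single contributor: IM equals that entry's warped mask
  one <- sr
  one$entries <- adm[1]
  im1 <- build_integrated_mask(one, p$moving_mask, nrow(ph$vis_mask), ncol(ph$vis_mask))
  expect_identical(im1$mask, warp_mask(p$moving_mask, adm[[1]]$result$transform,
                                       nrow(ph$vis_mask), ncol(ph$vis_mask)))
})

test_that("sweeps are deterministic under identical configs and seeds", {
  ph <- generate_phantom_pair(small_spec(seed = 86))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = c(0.7, 1.0), methods = c("FP", "PC"),
                      representations = "GS", seed = 11)
  t1 <- sweep_table(run_sweep(p$moving, p$fixed, cfg))
  t2 <- sweep_table(run_sweep(p$moving, p$fixed, cfg))
  expect_identical(t1, t2)
})

test_that("summarize_sweep aggregates SR per method and representation", {
  ph <- generate_phantom_pair(small_spec(seed = 87))
  p <- phantom_pair_gs(ph)
  cfg <- sweep_config(scales = c(0.6, 1.0), methods = c("FP", "PC"),
                      representations = c("GS", "CE"), seed = 12)
  sr <- run_sweep(p$moving, p$fixed, cfg, flu_mask = p$moving_mask,
                  vis_mask = ph$vis_mask)
  sm <- summarize_sweep(sr)
  expect_equal(nrow(sm$sr_table), 4L) # |methods| x |representations|
  expect_true(all(sm$sr_table$SR >= 0 & sm$sr_table$SR <= 1))
  expect_length(sm$best_or, 1L)
  if (nrow(sm$components) > 0) {
    expect_true(all(c("s", "alpha_deg", "tx", "ty") %in% names(sm$components)))
  }
})
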