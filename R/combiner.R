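# Scale-sweep combiner: run registration across scales x methods x image
# representations, select the best entry, and fuse multiple admissible
# registrations into an integrated mask approximating nonuniform motion.

#' Default sweep scale grid
#'
#' Equidistant downscaling factors over `[0.3, 1.0]` with step 0.02 (36
#' values inclusive).
#' @return numeric vector of scale factors.
#' @export
default_sweep_scales <- function() round(seq(0.3, 1.0, by = 0.02), 10)

#' Sweep configuration
#'
#' @param scales ascending downscale factors in `(0, 1]`
#'   (default [default_sweep_scales()]).
#' @param methods subset of `c("FP", "PC", "INT")`.
#' @param representations subset of `c("GS", "CE")`.
#' @param gate `gate_config` applied to full-resolution transforms.
#' @param fp,pc,mi named lists of extra arguments for [register_fp()],
#'   [pc_config()] and [mi_config()].
#' @param seed base seed; cell `i` uses `seed + i`.
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(scales = default_sweep_scales(),
                         methods = c("FP", "PC", "INT"),
                         representations = c("GS", "CE"),
                         gate = gate_config(),
                         fp = list(), pc = list(), mi = list(), seed = 1L) {
  stopifnot(length(scales) >= 1L, !is.unsorted(scales),
            all(scales > 0), all(scales <= 1),
            length(methods) >= 1L, length(representations) >= 1L)
  methods <- match.arg(methods, c("FP", "PC", "INT"), several.ok = TRUE)
  representations <- match.arg(representations, c("GS", "CE"), several.ok = TRUE)
  structure(list(scales = scales, methods = methods,
                 representations = representations, gate = gate,
                 fp = fp, pc = pc, mi = mi, seed = as.integer(seed)),
            class = "sweep_config")
}

run_engine_cell <- function(method, mov, fix, gate, cfg, cell_seed) {
  switch(method,
         PC = do.call(register_pc,
                      c(list(moving = mov, fixed = fix, gate = gate,
                             config = do.call(pc_config, cfg$pc)))),
         FP = do.call(register_fp,
                      c(list(moving = mov, fixed = fix, gate = gate,
                             seed = cell_seed), cfg$fp)),
         INT = {
           mi_args <- cfg$mi
           mi_args$seed <- cell_seed
           register_mi(mov, fix, cfg = do.call(mi_config, mi_args), gate = gate)
         })
}

#' Run a registration sweep over scales, methods and representations
#'
#' For every `(scale, method, representation)` cell: both images are
#' downscaled by the same factor, the representation is built, the engine is
#' run, and the estimated transform is conjugated back to full (prescaled)
#' resolution with [rescale_transform()] before gating. Individual cell
#' failures are recorded as failed entries and never abort the sweep.
#'
#' @param flu prescaled FLU image (moving; 1- or 3-channel).
#' @param vis VIS image (fixed; 1- or 3-channel).
#' @param cfg `sweep_config`.
#' @param flu_mask,vis_mask optional ground-truth masks on the same grids;
#'   when both are given, each successful entry is scored with
#'   [overlap_ratio()].
#' @return object of class `sweep_result`: list with `entries` (one per grid
#'   cell: `scale`, `method`, `representation`, `result`, `or` or `NA`) and
#'   `cfg`.
#' @export
run_sweep <- function(flu, vis, cfg = sweep_config(), flu_mask = NULL, vis_mask = NULL) {
  assert_image(flu, "flu"); assert_image(vis, "vis")
  grid <- expand.grid(scale = cfg$scales, method = cfg$methods,
                      representation = cfg$representations,
                      stringsAsFactors = FALSE)
  reps_needed <- unique(grid$representation)
  rep_imgs <- list()
  for (r in reps_needed) {
    rep_imgs[[r]] <- list(flu = build_representation(flu, r),
                          vis = build_representation(vis, r))
  }
  entries <- vector("list", nrow(grid))
  score_or <- !is.null(flu_mask) && !is.null(vis_mask)
  for (i in seq_len(nrow(grid))) {
    sc <- grid$scale[i]; me <- grid$method[i]; rp <- grid$representation[i]
    res <- tryCatch({
      mov <- if (sc < 1) downscale(rep_imgs[[rp]]$flu, sc) else rep_imgs[[rp]]$flu
      fix <- if (sc < 1) downscale(rep_imgs[[rp]]$vis, sc) else rep_imgs[[rp]]$vis
      r0 <- run_engine_cell(me, mov, fix, cfg$gate, cfg, cfg$seed + i)
      if (!is.null(r0$transform)) {
        t_full <- rescale_transform(r0$transform, sc, sc)
        adm <- is_admissible(t_full, cfg$gate)
        engine_fail <- any(!(r0$reasons %in% c("translation", "rotation", "scale")))
        registration_result(t_full, me,
                            success = adm$flag && !engine_fail,
                            quality = r0$quality, representation = rp,
                            scale = sc,
                            reasons = c(setdiff(r0$reasons,
                                                c("translation", "rotation", "scale")),
                                        adm$reasons),
                            extra = r0$extra)
      } else {
        r0$representation <- rp; r0$scale <- sc
        r0
      }
    }, error = function(e) failed_result(me, conditionMessage(e), rp, sc))
    or_val <- NA_real_
    if (score_or && res$success) {
      or_val <- overlap_ratio(flu_mask, vis_mask, res$transform)$OR
    }
    entries[[i]] <- list(scale = sc, method = me, representation = rp,
                         result = res, or = or_val)
  }
  structure(list(entries = entries, cfg = cfg), class = "sweep_result")
}

#' Merge the entries of several sweeps over the same image pair
#'
#' Useful when different engines are swept over different scale grids (e.g.,
#' a dense grid for the cheap engines and a coarse one for the
#' intensity-based engine) and their registrations should feed one
#' integrated mask.
#'
#' @param ... `sweep_result` objects for the same (moving, fixed) pair.
#' @return `sweep_result` with concatenated entries (cfg of the first).
#' @export
merge_sweeps <- function(...) {
  srs <- list(...)
  stopifnot(length(srs) >= 1L, all(vapply(srs, inherits, TRUE, "sweep_result")))
  structure(list(entries = do.call(c, lapply(srs, function(s) s$entries)),
                 cfg = srs[[1L]]$cfg),
            class = "sweep_result")
}

#' Tabulate a sweep result
#'
#' @param sr `sweep_result`.
#' @return `data.frame` with one row per grid cell: scale, method,
#'   representation, success flag, gate reasons, decomposed transform
#'   components, engine quality and OR (when scored).
#' @export
sweep_table <- function(sr) {
  stopifnot(inherits(sr, "sweep_result"))
  rows <- lapply(sr$entries, function(e) {
    r <- e$result
    d <- if (is.null(r$transform)) list(s = NA_real_, alpha = NA_real_,
                                        tx = NA_real_, ty = NA_real_)
         else decompose_similarity(r$transform)
    data.frame(scale = e$scale, method = e$method,
               representation = e$representation, success = r$success,
               reasons = paste(r$reasons, collapse = ";"),
               s = d$s, alpha_deg = d$alpha * 180 / pi, tx = d$tx, ty = d$ty,
               quality = as.numeric(r$quality), or = e$or,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

admissible_entries <- function(sr) {
  Filter(function(e) isTRUE(e$result$success), sr$entries)
}

#' Select the best entry of a sweep
#'
#' `criterion = "oracle_or"` picks the maximum ground-truth overlap ratio
#' (requires a sweep scored with masks). `criterion = "quality"` ranks
#' engine-native qualities within each engine (peak height, inlier fraction
#' and MI are not commensurable across engines) and picks the best rank with
#' method precedence PC, FP, INT on ties; remaining ties go to the larger
#' scale factor.
#'
#' @param sr `sweep_result`.
#' @param criterion `"oracle_or"` or `"quality"`.
#' @return the selected entry (list with `scale`, `method`,
#'   `representation`, `result`, `or`).
#' @export
select_best <- function(sr, criterion = c("oracle_or", "quality")) {
  criterion <- match.arg(criterion)
  adm <- admissible_entries(sr)
  if (length(adm) == 0L) stop("no admissible entry in sweep", call. = FALSE)
  if (criterion == "oracle_or") {
    ors <- vapply(adm, function(e) ifelse(is.na(e$or), -1, e$or), 0)
    if (all(ors < 0)) stop("sweep was not scored with ground-truth masks", call. = FALSE)
    return(adm[[which.max(ors)]])
  }
  meth <- vapply(adm, function(e) e$method, "")
  qual <- vapply(adm, function(e) {
    if (e$method == "FP" && !is.null(e$result$extra$inlier_fraction))
      e$result$extra$inlier_fraction else as.numeric(e$result$quality)
  }, 0)
  rankv <- numeric(length(adm))
  for (m in unique(meth)) {
    i <- meth == m
    rankv[i] <- rank(qual[i]) / sum(i)
  }
  prec <- c(PC = 3, FP = 2, INT = 1)
  scl <- vapply(adm, function(e) e$scale, 0)
  ord <- order(-rankv, -prec[meth], -scl)
  adm[[ord[1L]]]
}

#' Fuse multiple admissible registrations into an integrated mask
#'
#' Warps the FLU plant mask by every selected admissible entry's transform
#' onto the VIS grid and takes the pixelwise union, accumulating a per-pixel
#' count of contributing registrations. The union can only extend coverage,
#' so the integrated mask's overlap ratio dominates every contributor's -
#' this is what lets a set of single-step rigid registrations piecewise-cover
#' nonuniformly moving leaves.
#'
#' @param sr `sweep_result`.
#' @param flu_mask binary FLU plant mask on the sweep's moving grid.
#' @param out_height,out_width VIS grid dimensions.
#' @param top_k optional: keep only the `top_k` admissible entries by
#'   engine-native quality rank (default all).
#' @param vote_threshold keep a pixel if at least this many contributors
#'   cover it (default 1 = plain union).
#' @return object of class `integrated_mask`: list with `mask` (binary),
#'   `provenance` (per-pixel contributor count) and `contributors`
#'   (data.frame of the entries used).
#' @export
build_integrated_mask <- function(sr, flu_mask, out_height, out_width,
                                  top_k = NULL, vote_threshold = 1L) {
  adm <- admissible_entries(sr)
  if (length(adm) == 0L) stop("no admissible entry in sweep", call. = FALSE)
  if (!is.null(top_k) && length(adm) > top_k) {
    qual <- vapply(adm, function(e) {
      if (e$method == "FP" && !is.null(e$result$extra$inlier_fraction))
        e$result$extra$inlier_fraction else as.numeric(e$result$quality)
    }, 0)
    meth <- vapply(adm, function(e) e$method, "")
    rankv <- numeric(length(adm))
    for (m in unique(meth)) { i <- meth == m; rankv[i] <- rank(qual[i]) / sum(i) }
    adm <- adm[order(-rankv)[seq_len(top_k)]]
  }
  prov <- matrix(0L, out_height, out_width)
  for (e in adm) {
    prov <- prov + warp_mask(flu_mask, e$result$transform, out_height, out_width)
  }
  contributors <- do.call(rbind, lapply(adm, function(e)
    data.frame(scale = e$scale, method = e$method,
               representation = e$representation, or = e$or,
               stringsAsFactors = FALSE)))
  structure(list(mask = (prov >= vote_threshold) * 1, provenance = prov,
                 contributors = contributors),
            class = "integrated_mask")
}

#' Aggregate statistics over one or more sweeps
#'
#' @param sweeps list of `sweep_result` objects (or a single one).
#' @return list with `sr_table` (success rate per method x representation
#'   across all sweeps and scales), `best_or` (per-sweep maximum OR among
#'   admissible scored entries) and `components` (data.frame of decomposed
#'   transform components of all successful entries).
#' @export
summarize_sweep <- function(sweeps) {
  if (inherits(sweeps, "sweep_result")) sweeps <- list(sweeps)
  tabs <- lapply(sweeps, sweep_table)
  all_t <- do.call(rbind, tabs)
  sr_table <- aggregate(success ~ method + representation, data = all_t, FUN = mean)
  names(sr_table)[names(sr_table) == "success"] <- "SR"
  best_or <- vapply(tabs, function(tb) {
    v <- tb$or[tb$success & !is.na(tb$or)]
    if (length(v) == 0L) NA_real_ else max(v)
  }, 0)
  comp <- all_t[all_t$success, c("method", "representation", "scale",
                                 "s", "alpha_deg", "tx", "ty")]
  list(sr_table = sr_table, best_or = best_or, components = comp)
}

#' @importFrom stats aggregate
NULL
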