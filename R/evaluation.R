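# Registration evaluation: batch success rate and overlap-ratio accuracy
# against ground-truth plant masks.

#' Success rate of a batch of registrations
#'
#' `SR = n_s / n`: the fraction of outcomes whose transform passed the
#' admissibility gate (and engine-specific gates).
#'
#' @param outcomes list of `registration_result` objects, or a logical
#'   vector of success flags.
#' @return success rate in `[0, 1]` (exact rational as a double).
#' @export
success_rate <- function(outcomes) {
  if (length(outcomes) == 0L) stop("success_rate of an empty batch is undefined", call. = FALSE)
  flags <- if (is.logical(outcomes)) outcomes
           else vapply(outcomes, function(o) isTRUE(o$success), logical(1))
  sum(flags) / length(flags)
}

#' Overlap ratio between a registered FLU mask and a VIS ground-truth mask
#'
#' The FLU plant mask is warped onto the VIS grid by `t` (nearest-neighbor;
#' stays binary) and `OR = a_r / a` where `a_r` counts VIS plant pixels
#' covered by the warped FLU mask and `a` counts all VIS plant pixels. The
#' measure is deliberately asymmetric: warped FLU pixels falling outside VIS
#' plant regions do not penalize, because the purpose of the registration is
#' segmentation transfer into the VIS image.
#'
#' @param flu_mask binary FLU plant mask (0/1 matrix or logical).
#' @param vis_mask binary VIS plant mask with at least one plant pixel.
#' @param t `similarity_transform` mapping FLU into VIS coordinates.
#' @return list `(a_r, a, OR)`.
#' @export
overlap_ratio <- function(flu_mask, vis_mask, t) {
  if (is.logical(flu_mask)) flu_mask <- flu_mask * 1
  if (is.logical(vis_mask)) vis_mask <- vis_mask * 1
  assert_image(flu_mask, "flu_mask"); assert_image(vis_mask, "vis_mask")
  a <- sum(vis_mask >= 0.5)
  if (a == 0L) stop("empty VIS mask: overlap ratio undefined", call. = FALSE)
  warped <- warp_mask(flu_mask, t, img_height(vis_mask), img_width(vis_mask))
  a_r <- sum(warped == 1 & vis_mask >= 0.5)
  list(a_r = a_r, a = a, OR = a_r / a)
}

#' Gate a registration result and score its overlap accuracy
#'
#' Applies the success gate first; the overlap ratio is computed only for
#' successful outcomes (accuracy is defined for formally successful
#' alignments), unless `or_for_all = TRUE` for diagnostics.
#'
#' @param result `registration_result` (transform on the prescaled-FLU ->
#'   VIS grids).
#' @param flu_truth,vis_truth binary ground-truth masks; `flu_truth` lives
#'   on the grid `prescale_factor` times smaller than the grid `result`'s
#'   transform expects (use 1 when the mask is already prescaled).
#' @param prescale_factor FLU -> prescaled-FLU scale factor (default 1).
#' @param or_for_all compute OR even for failed outcomes (default `FALSE`).
#' @return list with `outcome` (the result) and `overlap` (list or `NULL`).
#' @export
evaluate_pair <- function(result, flu_truth, vis_truth, prescale_factor = 1,
                          or_for_all = FALSE) {
  stopifnot(inherits(result, "registration_result"))
  ov <- NULL
  if (!is.null(result$transform) && (result$success || or_for_all)) {
    t_full <- if (prescale_factor != 1)
      compose_transforms(result$transform, make_similarity(prescale_factor, 0, 0, 0))
    else result$transform
    ov <- overlap_ratio(flu_truth, vis_truth, t_full)
  }
  list(outcome = result, overlap = ov)
}

#' Format a ratio as a percentage string (two decimals, half-up)
#' @param x ratio in `[0, 1]`.
#' @return character, e.g. `"96.30"`.
#' @export
format_percent <- function(x) {
  sprintf("%.2f", floor(x * 10000 + 0.5) / 100)
}
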