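# Common result container shared by the three registration engines.

#' Construct a registration result
#'
#' @param transform `similarity_transform` (moving -> fixed) or `NULL` on
#'   engine failure.
#' @param method `"FP"`, `"PC"` or `"INT"`.
#' @param success logical: engine succeeded AND the transform passed the
#'   admissibility gate (plus engine-specific gates such as the PC peak
#'   threshold).
#' @param quality engine-native quality: FP inlier count, PC peak height `H`,
#'   INT final mutual information (nats).
#' @param representation `"GS"`, `"CE"` or `NA`.
#' @param scale sweep downscale factor the estimate was computed at.
#' @param reasons character vector of failure/gate reasons (empty if none).
#' @param extra optional named list of engine-specific provenance.
#' @return object of class `registration_result`.
#' @export
registration_result <- function(transform, method, success, quality,
                                representation = NA_character_, scale = 1,
                                reasons = character(0), extra = list()) {
  stopifnot(is.null(transform) || inherits(transform, "similarity_transform"))
  structure(list(transform = transform, method = method,
                 success = isTRUE(success), quality = quality,
                 representation = representation, scale = scale,
                 reasons = reasons, extra = extra),
            class = "registration_result")
}

failed_result <- function(method, reasons, representation = NA_character_,
                          scale = 1, quality = NA_real_, extra = list()) {
  registration_result(NULL, method, FALSE, quality, representation, scale,
                      reasons, extra)
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result [%s%s, scale %.2f]: %s (quality = %.4g)\n",
              x$method,
              if (is.na(x$representation)) "" else paste0("-", x$representation),
              x$scale,
              if (x$success) "success" else paste("failed:", paste(x$reasons, collapse = ", ")),
              if (is.numeric(x$quality)) x$quality else NA))
  if (!is.null(x$transform)) print(x$transform)
  invisible(x)
}

#' Serialize a registration result to a JSON-ready list
#' @param r `registration_result`.
#' @return plain list suitable for `jsonlite::write_json`.
#' @export
result_to_list <- function(r) {
  stopifnot(inherits(r, "registration_result"))
  list(method = r$method, representation = r$representation, scale = r$scale,
       success = r$success, quality = r$quality, reasons = as.list(r$reasons),
       transform = if (is.null(r$transform)) NULL else transform_to_list(r$transform))
}
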