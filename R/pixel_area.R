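#' Marker-positive area fraction
#'
#' Cell-agnostic quantification: the numerator is a boolean pixelwise
#' expression over named masks (`&`, `|`, `!`, parentheses), intersected
#' with the denominator region before counting, so numerator pixels
#' outside the denominator never contribute. The denominator is either a
#' mask name or `"image"` (the whole image).
#'
#' @param masks named list of [binary_mask]s sharing dimensions.
#' @param numerator boolean expression over mask names, e.g.
#'   `"IgA & lamina_propria"`.
#' @param denominator a mask name or `"image"`.
#' @param sample_id recorded in the result.
#' @return A one-row data frame with `sample_id`, `numerator_expression`,
#'   `denominator_name`, `positive_px`, `denominator_px` and `fraction`.
#' @export
positive_area <- function(masks, numerator, denominator = "image",
                          sample_id = "sample") {
  stopifnot(length(masks) >= 1L)
  mats <- lapply(masks, mask_px)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims != dims[, 1])) stop("masks have differing dimensions")
  expr <- parse_bool_expr(numerator, names(masks), what = "pixel-area")
  num <- eval(expr, envir = mats, enclos = baseenv())
  den <- if (identical(denominator, "image")) {
    matrix(TRUE, nrow(mats[[1L]]), ncol(mats[[1L]]))
  } else {
    if (!denominator %in% names(masks)) {
      stop("unknown denominator mask '", denominator, "'")
    }
    mats[[denominator]]
  }
  den_px <- sum(den)
  if (den_px == 0L) {
    stop("undefined fraction: denominator mask '", denominator,
         "' is empty")
  }
  pos_px <- sum(num & den)
  data.frame(sample_id = sample_id,
             numerator_expression = numerator,
             denominator_name = denominator,
             positive_px = pos_px,
             denominator_px = den_px,
             fraction = pos_px / den_px,
             stringsAsFactors = FALSE)
}
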