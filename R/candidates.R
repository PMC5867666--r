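# Drusen candidate detection by dual-scale median filtering.
#
# Hard drusen are small bright spots. A median filter with a mask larger
# than any druse erases them while preserving the retinal background and
# illumination gradient; a small mask removes impulse noise but leaves
# drusen intact. The difference of the two filtered images therefore
# isolates drusen-scale bright structure on a near-zero background, which a
# min-max histogram stretch then spreads over the full gray scale.

#' Median filter with an arbitrary square mask
#'
#' Rank filter replacing each pixel with the median of its
#' `mask_side` x `mask_side` neighbourhood under replicate border padding.
#' For even mask sides the output pixel sits at offset
#' `((mask_side-1) %/% 2, (mask_side-1) %/% 2)` within the window and the
#' lower median of the even-sized sample is taken, so the operation stays
#' deterministic and integer-valued.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param mask_side Window side in pixels (>= 1).
#' @return Filtered integer matrix, same dimensions.
#' @export
median_filter <- function(gray, mask_side) {
  assert_gray(gray)
  mask_side <- as.integer(mask_side)
  if (is.na(mask_side) || mask_side < 1) {
    druscan_abort("`mask_side` must be a positive integer", "druscan_invalid_parameter")
  }
  if (mask_side > nrow(gray) && mask_side > ncol(gray)) {
    druscan_abort(sprintf(
      "mask side %d exceeds both image dimensions (%d x %d)",
      mask_side, nrow(gray), ncol(gray)), "druscan_invalid_parameter")
  }
  median_filter_cpp(as_gray_int(gray), mask_side)
}

#' Dual-scale median-filter subtract image
#'
#' Computes `median(gray, small) - median(gray, large)`, clamped to
#' \[0, 255\]. The small mask (default 5) suppresses impulse noise without
#' touching drusen; the large mask (default 30) erases drusen along with the
#' noise, leaving the background. Their difference is bright exactly where
#' drusen-scale structure stood, and cancels smooth illumination gradients.
#' Negative residuals (dark structure such as vessels) clamp to zero since
#' only bright deposits are sought.
#'
#' @param gray Integer matrix in \[0, 255\] (green channel).
#' @param small_mask Odd window side for the noise-removal filter (default 5).
#' @param large_mask Window side exceeding the largest druse (default 30).
#' @return Integer matrix in \[0, 255\].
#' @export
subtract_candidates <- function(gray, small_mask = 5, large_mask = 30) {
  if (small_mask %% 2 == 0) {
    druscan_abort("`small_mask` must be odd", "druscan_invalid_parameter")
  }
  if (small_mask >= large_mask) {
    druscan_abort("`small_mask` must be smaller than `large_mask`",
                  "druscan_invalid_parameter")
  }
  small_f <- median_filter(gray, small_mask)
  large_f <- median_filter(gray, large_mask)
  out <- pmin(pmax(small_f - large_f, 0L), 255L)
  matrix(as.integer(out), nrow(gray), ncol(gray))
}

#' Min-max histogram stretch
#'
#' Linear rescale `v -> floor(255 * (v - min) / (max - min))` so the
#' subtract image, whose contrast is concentrated near zero, spans the full
#' 8-bit range before thresholding. A constant image maps to all zeros so
#' that druse-free inputs flow through the pipeline.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @return Integer matrix in \[0, 255\].
#' @export
histogram_stretch <- function(gray) {
  assert_gray(gray)
  gray <- as_gray_int(gray)
  lo <- min(gray); hi <- max(gray)
  if (hi == lo) {
    return(matrix(0L, nrow(gray), ncol(gray)))
  }
  matrix(as.integer(floor(255 * (as.numeric(gray) - lo) / (hi - lo))),
         nrow(gray), ncol(gray))
}
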