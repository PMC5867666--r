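# Optic-disc localisation and macular ROI construction.
#
# The optic disc is the brightest structure in a fundus photograph, so a
# fixed intensity threshold followed by connected-component labelling finds
# it reliably; the largest bright component is taken as the disc. The
# macular ROI is then built geometrically: the fovea lies roughly midway
# between the disc and the image edge on the opposite side, so the ROI is
# the circle centred at that midpoint whose radius reaches back to the disc
# centre (the fovea-to-disc distance).

#' Detect the optic disc
#'
#' Binarises the green channel at `intensity_threshold` (strictly greater),
#' labels connected components, and returns the largest as the optic disc.
#' The disc centre is the component centroid (mean member coordinate,
#' rounded half-up to the nearest pixel).
#'
#' @param gray Integer matrix in \[0, 255\] (green channel).
#' @param intensity_threshold 8-bit cutoff; pixels with intensity strictly
#'   above it are disc candidates. Default 200.
#' @param connectivity 4 or 8 (default 8) for component labelling.
#' @return An `optic_disc` object: `centroid` (row, col; 1-based),
#'   `pixel_count`, `mask` (logical matrix), and `side` ("left"/"right" half
#'   of the image).
#' @export
detect_optic_disc <- function(gray, intensity_threshold = 200, connectivity = 8) {
  assert_gray(gray)
  gray <- as_gray_int(gray)
  bw <- gray > intensity_threshold
  if (!any(bw)) {
    druscan_abort(sprintf(
      "no optic disc: no pixel exceeds intensity %d", intensity_threshold),
      "druscan_no_optic_disc")
  }
  lab <- label_components(bw, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  disc_id <- which.max(sizes)
  mask <- lab == disc_id
  idx <- which(mask, arr.ind = TRUE)
  centroid <- round_half_up(colMeans(idx))
  side <- if (centroid[2] <= ncol(gray) / 2) "left" else "right"
  structure(list(centroid = as.integer(unname(centroid)),
                 pixel_count = as.integer(sizes[disc_id]),
                 mask = mask,
                 side = side),
            class = "optic_disc")
}

#' @export
print.optic_disc <- function(x, ...) {
  cat(sprintf("<optic_disc> centroid (%d, %d), %d px, %s half\n",
              x$centroid[1], x$centroid[2], x$pixel_count, x$side))
  invisible(x)
}

#' Construct the macular ROI circle from the optic disc
#'
#' The ROI centre is the midpoint of the horizontal segment from the disc
#' centroid to the image edge on the opposite side, at the disc centroid's
#' row (taken as the fovea estimate); the radius is the distance from that
#' centre back to the disc centroid. Fractional midpoints floor to integer
#' columns.
#'
#' @param disc An `optic_disc`.
#' @param width,height Image dimensions in pixels.
#' @return A `roi_circle`: `center` (row, col; 1-based) and `radius` (pixels).
#' @export
compute_roi <- function(disc, width, height) {
  if (!inherits(disc, "optic_disc")) {
    druscan_abort("`disc` must be an optic_disc", "druscan_invalid_parameter")
  }
  row_d <- disc$centroid[1]; col_d <- disc$centroid[2]
  opposite <- if (disc$side == "left") as.integer(width) else 1L
  if (col_d == opposite) {
    druscan_abort("degenerate geometry: disc centroid lies on the opposite edge",
                  "druscan_invalid_geometry")
  }
  center_col <- (col_d + opposite) %/% 2L
  radius <- abs(center_col - col_d)
  if (radius <= 0) {
    druscan_abort("degenerate geometry: zero ROI radius", "druscan_invalid_geometry")
  }
  structure(list(center = c(row_d, as.integer(center_col)),
                 radius = as.integer(radius)),
            class = "roi_circle")
}

#' Construct an ROI circle directly
#'
#' @param center Numeric (row, col) centre, 1-based.
#' @param radius Positive radius in pixels (may be fractional).
#' @return A `roi_circle`.
#' @export
new_roi_circle <- function(center, radius) {
  if (length(center) != 2 || radius <= 0) {
    druscan_abort("`center` must be (row, col) and `radius` > 0",
                  "druscan_invalid_geometry")
  }
  structure(list(center = center, radius = radius), class = "roi_circle")
}

#' @export
print.roi_circle <- function(x, ...) {
  cat(sprintf("<roi_circle> center (%d, %d), radius %d px\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}

#' Rasterise an ROI circle to a binary mask
#'
#' A pixel belongs to the ROI iff its squared distance to the centre is at
#' most radius squared; the circle is clipped at the image bounds.
#'
#' @param roi A `roi_circle`.
#' @param width,height Image dimensions in pixels.
#' @return Logical matrix of dimension `height` x `width`.
#' @export
roi_mask <- function(roi, width, height) {
  if (!inherits(roi, "roi_circle")) {
    druscan_abort("`roi` must be a roi_circle", "druscan_invalid_parameter")
  }
  dr2 <- (seq_len(height) - roi$center[1])^2
  dc2 <- (seq_len(width) - roi$center[2])^2
  outer(dr2, dc2, `+`) <= roi$radius^2
}
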