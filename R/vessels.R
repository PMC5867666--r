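# Vessel-tree segmentation by seeded region growing.
#
# All retinal vessels emerge from the optic disc and are the darkest
# structures in the green channel, so seeds are picked as the darkest
# pixels in an annulus just outside the disc and grown by intensity
# similarity. The grown tree, together with the disc itself, is dilated
# into a "non-drusen" mask that absorbs the bright rims these structures
# leave in the subtract image.

disc_radius_px <- function(disc) sqrt(disc$pixel_count / pi)

annulus_indices <- function(disc, height, width) {
  r_disc <- disc_radius_px(disc)
  dr2 <- (seq_len(height) - disc$centroid[1])^2
  dc2 <- (seq_len(width) - disc$centroid[2])^2
  d2 <- outer(dr2, dc2, `+`)
  d2 > r_disc^2 & d2 <= (2 * r_disc)^2
}

#' Select a vessel seed just outside the optic disc
#'
#' Returns the darkest pixel in the annulus around the disc centroid whose
#' radii run from the disc's equivalent radius (the square root of
#' `pixel_count / pi`) to twice that value: vessels are the darkest
#' green-channel structures leaving the disc. Ties resolve to the first
#' pixel in row-major order.
#'
#' @param gray Integer matrix in \[0, 255\] (green channel).
#' @param disc An `optic_disc` detected on `gray`.
#' @return Integer vector `(row, col)`, 1-based.
#' @export
select_vessel_seed <- function(gray, disc) {
  assert_gray(gray)
  ann <- annulus_indices(disc, nrow(gray), ncol(gray))
  if (!any(ann)) {
    druscan_abort("vessel seed annulus is empty (disc fills the image)",
                  "druscan_invalid_geometry")
  }
  vals <- ifelse(ann, gray, NA_integer_)
  m <- min(vals, na.rm = TRUE)
  cand <- which(vals == m, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  as.integer(cand[1, ])
}

#' Select one vessel seed per angular sector around the disc
#'
#' A single seed can miss vessel branches on the far side of the disc, so
#' the annulus is split into `n_seeds` angular sectors and the darkest
#' pixel of each sector is returned. Sectors whose darkest pixel is not
#' clearly darker than the annulus median (by at least `min_contrast`) are
#' dropped: they contain no vessel.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param disc An `optic_disc`.
#' @param n_seeds Number of angular sectors (default 8).
#' @param min_contrast Minimum darkness below the annulus median intensity
#'   for a sector seed to count as vessel-like (default 15, the region-grow
#'   tolerance).
#' @return Integer matrix with columns `row`, `col`; zero rows if no sector
#'   holds a vessel-like pixel.
#' @export
select_vessel_seeds <- function(gray, disc, n_seeds = 8, min_contrast = 15) {
  assert_gray(gray)
  ann <- annulus_indices(disc, nrow(gray), ncol(gray))
  if (!any(ann)) {
    druscan_abort("vessel seed annulus is empty (disc fills the image)",
                  "druscan_invalid_geometry")
  }
  idx <- which(ann, arr.ind = TRUE)
  vals <- gray[ann]
  ref <- stats::median(vals)
  theta <- atan2(idx[, 1] - disc$centroid[1], idx[, 2] - disc$centroid[2])
  sector <- pmin(floor((theta + pi) / (2 * pi) * n_seeds) + 1, n_seeds)
  seeds <- matrix(0L, 0, 2, dimnames = list(NULL, c("row", "col")))
  for (s in seq_len(n_seeds)) {
    in_s <- sector == s
    if (!any(in_s)) next
    v <- vals[in_s]
    if (min(v) > ref - min_contrast) next
    sub <- idx[in_s, , drop = FALSE]
    cand <- sub[v == min(v), , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    seeds <- rbind(seeds, cand[1, , drop = FALSE])
  }
  storage.mode(seeds) <- "integer"
  seeds
}

#' Region growing from a seed pixel
#'
#' Breadth-first flood from `seed` that admits a neighbouring pixel iff its
#' intensity differs from the *seed* intensity by at most `tolerance`
#' (seed-fixed similarity). Growth aborts with a `druscan_region_overflow`
#' error once the region exceeds `max_region_fraction` of the image area,
#' which signals a tolerance too lax for the image at hand.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param seed Integer `(row, col)`, 1-based.
#' @param tolerance Maximum absolute intensity difference from the seed
#'   (default 15).
#' @param connectivity 4 or 8 (default 8).
#' @param max_region_fraction Abort threshold as a fraction of image area,
#'   in (0, 1\] (default 0.25).
#' @return Logical mask of the grown region.
#' @export
region_grow <- function(gray, seed, tolerance = 15, connectivity = 8,
                        max_region_fraction = 0.25) {
  assert_gray(gray)
  gray <- as_gray_int(gray)
  seed <- as.integer(seed)
  if (length(seed) != 2 || seed[1] < 1 || seed[1] > nrow(gray) ||
      seed[2] < 1 || seed[2] > ncol(gray)) {
    druscan_abort("`seed` must be (row, col) inside the image",
                  "druscan_invalid_parameter")
  }
  if (tolerance < 0 || max_region_fraction <= 0 || max_region_fraction > 1) {
    druscan_abort("need tolerance >= 0 and max_region_fraction in (0, 1]",
                  "druscan_invalid_parameter")
  }
  res <- region_grow_cpp(gray, seed[1] - 1L, seed[2] - 1L,
                         as.integer(tolerance), as.integer(connectivity),
                         max_region_fraction)
  if (res$overflow) {
    druscan_abort(sprintf(
      "region growing overflowed: reached %.1f%% of the image (limit %.1f%%); tolerance too lax",
      100 * res$fraction, 100 * max_region_fraction),
      "druscan_region_overflow", fraction = res$fraction)
  }
  res$mask
}

#' Build the non-drusen exclusion mask
#'
#' Union of the vessel mask and the optic-disc mask, dilated by
#' `dilation_radius` iterations of the 8-connected unit element, to absorb
#' the bright rims that flank vessels and disc in the subtract image.
#'
#' @param vessels Logical vessel mask.
#' @param disc An `optic_disc` (its mask is used), or a logical disc mask.
#' @param dilation_radius Dilation radius in pixels (default 2).
#' @return Logical exclusion mask.
#' @export
nondrusen_mask <- function(vessels, disc, dilation_radius = 2) {
  assert_mask(vessels, "vessels")
  disc_m <- if (inherits(disc, "optic_disc")) disc$mask else disc
  assert_mask(disc_m, "disc")
  assert_same_dim(vessels, disc_m, "masks")
  dilate_mask(vessels | disc_m, dilation_radius)
}
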