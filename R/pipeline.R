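# End-to-end drusen segmentation: green channel -> optic disc -> macular
# ROI -> dual-scale median subtract image -> histogram stretch -> Renyi
# threshold within the ROI -> vessel/disc exclusion -> size filter.

#' Pipeline configuration
#'
#' All tunable parameters of [segment_drusen()], grouped by stage, with the
#' published operating points as defaults.
#'
#' @param disc List: `intensity_threshold` (default 200), `connectivity` (8).
#' @param median List: `small_mask` (5), `large_mask` (30).
#' @param vessel List: `tolerance` (15), `connectivity` (8),
#'   `max_region_fraction` (0.25), `dilation_radius` (2), `n_seeds` (8).
#' @param renyi List: `alpha_low` (0.5), `alpha_high` (2).
#' @param min_drusen_area Components smaller than this many pixels are
#'   discarded from the final mask (default 4; set 0 to disable).
#' @param threshold_method `"renyi"` (default), `"max_entropy"` (the
#'   Shannon-limit component alone), or `"otsu"`.
#' @return A `druscan_config` (nested list).
#' @export
druscan_config <- function(disc = list(), median = list(), vessel = list(),
                           renyi = list(), min_drusen_area = 4,
                           threshold_method = c("renyi", "max_entropy", "otsu")) {
  merge_group <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) {
      druscan_abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
                    "druscan_invalid_parameter")
    }
    utils::modifyList(defaults, user)
  }
  structure(list(
    disc = merge_group(list(intensity_threshold = 200, connectivity = 8), disc),
    median = merge_group(list(small_mask = 5, large_mask = 30), median),
    vessel = merge_group(list(tolerance = 15, connectivity = 8,
                              max_region_fraction = 0.25, dilation_radius = 2,
                              n_seeds = 8), vessel),
    renyi = merge_group(list(alpha_low = 0.5, alpha_high = 2), renyi),
    min_drusen_area = min_drusen_area,
    threshold_method = match.arg(threshold_method)
  ), class = "druscan_config")
}

with_stage <- function(stage, expr) {
  withCallingHandlers(expr, druscan_error = function(e) {
    e$message <- sprintf("[stage %s] %s", stage, e$message)
    stop(e)
  })
}

#' Segment drusen in a fundus image
#'
#' Runs the full pipeline and returns the drusen mask together with every
#' intermediate product. Processing is carried out in a canonical
#' orientation (disc in the left half; right-disc images are mirrored in
#' and the results mirrored back), which makes the output exactly
#' equivariant under horizontal reflection of the input.
#'
#' If the region of interest contains a single gray level after
#' stretching (a druse-free image), there is nothing to threshold and an
#' empty drusen mask is returned with `threshold = NULL`.
#'
#' @param img A `fundus_rgb` image (or a `phantom_bundle`, whose image is
#'   used).
#' @param cfg A `druscan_config` (defaults apply if omitted).
#' @return A `drusen_segmentation`: `drusen_mask`, `candidate_mask`,
#'   `vessel_mask`, `nondrusen_mask`, `disc`, `roi`, `threshold`
#'   (`renyi_threshold` or `NULL`), `threshold_level`, `subtract`,
#'   `stretched`, and `config`.
#' @export
segment_drusen <- function(img, cfg = druscan_config()) {
  if (inherits(img, "phantom_bundle")) img <- img$image
  if (!inherits(img, "fundus_rgb")) {
    druscan_abort("`img` must be a fundus_rgb image", "druscan_invalid_parameter")
  }
  gray <- green_channel(img)
  H <- nrow(gray); W <- ncol(gray)

  disc <- with_stage("detect_optic_disc",
    detect_optic_disc(gray, cfg$disc$intensity_threshold, cfg$disc$connectivity))

  # canonical orientation: mirror right-disc images so the even-sized large
  # median window, which has no symmetric anchor, treats both laterality
  # classes identically
  flipped <- disc$side == "right"
  if (flipped) {
    gray <- fliplr(gray)
    disc <- flip_disc(disc, W)
  }

  roi <- with_stage("compute_roi", compute_roi(disc, W, H))
  roim <- roi_mask(roi, W, H)

  sub <- with_stage("subtract_candidates",
    subtract_candidates(gray, cfg$median$small_mask, cfg$median$large_mask))
  stretched <- histogram_stretch(sub)

  vmask <- with_stage("vessel_segmentation",
    grow_vessel_tree(gray, disc, cfg$vessel))
  ndm <- nondrusen_mask(vmask, disc, cfg$vessel$dilation_radius)

  # threshold over the ROI with the non-drusen structure excluded: the
  # bright rims the disc leaves in the subtract image would otherwise
  # dominate the upper histogram tail and push the cut above the drusen
  thr <- NULL
  t_level <- NULL
  hist_region <- roim & !ndm
  roi_levels <- unique(stretched[hist_region])
  if (length(roi_levels) < 2) {
    cand <- matrix(FALSE, H, W)  # nothing to threshold: druse-free ROI
  } else {
    h <- gray_histogram(stretched, within = hist_region)
    t_level <- switch(cfg$threshold_method,
      renyi = {
        thr <- with_stage("renyi_threshold",
          renyi_threshold(h, cfg$renyi$alpha_low, cfg$renyi$alpha_high))
        thr$t_c
      },
      max_entropy = with_stage("component_threshold", component_threshold(h, 1)),
      otsu = with_stage("otsu_threshold", otsu_threshold(h))
    )
    cand <- apply_threshold(stretched, t_level, roim)
  }

  drusen <- cand & !ndm
  drusen <- drop_small_components(drusen, cfg$min_drusen_area)

  if (flipped) {
    drusen <- fliplr(drusen); cand <- fliplr(cand)
    vmask <- fliplr(vmask); ndm <- fliplr(ndm)
    sub <- fliplr(sub); stretched <- fliplr(stretched)
    disc <- flip_disc(disc, W)
    roi$center[2] <- W + 1L - roi$center[2]
  }

  structure(list(drusen_mask = drusen,
                 candidate_mask = cand,
                 vessel_mask = vmask,
                 nondrusen_mask = ndm,
                 disc = disc,
                 roi = roi,
                 threshold = thr,
                 threshold_level = t_level,
                 subtract = sub,
                 stretched = stretched,
                 config = cfg),
            class = "drusen_segmentation")
}

flip_disc <- function(disc, width) {
  disc$mask <- fliplr(disc$mask)
  disc$centroid[2] <- as.integer(width + 1L - disc$centroid[2])
  disc$side <- if (disc$side == "left") "right" else "left"
  disc
}

# Grow the vessel tree from one seed per annulus sector; sectors whose seed
# floods past the area limit grew into the retinal background rather than a
# vessel and are discarded.
grow_vessel_tree <- function(gray, disc, vp) {
  H <- nrow(gray); W <- ncol(gray)
  seeds <- tryCatch(
    select_vessel_seeds(gray, disc, vp$n_seeds, min_contrast = vp$tolerance),
    druscan_invalid_geometry = function(e) matrix(0L, 0, 2))
  vmask <- matrix(FALSE, H, W)
  if (nrow(seeds) == 0) return(vmask)
  for (i in seq_len(nrow(seeds))) {
    grown <- tryCatch(
      region_grow(gray, seeds[i, ], vp$tolerance, vp$connectivity,
                  vp$max_region_fraction),
      druscan_region_overflow = function(e) NULL)
    if (!is.null(grown)) vmask <- vmask | grown
  }
  vmask
}

#' @export
print.drusen_segmentation <- function(x, ...) {
  n_comp <- max(label_components(x$drusen_mask, 8))
  cat("<drusen_segmentation>\n")
  print(x$disc)
  print(x$roi)
  if (!is.null(x$threshold)) print(x$threshold)
  else if (!is.null(x$threshold_level)) {
    cat(sprintf("  threshold level %d (%s)\n", x$threshold_level,
                x$config$threshold_method))
  } else cat("  no threshold applied (single-level ROI)\n")
  cat(sprintf("  %d drusen component(s), %d foreground pixel(s)\n",
              n_comp, sum(x$drusen_mask)))
  invisible(x)
}

#' Per-lesion areas of a segmentation mask
#'
#' Areas (pixel counts) of the 8-connected components of a mask; the unit
#' in which manual and automatic measurements are compared.
#'
#' @param mask Logical matrix.
#' @return Integer vector of component areas (possibly empty).
#' @export
component_areas <- function(mask) {
  assert_mask(mask)
  lab <- label_components(mask, 8)
  if (max(lab) == 0) return(integer(0))
  tabulate(lab[lab > 0L])
}
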