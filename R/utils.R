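# Internal helpers shared across the pipeline.

# Classed errors so callers can distinguish failure modes programmatically.
druscan_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "druscan_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

assert_gray <- function(gray, arg = "gray") {
  if (!is.matrix(gray) || !is.numeric(gray)) {
    druscan_abort(sprintf("`%s` must be a numeric matrix", arg),
                  "druscan_invalid_parameter")
  }
  if (anyNA(gray) || min(gray) < 0 || max(gray) > 255) {
    druscan_abort(sprintf("`%s` must hold 8-bit intensities in [0, 255]", arg),
                  "druscan_invalid_parameter")
  }
  invisible(gray)
}

as_gray_int <- function(gray) {
  storage.mode(gray) <- "integer"
  gray
}

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    druscan_abort(sprintf("`%s` must be a logical matrix", arg),
                  "druscan_invalid_parameter")
  }
  invisible(mask)
}

assert_same_dim <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    druscan_abort(sprintf("%s must share dimensions (%s vs %s)",
                          what, paste(dim(a), collapse = "x"),
                          paste(dim(b), collapse = "x")),
                  "druscan_dimension_mismatch")
  }
  invisible(NULL)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# Mirror a matrix about its vertical axis (reverse columns).
fliplr <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Label connected components of a binary mask
#'
#' Components are labelled 1..n; background is 0. Exposed because several
#' stages (optic-disc selection, region-level evaluation, small-component
#' suppression) rely on the same labelling semantics.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8): neighbourhood used to join pixels.
#' @return Integer matrix of component labels, same dimensions as `mask`.
#' @export
label_components <- function(mask, connectivity = 8) {
  assert_mask(mask)
  if (!connectivity %in% c(4, 8)) {
    druscan_abort("`connectivity` must be 4 or 8", "druscan_invalid_parameter")
  }
  label_components_cpp(mask, as.integer(connectivity))
}

# Morphological dilation by `radius` iterations of the 8-connected unit
# (3x3) structuring element, implemented with logical shifts.
dilate_mask <- function(mask, radius) {
  assert_mask(mask)
  if (radius <= 0) return(mask)
  H <- nrow(mask); W <- ncol(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, H, W)
    r_src <- max(1, 1 - dr):min(H, H - dr)
    c_src <- max(1, 1 - dc):min(W, W - dc)
    out[r_src + dr, c_src + dc] <- m[r_src, c_src]
    out
  }
  for (i in seq_len(radius)) {
    grown <- mask
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift(mask, dr, dc)
    }
    mask <- grown
  }
  mask
}

# Drop connected components with fewer than min_area pixels.
drop_small_components <- function(mask, min_area, connectivity = 8) {
  if (min_area <= 1 || !any(mask)) return(mask)
  lab <- label_components_cpp(mask, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}
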