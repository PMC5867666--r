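# Seeded synthetic fundus phantoms with exact ground truth.
#
# Clinical fundus photographs cannot ship with the package, so tests and
# examples run on phantoms that reproduce the structural features the
# pipeline depends on: a bright optic disc (intensity above the 200
# detection cutoff), dark vessels radiating outward from the disc, small
# soft-edged bright drusen in the macular half opposite the disc, a smooth
# illumination gradient, and salt-type impulse noise. Every phantom is
# deterministic given its seed and carries exact masks of what was planted.

#' Phantom specification
#'
#' Parameters of a synthetic fundus image. Defaults describe a
#' half-resolution fundus (768 x 512) with a moderate-contrast drusen load.
#'
#' @param width,height Image size in pixels (default 768 x 512).
#' @param disc_center Optional `(row, col)` disc centre; by default the
#'   disc sits at mid-height (small seeded jitter) at 15% of the width from
#'   the left or right edge, the side chosen by the seed.
#' @param disc_radius Disc radius in pixels (default 40).
#' @param disc_intensity Peak disc intensity, > 200 so the disc is
#'   detectable by the fixed threshold (default 230).
#' @param background_intensity Mean retinal background (default 120).
#' @param gradient_amplitude Peak-to-centre amplitude of the smooth linear
#'   illumination ramp, in gray levels (default 20).
#' @param n_vessels Number of vessels radiating from the disc (default 6).
#' @param vessel_intensity Vessel core intensity (dark; default 40).
#' @param vessel_width Vessel full width in pixels (default 3).
#' @param n_drusen Number of planted drusen (default 10).
#' @param drusen_diameter_range Min/max druse diameter in pixels (default
#'   c(4, 14); all well below the 30-px large median mask).
#' @param drusen_contrast Druse brightness above local background (default 40).
#' @param salt_noise_density Per-pixel probability of a salt (255) impulse
#'   (default 0.001).
#' @param seed Integer RNG seed; the phantom is a pure function of the spec.
#' @return A `phantom_spec` (list).
#' @export
phantom_spec <- function(width = 768, height = 512,
                         disc_center = NULL,
                         disc_radius = 40,
                         disc_intensity = 230,
                         background_intensity = 120,
                         gradient_amplitude = 20,
                         n_vessels = 6,
                         vessel_intensity = 40,
                         vessel_width = 3,
                         n_drusen = 10,
                         drusen_diameter_range = c(4, 14),
                         drusen_contrast = 40,
                         salt_noise_density = 0.001,
                         seed = 1L) {
  if (disc_intensity <= 200) {
    druscan_abort("`disc_intensity` must exceed 200 (the detection cutoff)",
                  "druscan_invalid_parameter")
  }
  if (max(drusen_diameter_range) >= 30) {
    druscan_abort("drusen diameters must stay below the 30-px large median mask",
                  "druscan_invalid_parameter")
  }
  if (salt_noise_density < 0 || salt_noise_density > 1) {
    druscan_abort("`salt_noise_density` must lie in [0, 1]",
                  "druscan_invalid_parameter")
  }
  structure(as.list(environment()), class = "phantom_spec")
}

# soft-edged disk profile: 1 inside radius - 0.5, linear falloff to 0 at
# radius + 1 (1.5-px taper), evaluated at distance d
soft_disk <- function(d, radius) {
  pmin(pmax((radius + 1 - d) / 1.5, 0), 1)
}

#' Generate a synthetic fundus phantom
#'
#' Renders the green plane as background + illumination ramp + anti-aliased
#' bright disc + dark random-walk vessels leaving the disc rim + soft-edged
#' bright drusen around the geometric fovea + salt impulses; red and blue
#' planes are scaled copies of the green plane. Ground-truth masks record
#' the planted pixels exactly and are pairwise disjoint (impulses are never
#' placed on a planted structure).
#'
#' @param spec A `phantom_spec`.
#' @return A `phantom_bundle`: `image` (`fundus_rgb`), `green` (the exact
#'   green plane), `disc_mask`, `vessel_mask`, `drusen_mask`,
#'   `macula_center`, `drusen_centers`, `drusen_diameters`, `n_salt`, and
#'   the `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    druscan_abort("`spec` must be a phantom_spec", "druscan_invalid_parameter")
  }
  withr::with_seed(spec$seed, render_phantom(spec))
}

render_phantom <- function(spec) {
  H <- spec$height; W <- spec$width
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  # illumination ramp in a random direction
  theta <- stats::runif(1, 0, 2 * pi)
  ramp <- spec$gradient_amplitude *
    (cos(theta) * (cols / W - 0.5) + sin(theta) * (rows / H - 0.5)) * 2
  v <- spec$background_intensity + ramp

  # disc: left or right side, mid-height with jitter
  if (is.null(spec$disc_center)) {
    side_left <- stats::runif(1) < 0.5
    disc_col <- if (side_left) round(0.15 * W) else round(0.85 * W)
    disc_row <- round(H / 2 + stats::runif(1, -0.05, 0.05) * H)
    disc_center <- c(disc_row, disc_col)
  } else {
    disc_center <- spec$disc_center
  }
  d_disc <- sqrt((rows - disc_center[1])^2 + (cols - disc_center[2])^2)
  f_disc <- soft_disk(d_disc, spec$disc_radius)
  v <- v + (spec$disc_intensity - v) * f_disc
  disc_mask <- f_disc >= 0.5

  # vessels: random-walk polylines leaving the disc rim outward; the
  # cross-section has a flat dark core (vessels are near-uniformly dark in
  # the green channel) with a 0.75-px anti-aliasing taper
  vessel_w <- matrix(0, H, W)
  v_radius <- spec$vessel_width / 2
  reach <- ceiling(v_radius + 1)
  n_v <- spec$n_vessels
  if (n_v > 0) {
    angles <- 2 * pi * (seq_len(n_v) - 1) / n_v + stats::runif(n_v, -0.3, 0.3)
    for (ang0 in angles) {
      pos <- disc_center + (spec$disc_radius + 1) * c(sin(ang0), cos(ang0))
      ang <- ang0
      for (step in seq_len(2 * max(H, W))) {
        r0 <- pos[1]; c0 <- pos[2]
        if (r0 < 1 || r0 > H || c0 < 1 || c0 > W) break
        rr <- max(1, floor(r0) - reach):min(H, ceiling(r0) + reach)
        cc <- max(1, floor(c0) - reach):min(W, ceiling(c0) + reach)
        d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
        w <- pmin(pmax((v_radius + 0.75 - sqrt(d2)) / 0.75, 0), 1)
        vessel_w[rr, cc] <- pmax(vessel_w[rr, cc], w)
        ang <- ang + stats::rnorm(1, 0, 0.08)
        pos <- pos + c(sin(ang), cos(ang))
      }
    }
  }
  # never darken the disc interior; vessels live outside the rim
  vessel_w[d_disc <= spec$disc_radius + 1] <- 0
  v <- v + (spec$vessel_intensity - v) * vessel_w
  vessel_mask <- vessel_w >= 0.5

  # macular centre: midpoint between disc and opposite edge, with jitter
  opposite <- if (disc_center[2] <= W / 2) W else 1
  fovea <- c(disc_center[1] + round(stats::runif(1, -0.05, 0.05) * H),
             (disc_center[2] + opposite) %/% 2 + round(stats::runif(1, -0.03, 0.03) * W))

  # drusen: soft-edged bright disks near the fovea, off vessels and disc
  drusen_mask <- matrix(FALSE, H, W)
  blocked <- dilate_mask(vessel_mask, 3) | dilate_mask(disc_mask, 3)
  place_r <- 0.22 * W
  centers <- matrix(numeric(0), 0, 2)
  diams <- numeric(0)
  n_d <- spec$n_drusen
  if (n_d > 0) {
    tries <- 0
    while (nrow(centers) < n_d) {
      tries <- tries + 1
      if (tries > 200 * n_d) {
        druscan_abort("cannot place the requested drusen without overlap",
                      "druscan_placement_error")
      }
      diam <- stats::runif(1, spec$drusen_diameter_range[1],
                           spec$drusen_diameter_range[2])
      rad <- diam / 2
      ang <- stats::runif(1, 0, 2 * pi)
      dist <- place_r * sqrt(stats::runif(1))
      ctr <- round(fovea + dist * c(sin(ang), cos(ang)))
      margin <- rad + 2
      if (ctr[1] < 1 + margin || ctr[1] > H - margin ||
          ctr[2] < 1 + margin || ctr[2] > W - margin) next
      # stay in the macular half opposite the disc
      if (disc_center[2] <= W / 2) {
        if (ctr[2] - margin <= W / 2) next
      } else {
        if (ctr[2] + margin > W / 2) next
      }
      # keep drusen in the macular half, apart, and off vessels/disc
      if (nrow(centers) > 0) {
        gaps <- sqrt((centers[, 1] - ctr[1])^2 + (centers[, 2] - ctr[2])^2)
        if (any(gaps < (diams / 2 + rad + 4))) next
      }
      rr <- max(1, ctr[1] - ceiling(rad) - 2):min(H, ctr[1] + ceiling(rad) + 2)
      cc <- max(1, ctr[2] - ceiling(rad) - 2):min(W, ctr[2] + ceiling(rad) + 2)
      if (any(blocked[rr, cc])) next
      d <- sqrt(outer((rr - ctr[1])^2, (cc - ctr[2])^2, `+`))
      f <- soft_disk(d, rad)
      v[rr, cc] <- v[rr, cc] + spec$drusen_contrast * f
      drusen_mask[rr, cc] <- drusen_mask[rr, cc] | (f >= 0.5)
      centers <- rbind(centers, ctr)
      diams <- c(diams, diam)
    }
  }

  # salt impulses, kept off every planted structure
  planted <- disc_mask | vessel_mask | drusen_mask
  salt <- matrix(stats::runif(H * W) < spec$salt_noise_density, H, W) & !planted
  green <- round_half_up(v)
  green[salt] <- 255
  green <- matrix(as.integer(pmin(pmax(green, 0), 255)), H, W)

  red <- matrix(as.integer(pmin(pmax(round_half_up(green * 0.85 + 60), 0), 255)), H, W)
  blue <- matrix(as.integer(pmin(pmax(round_half_up(green * 0.35), 0), 255)), H, W)

  structure(list(image = new_fundus_rgb(red, green, blue),
                 green = green,
                 disc_mask = disc_mask,
                 vessel_mask = vessel_mask,
                 drusen_mask = drusen_mask,
                 disc_center = disc_center,
                 macula_center = fovea,
                 drusen_centers = centers,
                 drusen_diameters = diams,
                 n_salt = sum(salt),
                 spec = spec),
            class = "phantom_bundle")
}

#' @export
print.phantom_bundle <- function(x, ...) {
  cat(sprintf(
    "<phantom_bundle> %d x %d, disc at (%d, %d), %d drusen, %d salt impulses (seed %d)\n",
    nrow(x$green), ncol(x$green), x$disc_center[1], x$disc_center[2],
    nrow(x$drusen_centers), x$n_salt, x$spec$seed))
  invisible(x)
}

#' Difficulty-graded phantom suites
#'
#' Fixed parameter tables spanning easy to hard imaging conditions:
#' \describe{
#'   \item{easy}{drusen contrast +60, no illumination gradient, sparse noise}
#'   \item{medium}{contrast +40, moderate gradient (20 levels)}
#'   \item{hard}{contrast +20, strong gradient (40 levels), dense noise}
#' }
#'
#' @param seeds Nonempty integer vector; one phantom per seed.
#' @param difficulty `"easy"`, `"medium"`, or `"hard"`.
#' @param ... Further overrides passed to [phantom_spec()].
#' @return List of `phantom_bundle`s.
#' @export
phantom_suite <- function(seeds, difficulty = c("easy", "medium", "hard"), ...) {
  if (length(seeds) == 0) {
    druscan_abort("`seeds` must be nonempty", "druscan_invalid_parameter")
  }
  difficulty <- match.arg(difficulty)
  pars <- switch(difficulty,
    easy   = list(drusen_contrast = 60, gradient_amplitude = 0,
                  salt_noise_density = 0.0005),
    medium = list(drusen_contrast = 40, gradient_amplitude = 20,
                  salt_noise_density = 0.001),
    hard   = list(drusen_contrast = 20, gradient_amplitude = 40,
                  salt_noise_density = 0.005))
  lapply(seeds, function(s) {
    generate_phantom(do.call(phantom_spec, c(pars, list(seed = s), list(...))))
  })
}
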