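# Independent reference implementations used to cross-check the package's
# vectorised / compiled paths, plus small fixture builders. Everything here
# is deliberately written the slow, literal way.

# Renyi / Shannon class-entropy sum at cut t (levels 0..255), by direct
# summation over the class distributions.
oracle_entropy_sum <- function(p, t, alpha) {
  i <- t + 1
  p1 <- p[1:i]; p2 <- p[(i + 1):256]
  P1 <- sum(p1); P2 <- sum(p2)
  if (P1 <= 0 || P2 <= 0) return(NA_real_)
  ent <- function(q, P) {
    q <- q[q > 0] / P
    if (abs(alpha - 1) < 1e-12) -sum(q * log(q))
    else log(sum(q^alpha)) / (1 - alpha)
  }
  ent(p1, P1) + ent(p2, P2)
}

# Exhaustive argmax over all 255 cut points (smallest-t tie-break).
oracle_component_threshold <- function(p, alpha) {
  best_t <- NA_integer_; best <- -Inf
  for (t in 0:254) {
    v <- oracle_entropy_sum(p, t, alpha)
    if (!is.na(v) && v > best + 1e-15) { best <- v; best_t <- t }
  }
  best_t
}

# Literal transcription of the three-threshold combination rule, applied to
# given component thresholds.
oracle_combined_threshold <- function(p, comps) {
  ts <- sort(comps)
  P <- function(t) sum(p[1:(t + 1)])
  d12 <- abs(ts[1] - ts[2]); d23 <- abs(ts[2] - ts[3])
  if (d12 <= 5 && d23 <= 5) b <- c(1, 2, 1)
  else if (d12 > 5 && d23 > 5) b <- c(1, 2, 1)
  else if (d12 <= 5 && d23 > 5) b <- c(0, 1, 3)
  else b <- c(3, 1, 0)
  om <- P(ts[3]) - P(ts[1])
  tc <- ts[1] * (P(ts[1]) + 0.25 * om * b[1]) +
    0.25 * ts[2] * om * b[2] +
    ts[3] * (1 - P(ts[3]) + 0.25 * om * b[3])
  list(beta = b, omega = om, t_c = floor(tc + 0.5))
}

# Exhaustive Otsu: maximize between-class variance directly.
oracle_otsu <- function(p) {
  lv <- 0:255
  best_t <- NA_integer_; best <- -Inf
  for (t in 0:254) {
    w1 <- sum(p[1:(t + 1)]); w2 <- 1 - w1
    if (w1 <= 0 || w2 <= 0) next
    m1 <- sum(p[1:(t + 1)] * lv[1:(t + 1)]) / w1
    m2 <- sum(p[(t + 2):256] * lv[(t + 2):256]) / w2
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best + 1e-15) { best <- v; best_t <- t }
  }
  best_t
}

# Sparse random histogram over a limited number of active bins.
random_histogram <- function(seed, n_bins = 40) {
  withr::with_seed(seed, {
    bins <- sample.int(256, n_bins)
    p <- numeric(256)
    p[bins] <- stats::runif(n_bins)
    p / sum(p)
  })
}

# Plain-R flood fill: connected component of the seed in the similarity-
# thresholded image, via repeated neighbourhood expansion on a logical
# matrix (no shared code with the compiled path).
oracle_region_grow <- function(img, seed, tol, connectivity = 8) {
  H <- nrow(img); W <- ncol(img)
  sim <- abs(img - img[seed[1], seed[2]]) <= tol
  reg <- matrix(FALSE, H, W)
  reg[seed[1], seed[2]] <- TRUE
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  repeat {
    grown <- reg
    for (k in seq_len(nrow(offs))) {
      dr <- offs[k, 1]; dc <- offs[k, 2]
      sh <- matrix(FALSE, H, W)
      r_src <- max(1, 1 - dr):min(H, H - dr)
      c_src <- max(1, 1 - dc):min(W, W - dc)
      sh[r_src + dr, c_src + dc] <- reg[r_src, c_src]
      grown <- grown | (sh & sim)
    }
    if (identical(grown, reg)) break
    reg <- grown
  }
  reg
}

# Two-way ANOVA variance components for the agreement ICC, from explicit
# sums of squares (n subjects, 2 raters).
oracle_icc_a1 <- function(manual, auto) {
  n <- length(manual); k <- 2
  x <- cbind(manual, auto)
  grand <- mean(x)
  ss_rows <- k * sum((rowMeans(x) - grand)^2)
  ss_cols <- n * sum((colMeans(x) - grand)^2)
  ss_tot <- sum((x - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Flat grayscale field with a soft-edged bright disk planted at its centre
# (same edge model as the phantom drusen).
planted_disk_image <- function(size = 101, diameter = 8, background = 100,
                               contrast = 60) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  d <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  f <- pmin(pmax((diameter / 2 + 1 - d) / 1.5, 0), 1)
  matrix(as.integer(round(background + contrast * f)), size, size)
}

# Uncompressed 24-bit BMP writer (test fixture only; the package only reads
# BMP). rgb: list of integer matrices red/green/blue.
write_bmp24 <- function(rgb, path) {
  H <- nrow(rgb$red); W <- ncol(rgb$red)
  row_bytes <- ((W * 3 + 3) %/% 4) * 4
  data_size <- row_bytes * H
  le <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)
  header <- c(charToRaw("BM"), le(54 + data_size, 4), le(0, 4), le(54, 4),
              le(40, 4), le(W, 4), le(H, 4), le(1, 2), le(24, 2),
              le(0, 4), le(data_size, 4), le(2835, 4), le(2835, 4),
              le(0, 4), le(0, 4))
  px <- raw(data_size)
  for (r in seq_len(H)) {
    rr <- H - r + 1  # bottom-up
    row <- as.raw(rbind(rgb$blue[rr, ], rgb$green[rr, ], rgb$red[rr, ]))
    px[((r - 1) * row_bytes + 1):((r - 1) * row_bytes + 3 * W)] <- row
  }
  writeBin(c(header, px), path)
  invisible(path)
}

# Region-level recall/DSC of a segmentation against a phantom's truth.
phantom_scores <- function(bundle, result) {
  roim <- roi_mask(result$roi, ncol(bundle$green), nrow(bundle$green))
  reg <- conditional_probabilities(
    confusion_regionwise(result$drusen_mask, bundle$drusen_mask, roim))
  pix <- conditional_probabilities(
    confusion_pixelwise(result$drusen_mask, bundle$drusen_mask, roim))
  list(region = reg, pixel = pix, roi = roim)
}

flip_cols <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
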