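# Renyi-entropy automatic thresholding.
#
# A gray-level cut t splits the histogram P_0..P_255 into a low class A1
# (levels 0..t) and a high class A2 (levels t+1..255). For an order
# alpha != 1 the Renyi entropy of each normalised class distribution is
#
#   H^a_A1(t) = 1/(1-a) * ln( sum_{i<=t} (P_i / P_A1)^a ),
#
# and the component threshold t(alpha) maximises H^a_A1(t) + H^a_A2(t); as
# alpha -> 1 this reduces to the Shannon (maximum-entropy-sum) criterion.
# Three components are computed -- one with alpha < 1, the Shannon limit,
# and one with alpha > 1 -- sorted ascending and blended into a single cut
#
#   t_c = t[1]*(P(t[1]) + w*b1/4) + t[2]*w*b2/4 + t[3]*(1 - P(t[3]) + w*b3/4)
#
# where P(t) is the cumulative mass up to t, w = P(t[3]) - P(t[1]), and the
# weights (b1,b2,b3) depend on how far apart the components landed:
# (1,2,1) when the spacings |t[1]-t[2]| and |t[2]-t[3]| are both <= 5 or
# both > 5, (0,1,3) when only the upper spacing exceeds 5, and (3,1,0) when
# only the lower one does. Since the blend weights sum to one, t_c always
# lies between t[1] and t[3].

#' Normalised gray-level histogram
#'
#' 256-bin probability distribution of the 8-bit intensities inside a mask.
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param within Optional logical mask restricting the pixels counted
#'   (default: whole image).
#' @return A `gray_histogram`: numeric vector of 256 probabilities summing
#'   to 1; element `i` is the mass of gray level `i - 1`.
#' @export
gray_histogram <- function(gray, within = NULL) {
  assert_gray(gray)
  gray <- as_gray_int(gray)
  vals <- if (is.null(within)) {
    as.vector(gray)
  } else {
    assert_mask(within, "within")
    assert_same_dim(gray, within, "image and mask")
    gray[within]
  }
  if (length(vals) == 0) {
    druscan_abort("empty region: no pixels to histogram", "druscan_empty_region")
  }
  counts <- tabulate(vals + 1L, nbins = 256L)
  structure(counts / sum(counts), class = "gray_histogram")
}

#' Construct a gray histogram from counts or probabilities
#'
#' @param x Numeric vector of 256 nonnegative bin weights; normalised to
#'   sum to 1.
#' @return A `gray_histogram`.
#' @export
as_gray_histogram <- function(x) {
  if (length(x) != 256 || any(x < 0) || sum(x) <= 0) {
    druscan_abort("need 256 nonnegative bin weights with positive total",
                  "druscan_invalid_parameter")
  }
  structure(as.numeric(x) / sum(x), class = "gray_histogram")
}

#' Renyi entropy of a gray-level distribution
#'
#' `H^a = 1/(1-a) * ln(sum p_i^a)` over the nonzero bins; at `alpha = 1`
#' the Shannon limit `-sum p_i ln p_i`. The uniform distribution over n
#' levels has entropy `ln n` for every order; a degenerate (single-level)
#' distribution has entropy 0.
#'
#' @param h A `gray_histogram`.
#' @param alpha Entropy order (positive; 1 means Shannon).
#' @return Entropy in nats.
#' @export
renyi_entropy <- function(h, alpha) {
  p <- unclass(h)
  if (alpha <= 0) {
    druscan_abort("`alpha` must be positive", "druscan_invalid_parameter")
  }
  p <- p[p > 0]
  if (abs(alpha - 1) < 1e-12) -sum(p * log(p))
  else log(sum(p^alpha)) / (1 - alpha)
}

#' Renyi class entropies at a cut point
#'
#' Entropies of the two class distributions induced by cutting the
#' histogram after level `t`: A1 spans levels `0..t`, A2 spans `t+1..255`.
#' `alpha = 1` gives the Shannon entropies (the Renyi limit).
#'
#' @param h A `gray_histogram`.
#' @param t Cut level in \[0, 254\].
#' @param alpha Entropy order (positive; 1 means Shannon).
#' @return Numeric `(H_A1, H_A2)` in nats; `NA` for a class with zero mass
#'   (entropy undefined there).
#' @export
class_entropies <- function(h, t, alpha) {
  p <- unclass(h)
  if (t < 0 || t > 254) {
    druscan_abort("`t` must lie in [0, 254]", "druscan_invalid_parameter")
  }
  i <- t + 1L
  p1 <- p[seq_len(i)]; p2 <- p[(i + 1L):256L]
  ent <- function(q) {
    mass <- sum(q)
    if (mass <= 0) return(NA_real_)
    q <- q[q > 0] / mass
    if (abs(alpha - 1) < 1e-12) -sum(q * log(q))
    else log(sum(q^alpha)) / (1 - alpha)
  }
  c(ent(p1), ent(p2))
}

# Vectorised entropy-sum curve over all cuts t = 0..254; NA where a class
# has zero mass. Shared by component_threshold and its callers.
entropy_sum_curve <- function(p, alpha) {
  cp <- cumsum(p)
  P1 <- cp[1:255]
  P2 <- 1 - P1
  valid <- P1 > 0 & P2 > 0
  if (abs(alpha - 1) < 1e-12) {
    s <- ifelse(p > 0, p * log(p), 0)
    cs <- cumsum(s)
    S1 <- cs[1:255]; S2 <- cs[256] - S1
    H1 <- log(P1) - S1 / P1
    H2 <- log(P2) - S2 / P2
  } else {
    a <- p^alpha
    ca <- cumsum(a)
    A1 <- ca[1:255]; A2 <- ca[256] - A1
    H1 <- (log(A1) - alpha * log(P1)) / (1 - alpha)
    H2 <- (log(A2) - alpha * log(P2)) / (1 - alpha)
  }
  out <- H1 + H2
  out[!valid] <- NA_real_
  out
}

#' Entropy-maximising component threshold
#'
#' Argmax over cuts `t` in 0..254 of the class-entropy sum
#' `H^a_A1(t) + H^a_A2(t)`. `alpha = 1` uses the Shannon limit, i.e. the
#' classic maximum-entropy-sum threshold. Cuts leaving either class empty
#' are excluded; ties resolve to the smallest `t`.
#'
#' @param h A `gray_histogram` with at least two nonzero bins.
#' @param alpha Entropy order (positive).
#' @return Integer threshold in \[0, 254\].
#' @export
component_threshold <- function(h, alpha) {
  p <- unclass(h)
  if (sum(p > 0) < 2) {
    druscan_abort("degenerate histogram: fewer than two nonzero bins",
                  "druscan_degenerate_histogram")
  }
  if (alpha <= 0) {
    druscan_abort("`alpha` must be positive", "druscan_invalid_parameter")
  }
  curve <- entropy_sum_curve(p, alpha)
  if (all(is.na(curve))) {
    druscan_abort("degenerate histogram: no admissible cut point",
                  "druscan_degenerate_histogram")
  }
  as.integer(which.max(ifelse(is.na(curve), -Inf, curve)) - 1L)
}

#' Combined Renyi-entropy threshold
#'
#' Computes the three component thresholds -- `t(alpha_low)` with
#' `alpha_low` in (0,1), the Shannon limit `t(1)`, and `t(alpha_high)` with
#' `alpha_high > 1` -- sorts them ascending, and blends them into the final
#' cut `t_c` using the spacing-dependent weight table (see the package
#' vignette for the formula). `t_c` is rounded half-up to a gray level.
#'
#' @param h A `gray_histogram` with at least two nonzero bins.
#' @param alpha_low Order below 1 (default 0.5).
#' @param alpha_high Order above 1 (default 2).
#' @return A `renyi_threshold` object: `t_components` (in alpha order),
#'   `t_sorted` (ascending), `beta` (weight triple), `omega` (probability
#'   mass between the outer components), `t_c` (combined threshold), and
#'   `alphas`.
#' @export
renyi_threshold <- function(h, alpha_low = 0.5, alpha_high = 2) {
  if (alpha_low <= 0 || alpha_low >= 1 || alpha_high <= 1) {
    druscan_abort("need 0 < alpha_low < 1 and alpha_high > 1",
                  "druscan_invalid_parameter")
  }
  comps <- c(low = component_threshold(h, alpha_low),
             shannon = component_threshold(h, 1),
             high = component_threshold(h, alpha_high))
  combine_renyi_components(h, comps, c(alpha_low, 1, alpha_high))
}

# Blend sorted component thresholds by the spacing-dependent weight table.
combine_renyi_components <- function(h, comps, alphas) {
  p <- unclass(h)
  cp <- cumsum(p)
  ts <- sort(as.integer(comps))
  P <- function(t) if (t < 0) 0 else cp[t + 1L]  # cumulative mass up to level t
  d12 <- ts[2] - ts[1]
  d23 <- ts[3] - ts[2]
  beta <-
    if (d12 <= 5 && d23 <= 5)      c(1, 2, 1)
    else if (d12 > 5 && d23 > 5)   c(1, 2, 1)
    else if (d12 <= 5 && d23 > 5)  c(0, 1, 3)
    else                           c(3, 1, 0)
  omega <- P(ts[3]) - P(ts[1])
  t_c <- ts[1] * (P(ts[1]) + 0.25 * omega * beta[1]) +
         0.25 * ts[2] * omega * beta[2] +
         ts[3] * (1 - P(ts[3]) + 0.25 * omega * beta[3])
  structure(list(t_components = comps,
                 t_sorted = ts,
                 beta = beta,
                 omega = omega,
                 t_c = as.integer(round_half_up(t_c)),
                 alphas = alphas),
            class = "renyi_threshold")
}

#' @export
print.renyi_threshold <- function(x, ...) {
  cat(sprintf(
    "<renyi_threshold> components (%s) -> sorted (%s), beta (%s), omega %.4f, t_c = %d\n",
    paste(x$t_components, collapse = ", "),
    paste(x$t_sorted, collapse = ", "),
    paste(x$beta, collapse = ","), x$omega, x$t_c))
  invisible(x)
}

#' Apply an intensity threshold within a mask
#'
#' @param gray Integer matrix in \[0, 255\].
#' @param t Threshold in \[0, 255\]; pixels strictly above it are foreground.
#' @param within Optional logical mask; pixels outside it are always
#'   background.
#' @return Logical mask.
#' @export
apply_threshold <- function(gray, t, within = NULL) {
  assert_gray(gray)
  if (t < 0 || t > 255) {
    druscan_abort("`t` must lie in [0, 255]", "druscan_invalid_parameter")
  }
  out <- gray > t
  if (!is.null(within)) {
    assert_mask(within, "within")
    assert_same_dim(gray, within, "image and mask")
    out <- out & within
  }
  out
}

#' Otsu threshold (baseline)
#'
#' Maximises the between-class variance over all cuts; provided as the
#' conventional baseline against which entropy thresholding is compared.
#' Ties resolve to the smallest threshold.
#'
#' @param h A `gray_histogram` with at least two nonzero bins.
#' @return Integer threshold in \[0, 254\].
#' @export
otsu_threshold <- function(h) {
  p <- unclass(h)
  if (sum(p > 0) < 2) {
    druscan_abort("degenerate histogram: fewer than two nonzero bins",
                  "druscan_degenerate_histogram")
  }
  lv <- 0:255
  w1 <- cumsum(p)[1:255]
  w2 <- 1 - w1
  m1 <- cumsum(p * lv)[1:255]
  mu <- sum(p * lv)
  valid <- w1 > 0 & w2 > 0
  crit <- (mu * w1 - m1)^2 / (w1 * w2)
  crit[!valid] <- -Inf
  as.integer(which.max(crit) - 1L)
}
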