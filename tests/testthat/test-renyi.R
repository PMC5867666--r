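two_spike <- function(a = 50, b = 200, wa = 0.5) {
  p <- numeric(256); p[a + 1] <- wa; p[b + 1] <- 1 - wa
  as_gray_histogram(p)
}

test_that("gray histograms are normalised over the requested region", {
  g <- matrix(c(0L, 0L, 255L, 255L), 2, 2)
  h <- gray_histogram(g)
  expect_equal(h[1], 0.5)
  expect_equal(h[256], 0.5)
  expect_equal(sum(h), 1)

  uni <- gray_histogram(matrix(7L, 3, 3))
  expect_equal(uni[8], 1)

  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  h2 <- gray_histogram(g, within = m)
  expect_equal(h2[1], 1)  # only the two zeros are inside the mask

  expect_error(gray_histogram(g, within = matrix(FALSE, 2, 2)),
               class = "druscan_empty_region")
})

test_that("class entropies match analytic values and the direct-sum oracle", {
  h <- two_spike(0, 255)
  expect_equal(class_entropies(h, 0, 2), c(0, 0))
  expect_equal(class_entropies(h, 0, 0.5), c(0, 0))
  expect_equal(class_entropies(h, 0, 1), c(0, 0))

  uni <- as_gray_histogram(rep(1, 256))
  for (a in c(0.5, 1, 2)) {
    expect_equal(class_entropies(uni, 127, a), c(log(128), log(128)),
                 tolerance = 1e-12)
  }

  # class with zero mass is undefined
  expect_true(is.na(class_entropies(two_spike(50, 200), 10, 2)[1]))

  withr::with_seed(77, {
    p <- numeric(256); p[1:16] <- stats::runif(16); p <- p / sum(p)
    h16 <- as_gray_histogram(p)
    for (t in c(0, 3, 9, 14)) {
      mine <- class_entropies(h16, t, 0.5)
      q1 <- p[1:(t + 1)] / sum(p[1:(t + 1)])
      q2 <- p[(t + 2):256]; q2 <- q2[q2 > 0] / sum(q2)
      direct <- c(log(sum(q1^0.5)) / 0.5, log(sum(q2^0.5)) / 0.5)
      expect_equal(mine, direct, tolerance = 1e-10)
    }
  })
})

test_that("component thresholds equal the exhaustive argmax oracle", {
  for (s in 1:6) {
    p <- random_histogram(s)
    h <- as_gray_histogram(p)
    for (a in c(0.5, 1, 2)) {
      expect_identical(component_threshold(h, a),
                       oracle_component_threshold(p, a))
    }
  }
})

test_that("degenerate and tied histograms follow the stated conventions", {
  single <- numeric(256); single[100] <- 1
  expect_error(component_threshold(as_gray_histogram(single), 2),
               class = "druscan_degenerate_histogram")
  # two spikes leave every cut between them equally good; smallest t wins
  for (a in c(0.5, 1, 2)) {
    expect_identical(component_threshold(two_spike(), a), 50L)
  }
  expect_identical(otsu_threshold(two_spike()), 50L)
})

test_that("a bimodal mixture is cut between its modes in all alpha regimes", {
  lv <- 0:255
  p <- exp(-(lv - 60)^2 / (2 * 100)) + exp(-(lv - 180)^2 / (2 * 100))
  p[abs(lv - 60) > 30 & abs(lv - 180) > 30] <- 0  # truncate at 3 sigma
  h <- as_gray_histogram(p)
  for (a in c(0.5, 1, 2)) {
    t <- component_threshold(h, a)
    expect_gt(t, 80); expect_lt(t, 160)
  }
  t_otsu <- otsu_threshold(h)
  expect_gt(t_otsu, 80); expect_lt(t_otsu, 160)
})

test_that("the alpha -> 1 path agrees with near-unity orders", {
  for (s in 1:5) {
    h <- as_gray_histogram(random_histogram(s))
    t1 <- component_threshold(h, 1)
    expect_lte(abs(component_threshold(h, 1 - 1e-6) - t1), 1)
    expect_lte(abs(component_threshold(h, 1 + 1e-6) - t1), 1)
  }
})

test_that("thresholds are invariant to histogram scaling", {
  p <- random_histogram(123)
  h1 <- as_gray_histogram(p)
  h2 <- as_gray_histogram(p * 1e6)
  for (a in c(0.5, 1, 2)) {
    expect_identical(component_threshold(h1, a), component_threshold(h2, a))
  }
  expect_identical(otsu_threshold(h1), otsu_threshold(h2))
})

test_that("cut-point mass conservation holds at every cut", {
  p <- random_histogram(5)
  cp <- cumsum(p)
  expect_equal(cp[1:255] + (1 - cp[1:255]), rep(1, 255), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("coincident component thresholds collapse the combination to t", {
  for (pair in list(c(50L, 200L), c(10L, 30L), c(100L, 240L))) {
    h <- two_spike(pair[1], pair[2])
    res <- renyi_threshold(h)
    expect_identical(unique(res$t_sorted), pair[1])
    expect_identical(res$t_c, pair[1])
    expect_equal(res$omega, 0)
    expect_equal(res$beta, c(1, 2, 1))
  }
})

test_that("the spacing table selects the printed beta triples", {
  p <- random_histogram(42)
  h <- as_gray_histogram(p)
  cases <- list(
    list(comps = c(100, 103, 104), beta = c(1, 2, 1)),  # both spacings <= 5
    list(comps = c(100, 110, 120), beta = c(1, 2, 1)),  # both > 5
    list(comps = c(100, 103, 120), beta = c(0, 1, 3)),  # upper spacing > 5
    list(comps = c(100, 110, 112), beta = c(3, 1, 0))   # lower spacing > 5
  )
  for (cs in cases) {
    res <- druscan:::combine_renyi_components(h, cs$comps, c(0.5, 1, 2))
    expect_equal(res$beta, cs$beta)
  }
})

test_that("the combined threshold matches an independent transcription", {
  for (s in 1:10) {
    p <- random_histogram(s + 100)
    h <- as_gray_histogram(p)
    comps <- vapply(c(0.5, 1, 2), function(a) oracle_component_threshold(p, a),
                    integer(1))
    res <- renyi_threshold(h)
    expect_identical(unname(res$t_components), comps)
    oracle <- oracle_combined_threshold(p, comps)
    expect_equal(res$beta, oracle$beta)
    expect_equal(res$omega, oracle$omega, tolerance = 1e-12)
    expect_identical(res$t_c, as.integer(oracle$t_c))
    # the blend is convex: t_c stays within the component range
    expect_gte(res$t_c, res$t_sorted[1])
    expect_lte(res$t_c, res$t_sorted[3])
  }
})

test_that("otsu agrees with the brute-force variance oracle", {
  for (s in 1:6) {
    p <- random_histogram(s + 50)
    expect_identical(otsu_threshold(as_gray_histogram(p)), oracle_otsu(p))
  }
})

test_that("apply_threshold masks by level and region", {
  g <- matrix(c(10L, 100L, 200L, 250L), 2, 2)
  expect_false(any(apply_threshold(g, 255)))
  within <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  expect_identical(apply_threshold(g, 0, within), within & g > 0)
  expect_identical(apply_threshold(g, 150, within),
                   matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
})
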