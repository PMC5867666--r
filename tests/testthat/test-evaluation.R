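# 2 x 5 toy scene used by the hand-counted confusion examples: a 10-pixel
# ROI, 4 true positives, prediction hits 3 of them plus 1 background pixel.
toy_masks <- function() {
  roi <- matrix(TRUE, 2, 5)
  truth <- matrix(FALSE, 2, 5); truth[1, 1:4] <- TRUE
  pred <- matrix(FALSE, 2, 5); pred[1, 1:3] <- TRUE; pred[2, 5] <- TRUE
  list(roi = roi, truth = truth, pred = pred)
}

test_that("pixelwise confusion counts match hand counts", {
  m <- toy_masks()
  cc <- confusion_pixelwise(m$pred, m$truth, m$roi)
  expect_identical(cc$tp, 3L); expect_identical(cc$fp, 1L)
  expect_identical(cc$tn, 5L); expect_identical(cc$fn, 1L)

  ident <- confusion_pixelwise(m$truth, m$truth, m$roi)
  expect_identical(ident$tp, 4L); expect_identical(ident$fp, 0L)
  expect_identical(ident$tn, 6L); expect_identical(ident$fn, 0L)

  none <- confusion_pixelwise(matrix(FALSE, 2, 5), m$truth, m$roi)
  expect_identical(none$tp, 0L); expect_identical(none$fp, 0L)
  expect_identical(none$fn, 4L)
})

test_that("pixel counts always partition the ROI", {
  withr::with_seed(8, {
    for (i in 1:5) {
      pred <- matrix(stats::runif(300) < 0.3, 15, 20)
      truth <- matrix(stats::runif(300) < 0.2, 15, 20)
      roi <- matrix(stats::runif(300) < 0.7, 15, 20)
      if (!any(roi)) next
      cc <- confusion_pixelwise(pred, truth, roi)
      expect_identical(cc$tp + cc$fp + cc$tn + cc$fn, sum(roi))
    }
  })
})

test_that("regionwise counting follows the any-overlap rule", {
  roi <- matrix(TRUE, 10, 10)
  truth <- matrix(FALSE, 10, 10)
  truth[2:3, 2:3] <- TRUE; truth[2:3, 7:8] <- TRUE; truth[8:9, 2:3] <- TRUE

  ident <- confusion_regionwise(truth, truth, roi)
  expect_identical(ident$tp, 3L); expect_identical(ident$fp, 0L)
  expect_identical(ident$fn, 0L); expect_true(is.na(ident$tn))

  pred <- matrix(FALSE, 10, 10)
  pred[2, 2] <- TRUE          # clips lesion 1
  pred[3, 7] <- TRUE          # clips lesion 2
  pred[8:9, 7:8] <- TRUE      # spurious
  cc <- confusion_regionwise(pred, truth, roi)
  expect_identical(cc$tp, 2L); expect_identical(cc$fn, 1L)
  expect_identical(cc$fp, 1L)

  none <- confusion_regionwise(matrix(FALSE, 10, 10), truth, roi)
  expect_identical(none$tp, 0L); expect_identical(none$fn, 3L)
  expect_identical(none$fp, 0L)
})

test_that("a stricter overlap fraction demotes clipped detections", {
  roi <- matrix(TRUE, 10, 10)
  truth <- matrix(FALSE, 10, 10); truth[2:5, 2:5] <- TRUE  # 16 px
  pred <- matrix(FALSE, 10, 10); pred[2, 2] <- TRUE        # 1/16 overlap
  loose <- confusion_regionwise(pred, truth, roi)
  strict <- confusion_regionwise(pred, truth, roi, min_overlap_fraction = 0.5)
  expect_identical(loose$tp, 1L)
  expect_identical(strict$tp, 0L)
  expect_identical(strict$fn, 1L)
})

test_that("conditional probabilities reproduce the worked arithmetic", {
  m <- toy_masks()
  cp <- conditional_probabilities(confusion_pixelwise(m$pred, m$truth, m$roi))
  expect_equal(cp$sensitivity, 75)
  expect_equal(cp$specificity, 100 * 5 / 6, tolerance = 1e-12)
  expect_equal(cp$accuracy, 80)
  expect_equal(cp$dsc, 0.75)

  perfect <- conditional_probabilities(
    confusion_pixelwise(m$truth, m$truth, m$roi))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$dsc, 1)

  reg <- structure(list(tp = 2L, fp = 1L, tn = NA_integer_, fn = 1L,
                        mode = "region"), class = "confusion_counts")
  rp <- conditional_probabilities(reg)
  expect_equal(rp$sensitivity, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(rp$dsc, 2 / 3, tolerance = 1e-12)
  expect_true(is.na(rp$specificity))
  expect_true(is.na(rp$accuracy))
})

test_that("zero denominators yield undefined metrics, not zeros", {
  empty <- structure(list(tp = 0L, fp = 0L, tn = 10L, fn = 0L, mode = "pixel"),
                     class = "confusion_counts")
  cp <- conditional_probabilities(empty)
  expect_true(is.na(cp$sensitivity))
  expect_equal(cp$specificity, 100)
})

test_that("agreement statistics handle exact and anti-correlated inputs", {
  a <- c(120, 340, 560, 210, 980)
  st <- agreement_stats(a, a)
  expect_equal(st$pearson_r, 1)
  expect_equal(st$icc$estimate, 1)
  expect_equal(st$bland_altman$mean_diff, 0)

  st2 <- agreement_stats(c(1, 2, 3), c(3, 2, 1))
  expect_equal(st2$pearson_r, -1)

  expect_error(agreement_stats(c(5, 5, 5), c(1, 2, 3)),
               class = "druscan_degenerate_data")
  expect_error(agreement_stats(c(1, 2), c(1, 2)),
               class = "druscan_invalid_parameter")
})

test_that("the ICC matches an independent variance-components oracle", {
  withr::with_seed(2024, {
    manual <- stats::runif(30, 200, 2000)
    auto <- manual + stats::rnorm(30, 0, 0.05 * mean(manual))
  })
  st <- agreement_stats(manual, auto)
  expect_equal(st$icc$estimate, oracle_icc_a1(manual, auto), tolerance = 1e-6)
  expect_lte(st$icc$lower, st$icc$estimate)
  expect_gte(st$icc$upper, st$icc$estimate)
})

test_that("Bland-Altman limits bracket most Gaussian differences", {
  for (s in 1:5) {
    withr::with_seed(s, {
      manual <- stats::runif(30, 500, 1500)
      auto <- manual + stats::rnorm(30, 10, 40)
    })
    st <- agreement_stats(manual, auto)
    expect_gte(st$bland_altman$fraction_within, 0.9)
    expect_equal(st$bland_altman$upper - st$bland_altman$lower,
                 2 * 1.96 * stats::sd(auto - manual), tolerance = 1e-12)
  }
})

test_that("region-level sensitivity is at least pixel-level on phantoms", {
  b <- generate_phantom(phantom_spec(seed = 13))
  res <- segment_drusen(b)
  sc <- phantom_scores(b, res)
  expect_gte(sc$region$sensitivity, sc$pixel$sensitivity)
})
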