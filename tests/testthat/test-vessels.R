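test_that("the vessel seed lands on a planted vessel", {
  b <- generate_phantom(phantom_spec(seed = 5))
  disc <- detect_optic_disc(b$green)
  seed <- select_vessel_seed(b$green, disc)
  expect_true(b$vessel_mask[seed[1], seed[2]])
})

test_that("seed ties resolve to the first annulus pixel in row-major order", {
  g <- matrix(100L, 60, 60)
  rows <- matrix(seq_len(60), 60, 60)
  cols <- matrix(seq_len(60), 60, 60, byrow = TRUE)
  g[(rows - 30)^2 + (cols - 30)^2 <= 100] <- 230L
  disc <- detect_optic_disc(g)
  seed <- select_vessel_seed(g, disc)
  # uniform annulus: expected winner is its topmost, then leftmost pixel
  ann <- druscan:::annulus_indices(disc, 60, 60)
  idx <- which(ann & g == 100L, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), ]
  expect_identical(seed, as.integer(idx[1, ]))
})

test_that("a disc engulfing the image leaves no annulus", {
  # equivalent disc radius far beyond the image bounds -> empty annulus
  g <- matrix(230L, 5, 5)
  disc <- structure(list(centroid = c(3L, 3L), pixel_count = 10000L,
                         mask = matrix(TRUE, 5, 5), side = "left"),
                    class = "optic_disc")
  expect_error(select_vessel_seed(g, disc), class = "druscan_invalid_geometry")
  expect_error(select_vessel_seeds(g, disc), class = "druscan_invalid_geometry")
})

test_that("region growing honours the tolerance and contains its seed", {
  g <- matrix(60L, 10, 10)
  g[5, 6] <- 75L
  reg <- region_grow(g, c(5, 5), tolerance = 10, connectivity = 8,
                     max_region_fraction = 1)
  expect_true(reg[5, 5])
  expect_false(reg[5, 6])  # |75 - 60| > 10

  all_reg <- region_grow(matrix(7L, 12, 12), c(3, 3), tolerance = 0,
                         max_region_fraction = 1)
  expect_true(all(all_reg))
})

test_that("region growing is monotone in tolerance", {
  withr::with_seed(21, {
    g <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
    storage.mode(g) <- "integer"
    prev <- NULL
    for (tol in c(10, 40, 90)) {
      reg <- region_grow(g, c(20, 20), tol, max_region_fraction = 1)
      if (!is.null(prev)) expect_true(all(reg[prev]))
      prev <- reg
    }
  })
})

test_that("overflowing growth raises a classed error carrying the fraction", {
  g <- matrix(100L, 20, 20)
  err <- tryCatch(
    region_grow(g, c(10, 10), tolerance = 5, max_region_fraction = 0.1),
    druscan_region_overflow = function(e) e)
  expect_s3_class(err, "druscan_region_overflow")
  expect_gt(err$fraction, 0.1)
})

test_that("region growing equals the brute-force flood oracle", {
  withr::with_seed(314, {
    for (i in 1:4) {
      g <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
      storage.mode(g) <- "integer"
      seed <- c(sample(64, 1), sample(64, 1))
      for (conn in c(4, 8)) {
        mine <- region_grow(g, seed, tolerance = 60, connectivity = conn,
                            max_region_fraction = 1)
        expect_identical(mine, oracle_region_grow(g, seed, 60, conn))
      }
    }
  })
})

test_that("grown vessels cover the planted tree and avoid background", {
  b <- generate_phantom(phantom_spec(seed = 9))
  disc <- detect_optic_disc(b$green)
  seeds <- select_vessel_seeds(b$green, disc)
  expect_gt(nrow(seeds), 0)
  vm <- matrix(FALSE, nrow(b$green), ncol(b$green))
  for (i in seq_len(nrow(seeds))) {
    g <- tryCatch(region_grow(b$green, seeds[i, ]),
                  druscan_region_overflow = function(e) NULL)
    if (!is.null(g)) vm <- vm | g
  }
  expect_gte(sum(vm & b$vessel_mask) / sum(b$vessel_mask), 0.8)
  expect_lt(sum(vm & !b$vessel_mask) / sum(!b$vessel_mask), 0.01)
})

test_that("the non-drusen mask dilates the vessel/disc union", {
  empty <- matrix(FALSE, 5, 5)
  expect_identical(nondrusen_mask(empty, empty, 2), empty)

  single <- empty; single[3, 3] <- TRUE
  out <- nondrusen_mask(single, empty, 1)
  expect_identical(which(out), which(matrix(seq_len(25), 5, 5) %in%
                                       c(7:9, 12:14, 17:19)))
  expect_identical(sum(out), 9L)
})
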