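test_that("roi_stats matches a hand calculation on a toy region", {
  v <- matrix(1, 5, 5)
  v[2:4, 2:4] <- matrix(c(0.1, 0.2, 0.4, 0.2, 0.25, 0.5, 0.4, 0.5, 0.8),
                        3, 3)
  sc <- scene_luminance(v)
  mask <- matrix(FALSE, 5, 5); mask[2:4, 2:4] <- TRUE
  st <- roi_stats(sc, mask, log_range(2), roi_name = "toy", erode = 0L)
  vals <- c(0.1, 0.2, 0.4, 0.2, 0.25, 0.5, 0.4, 0.5, 0.8)
  expect_identical(st$pixels, 9L)
  expect_equal(st$log10_min, log10(0.1))
  expect_equal(st$log10_max, log10(0.8))
  expect_equal(st$log10_mean, mean(log10(vals)))
  expect_equal(st$pct_min, 100 * (1 + log10(0.1) / 2))
  expect_equal(st$pct_mean, mean(100 * (1 + log10(vals) / 2)))
  # a uniform region collapses to min = mean = max
  u <- roi_stats(sc, matrix(c(TRUE, rep(FALSE, 24)), 5, 5), erode = 0L)
  expect_identical(u$log10_min, u$log10_max)
  expect_identical(u$log10_min, u$log10_mean)
  expect_error(roi_stats(sc, matrix(FALSE, 5, 5)), "empty")
  expect_error(roi_stats(sc, matrix(TRUE, 4, 4)), "shape")
})

test_that("mask erosion strips the declared number of border pixels", {
  m <- matrix(FALSE, 9, 9)
  m[3:7, 2:8] <- TRUE
  e1 <- erode_mask(m, 1L)
  expect_identical(which(e1, arr.ind = TRUE),
                   which(matrix(FALSE, 9, 9) | {
                     z <- matrix(FALSE, 9, 9); z[4:6, 3:7] <- TRUE; z
                   }, arr.ind = TRUE))
  e2 <- erode_mask(m, 2L)
  expect_identical(sum(e2), 3L)   # single row 5, cols 4:6
  expect_true(all(which(e2) %in% which(m)))
})

test_that("image_range reports the occupied fraction of the reference range", {
  b <- make_contrast_assimilation("A", 512)
  sc <- bundle_scene(b)
  expect_identical(image_range(sc), 100)   # the scene spans its full range
  v <- matrix(c(1, 10^-1.15), 1)
  expect_equal(image_range(scene_luminance(v)), 50, tolerance = 1e-9)
})

test_that("histograms use 256 bins, peak-normalize, and match a tally oracle", {
  b <- make_centered_square(257L, 75L)
  sc <- bundle_scene(b)
  h <- glare_histogram(sc, "log")
  expect_identical(length(h$counts), 256L)
  expect_identical(sum(h$counts > 0), 2L)      # a two-level image
  expect_identical(max(h$normalized), 1)
  # tally oracle on a small random image
  set.seed(13)
  v <- matrix(10^runif(64, -2, 0), 8, 8)
  sc2 <- scene_luminance(v)
  h2 <- glare_histogram(sc2, "linear")
  oracle <- table(cut(as.vector(sc2$values), h2$breaks,
                      include.lowest = TRUE))
  expect_identical(h2$counts, as.integer(oracle))
  expect_identical(sum(h2$counts), 64L)
})

test_that("scan profiles index the arrays directly and show range compression", {
  b <- make_todorovic(c(512L, 1024L))
  sc <- bundle_scene(b)
  rc <- convolve_glare(sc, build_kernel(b$geometry, cache = FALSE))
  row <- b$scan_rows[["circles"]]
  sp <- scan_profile(sc, rc, row)
  expect_identical(nrow(sp), 1024L)
  expect_identical(sp$scene_log10, log10(sc$values[row, ] / max(sc$values)))
  expect_identical(sp$retina_log10, log10(rc$values[row, ] / max(rc$values)))
  # the scene profile is piecewise-constant at the set levels
  expect_lte(length(unique(sp$scene_log10)), 4L)
  # glare compresses the span along the scan
  expect_lt(diff(range(sp$retina_log10)), diff(range(sp$scene_log10)))
  expect_error(scan_profile(sc, rc, 0), "out of bounds")
})

test_that("paradox reports follow the declared ordering and the mean comparison", {
  b <- make_contrast_assimilation("C", 512)
  sc <- bundle_scene(b)
  # scene as input: equal means, so no pair can show a paradox
  fake <- structure(list(values = sc$values), class = "retinal_contrast")
  pr0 <- paradox_report(fake, b)
  expect_false(any(pr0$paradox))
  # missing ROI is an error
  b2 <- b
  b2$appearance_order$darker[1] <- "nope"
  expect_error(paradox_report(fake, b2), "missing")
  expect_error(paradox_report(fake, make_centered_square(257L, 75L)),
               "no appearance ordering")
})
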