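test_that("contrast+assimilation variants honor the printed area fractions", {
  for (v in c("A", "B")) {
    b <- make_contrast_assimilation(v, 512)
    fr <- b$metadata$area_fractions
    expect_lt(abs(fr[["white"]] - 0.57), 0.01)
    expect_lt(abs(fr[["black"]] - 0.29), 0.01)
    expect_lt(abs(fr[["gray"]] - 0.14), 0.01)
  }
  for (v in c("C", "D")) {
    b <- make_contrast_assimilation(v, 512)
    fr <- b$metadata$area_fractions
    expect_lt(abs(fr[["white"]] - 0.29), 0.01)
    expect_lt(abs(fr[["black"]] - 0.57), 0.01)
    expect_lt(abs(fr[["gray"]] - 0.14), 0.01)
  }
  expect_error(make_contrast_assimilation("A", 400), ">= 512")
})

test_that("gray ROIs share one digit and identical locations across variants", {
  bundles <- lapply(c("A", "B", "C", "D"), make_contrast_assimilation, 512)
  roi_names <- c("contrast_gray_in_white", "contrast_gray_in_black",
                 "assim_gray_in_white", "assim_gray_in_black")
  for (b in bundles) {
    for (nm in roi_names) {
      digs <- unique(b$map$digits[b$rois[[nm]]])
      expect_identical(digs, 145L)
    }
    # disjoint ROI pairs
    expect_false(any(b$rois$contrast_gray_in_white &
                       b$rois$contrast_gray_in_black))
  }
  for (nm in roi_names)
    for (b in bundles[-1])
      expect_identical(b$rois[[nm]], bundles[[1]]$rois[[nm]])
})

test_that("generators are deterministic", {
  expect_identical(make_contrast_assimilation("B", 512),
                   make_contrast_assimilation("B", 512))
  expect_identical(make_mondrian(seed = 4, size = 512),
                   make_mondrian(seed = 4, size = 512))
  expect_false(identical(make_mondrian(seed = 4, size = 512)$map$digits,
                         make_mondrian(seed = 5, size = 512)$map$digits))
})

test_that("the Todorovic target has stated cross geometry and equal grays", {
  b <- make_todorovic(c(512L, 1024L))
  s <- 512 / 2048
  # control cross bounding box matches the scaled 380 x 25 arms
  m <- b$rois$cross_control_1
  rows <- range(which(rowSums(m) > 0)); cols <- range(which(colSums(m) > 0))
  expect_identical(diff(rows) + 1L, as.integer(round(380 * s)))
  expect_identical(diff(cols) + 1L, as.integer(round(380 * s)))
  # rows crossed only by the vertical arm count one arm width of pixels
  arm_rows <- rowSums(m)[rowSums(m) > 0]
  expect_identical(sum(arm_rows == as.integer(round(25 * s))),
                   as.integer(round(380 * s) - round(25 * s)))
  # all eight gray elements share the gray digit
  for (nm in names(b$rois))
    expect_identical(unique(b$map$digits[b$rois[[nm]]]), 145L)
  # four scene luminances only
  expect_identical(sort(unique(as.vector(b$map$digits))),
                   c(21L, 145L, 200L, 255L))
  # scan rows pass through the element centers; left-half control profiles
  # take only the set digit levels
  sc <- bundle_scene(b)
  left <- sc$values[b$scan_rows["circles"], 1:512]
  cal_lut <- stats::approx(b$calibration$digits, b$calibration$cd_per_m2,
                           xout = c(145, 200))$y / 450
  expect_true(all(left %in% c(cal_lut, 1, 2.24 / 450)))
  expect_error(make_todorovic(c(128L, 256L)), "cross dimensions")
})

test_that("the centered-square fixture is a two-level map with a 1-px ring", {
  b <- make_centered_square(513L, 151L)
  expect_identical(sort(unique(as.vector(b$map$digits))), c(21L, 255L))
  expect_equal(mean(b$rois$square), (151 / 513)^2, tolerance = 1e-6)
  ring <- b$rois$boundary_ring
  expect_identical(sum(ring), 4L * 151L - 4L)
  expect_true(all(b$map$digits[ring] == 255L))
  expect_error(make_centered_square(512L, 151L), "odd")
  expect_error(make_centered_square(513L, 515L), "smaller")
})

test_that("Mondrian circles are equal-luminance at 80% of the log range", {
  b <- make_mondrian(seed = 3, size = 512)
  sc <- bundle_scene(b)
  top <- sc$values[b$rois$circle_top]
  bot <- sc$values[b$rois$circle_bottom]
  expect_lt(max(abs(top - bot[1])) / bot[1], 1e-9)
  pct <- percent_of_range(top[1], max(sc$values), log_range(2.3))
  expect_lt(abs(pct - 80), 1)
  expect_gte(min(b$map$digits), 10L)
  expect_identical(max(b$map$digits), 235L)
})

test_that("inversion is an involution that preserves ROI equality", {
  b <- make_mondrian(seed = 2, size = 512)
  n <- invert_target(b)
  expect_identical(invert_target(n)$map$digits, b$map$digits)
  expect_null(n$appearance_order)
  # white endpoint maps to zero
  cs <- make_centered_square(257L, 75L)
  expect_identical(unique(invert_target(cs)$map$digits[cs$rois$square]), 0L)
  # equal-digit circles stay equal in scene luminance after inversion
  sn <- bundle_scene(n)
  expect_lt(max(abs(sn$values[n$rois$circle_top] -
                      sn$values[n$rois$circle_bottom][1])), 1e-12)
})

test_that("equal scene luminances become unequal retinal contrasts", {
  b <- make_contrast_assimilation("A", 512)
  sc <- bundle_scene(b)
  rc <- convolve_glare(sc, small_kernel())
  pair <- c("contrast_gray_in_white", "contrast_gray_in_black")
  expect_identical(mean(sc$values[b$rois[[pair[1]]]]),
                   mean(sc$values[b$rois[[pair[2]]]]))
  expect_false(mean(rc$values[b$rois[[pair[1]]]]) ==
                 mean(rc$values[b$rois[[pair[2]]]]))
})

test_that("target bundles export map, calibration, masks and metadata", {
  b <- make_centered_square(257L, 75L)
  d <- file.path(tempdir(), "cs_target")
  write_target(b, d)
  expect_identical(load_digit_map(file.path(d, "map.tif"))$digits,
                   b$map$digits)
  expect_identical(read_calibration_csv(file.path(d, "calibration.csv"))$digits,
                   b$calibration$digits)
  meta <- jsonlite::read_json(file.path(d, "metadata.json"))
  expect_identical(meta$variant, "centered_square")
  expect_true(file.exists(file.path(d, "roi_boundary_ring.png")))
})
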