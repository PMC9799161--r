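test_that("digit maps round-trip through TIFF and PNG bit-identically", {
  set.seed(42)
  m <- matrix(sample(0:255, 64 * 48, replace = TRUE), 64, 48)
  dm <- digit_map(m)
  for (ext in c(".tif", ".png")) {
    f <- tempfile(fileext = ext)
    write_digit_map(dm, f)
    back <- load_digit_map(f)
    expect_identical(back$digits, dm$digits)
  }
})

test_that("multi-channel and missing inputs are rejected", {
  f <- tempfile(fileext = ".png")
  png::writePNG(array(runif(16 * 16 * 3), c(16, 16, 3)), f)   # RGB
  expect_error(load_digit_map(f), "multi-channel")
  f2 <- tempfile(fileext = ".tif")
  tiff::writeTIFF(array(runif(16 * 16 * 3), c(16, 16, 3)), f2,
                  bits.per.sample = 8L)
  expect_error(load_digit_map(f2), "multi-channel")
  expect_error(load_digit_map(tempfile(fileext = ".png")), "no such file")
  expect_error(digit_map(matrix(300L, 2, 2)), "0, 255")
})

test_that("the three-point display table yields the 200:1 (2.3 log) range", {
  cal <- display_calibration(c(21, 145, 255), c(2.24, 136, 450))
  dm <- digit_map(matrix(c(255L, 145L, 21L), 1, 3))
  sc <- apply_calibration(dm, cal)
  expect_identical(sc$values[1, 1], 1)
  expect_equal(sc$values[1, 3], 2.24 / 450, tolerance = 1e-12)
  expect_equal(sc$max_cd_m2, 450)
  expect_equal(max(sc$values) / min(sc$values), 200, tolerance = 0.01)
  expect_equal(log10(max(sc$values) / min(sc$values)), 2.3, tolerance = 0.01)
})

test_that("a flat field stays flat and maps to 1", {
  cal <- display_calibration(c(0, 255), c(0.001, 255))
  sc <- apply_calibration(digit_map(matrix(128L, 8, 8)), cal)
  expect_true(all(sc$values == 1))
})

test_that("calibration interpolation agrees with a pointwise oracle", {
  cal <- display_calibration(c(10, 60, 130, 200, 250),
                             c(1.5, 22, 80, 310, 440))
  digits <- matrix(as.integer(seq(10, 250, length.out = 120)), 12, 10)
  sc <- apply_calibration(digit_map(digits), cal)
  oracle <- vapply(as.vector(digits), function(d)
    stats::approx(cal$digits, cal$cd_per_m2, xout = d)$y, numeric(1))
  expect_equal(as.vector(sc$values), oracle / max(oracle), tolerance = 1e-12)
})

test_that("calibrated luminance is monotone in digit value", {
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    cal <- display_calibration(sort(sample(0:255, n)),
                               sort(runif(n, 0.5, 500)))
    d <- sort(sample(cal$digits[1]:cal$digits[n], 20, replace = TRUE))
    sc <- apply_calibration(digit_map(matrix(as.integer(d), 1)), cal)
    expect_true(all(diff(sc$values[1, ]) >= 0))
  }
})

test_that("digits outside the calibrated span clamp below and error above", {
  cal <- display_calibration(c(21, 255), c(2.24, 450))
  expect_warning(sc <- apply_calibration(digit_map(matrix(c(5L, 255L), 1)),
                                         cal),
                 "clamped")
  expect_equal(sc$values[1, 1], 2.24 / 450, tolerance = 1e-12)
  cal2 <- display_calibration(c(21, 200), c(2.24, 300))
  expect_error(apply_calibration(digit_map(matrix(c(21L, 255L), 1)), cal2),
               "above calibrated span")
})

test_that("invalid calibrations are rejected", {
  expect_error(display_calibration(c(10, 10), c(1, 2)), "strictly increase")
  expect_error(display_calibration(c(10, 20), c(2, 1)), "monotone")
  expect_error(display_calibration(c(10, 20), c(-1, 2)), "> 0")
  expect_error(display_calibration(300, 5), "pairs")
})

test_that("calibration CSV round-trips", {
  cal <- default_calibration()
  f <- tempfile(fileext = ".csv")
  write_calibration_csv(cal, f)
  back <- read_calibration_csv(f)
  expect_identical(back$digits, cal$digits)
  expect_equal(back$cd_per_m2, cal$cd_per_m2)
  expect_error(read_calibration_csv({
    f2 <- tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1, b = 2), f2, row.names = FALSE)
    f2
  }), "columns")
})
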