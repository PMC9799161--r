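test_that("the cmap table has 64 four-digit bands anchored at the gray green", {
  lut <- lut_cmap()
  expect_identical(nrow(lut$entries), 256L)
  # the printed anchor: digits 194-197 share the green triplet [192, 255, 64]
  for (d in 194:197)
    expect_identical(unname(lut$entries[d + 1L, ]), c(192L, 255L, 64L))
  expect_false(identical(unname(lut$entries[194L, ]), c(192L, 255L, 64L)))
  expect_false(identical(unname(lut$entries[199L, ]), c(192L, 255L, 64L)))
  # band partition: exactly 64 contiguous constant-color runs; every
  # interior run covers 4 consecutive digits
  key <- apply(lut$entries, 1, paste, collapse = ",")
  runs <- rle(key)
  expect_identical(length(runs$lengths), 64L)
  expect_true(all(runs$lengths[2:63] == 4L))
  expect_identical(sum(runs$lengths), 256L)
})

test_that("the 3-3-2 table runs from black to its maximal yellow", {
  lut <- lut_332()
  expect_identical(unname(lut$entries[1, ]), c(0L, 0L, 0L))        # entry 0
  expect_identical(unname(lut$entries[256, ]), c(224L, 224L, 192L)) # entry 255
  expect_identical(max(lut$entries[, "b"]), 192L)
  expect_identical(max(lut$entries[, "r"]), 224L)
  # entry 255 maximizes every channel simultaneously
  expect_true(all(lut$entries[, "r"] <= 224L & lut$entries[, "g"] <= 224L))
})

test_that("apply_lut is a pure per-pixel lookup", {
  lut <- lut_cmap()
  d <- matrix(c(0L, 64L, 197L, 255L), 2, 2)
  rgb <- apply_lut(digit_map(d), lut)
  expect_identical(dim(rgb), c(2L, 2L, 3L))
  expect_identical(rgb[1, 2, ], unname(lut$entries[198L, ]))
  expect_identical(rgb[2, 2, ], unname(lut$entries[256L, ]))
  # constant image -> constant RGB
  cons <- apply_lut(digit_map(matrix(130L, 4, 4)), lut)
  expect_identical(length(unique(as.vector(cons[, , 1]))), 1L)
  # permutation equivariance under pixel shuffles
  set.seed(2)
  m <- matrix(sample(0:255, 36, replace = TRUE), 6, 6)
  p <- sample(36)
  shuffled <- matrix(m[p], 6, 6)
  a <- apply_lut(digit_map(m), lut)
  b <- apply_lut(digit_map(shuffled), lut)
  for (ch in 1:3)
    expect_identical(as.vector(b[, , ch]), as.vector(a[, , ch])[p])
  expect_error(pseudocolor_lut("bad", matrix(0L, 12, 3)), "256")
})

test_that("the color bar exposes all 256 entries with log-luminance ticks", {
  cb <- make_colorbar(lut_cmap(), log_range(2.3))
  expect_identical(dim(cb$bar), c(256L, 32L, 3L))
  expect_identical(cb$bar[1, 1, ], unname(lut_cmap()$entries[256, ]))  # top = max
  expect_identical(cb$ticks$log10[1], 0)
  expect_identical(cb$ticks$log10[nrow(cb$ticks)], -2.3)
})

test_that("superposition composites quadrants in caption order and paints the mask red", {
  mk <- function(col3) {
    a <- array(0L, c(8L, 8L, 3L))
    for (ch in 1:3) a[, , ch] <- col3[ch]
    a
  }
  imgs <- list(mk(c(10L, 0L, 0L)), mk(c(0L, 20L, 0L)),
               mk(c(0L, 0L, 30L)), mk(c(40L, 40L, 0L)))
  out <- superposition(imgs)
  expect_identical(out[1, 1, ], c(10L, 0L, 0L))      # top-left from 1
  expect_identical(out[1, 8, ], c(0L, 20L, 0L))      # top-right from 2
  expect_identical(out[8, 8, ], c(0L, 0L, 30L))      # bottom-right from 3
  expect_identical(out[8, 1, ], c(40L, 40L, 0L))     # bottom-left from 4
  # identity: four copies of one image reproduce it
  same <- superposition(rep(imgs[1], 4))
  expect_identical(same, imgs[[1]])
  # mask passthrough: red exactly at the masked pixels
  mask <- matrix(FALSE, 8, 8); mask[3, 5] <- TRUE
  red <- superposition(imgs, mask)
  expect_identical(red[3, 5, ], c(255L, 0L, 0L))
  expect_identical(red[3, 4, ], out[3, 4, ])
  expect_error(superposition(c(imgs[1:3], list(mk(c(1L, 1L, 1L))[1:7, , ,
                                                                 drop = FALSE]))),
               "share one shape")
})

test_that("LUT CSV round-trips exactly", {
  lut <- lut_cmap()
  f <- tempfile(fileext = ".csv")
  lut_to_csv(lut, f)
  back <- lut_from_csv(f)
  expect_identical(back$entries, lut$entries)
})
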