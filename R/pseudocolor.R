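#' Pseudocolor look-up tables
#'
#' A pseudocolor LUT maps each of the 256 analysis digits to an RGB triplet
#' so that sub-threshold luminance gradients become discriminable color
#' bands. Two tables are provided:
#'
#' \itemize{
#'   \item \code{lut_cmap()}: 64 color bands (8 hue progressions of 8 steps),
#'     each band covering 4 consecutive digits, running from black at digit 0
#'     to white at digit 255 so the sense of lightness order is preserved.
#'     The band covering digits 194-197 is the green triplet
#'     \code{[192, 255, 64]} used to trace gray patches.
#'   \item \code{lut_332()}: the 3-3-2 bit-partition table (red = top 3 bits,
#'     green = next 3, blue = low 2 bits, each left-shifted into an 8-bit
#'     channel, so blue peaks at 192 and entry 255 is a yellow). It cycles
#'     rapidly through colors, which emphasizes gradient visibility at the
#'     cost of lightness order.
#' }
#'
#' @param name Identifier for the table.
#' @param entries 256 x 3 matrix of integers in [0, 255].
#' @return An object of class \code{"pseudocolor_lut"}.
#' @export
pseudocolor_lut <- function(name, entries) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  if (nrow(entries) != 256L || ncol(entries) != 3L)
    stop("a pseudocolor LUT needs exactly 256 RGB entries, got ",
         nrow(entries))
  if (anyNA(entries) || any(entries < 0L) || any(entries > 255L))
    stop("LUT entries must be integers in [0, 255]")
  dimnames(entries) <- list(NULL, c("r", "g", "b"))
  structure(list(name = name, entries = entries), class = "pseudocolor_lut")
}

#' @export
print.pseudocolor_lut <- function(x, ...) {
  cat(sprintf("pseudocolor LUT `%s`: 256 entries, %d distinct colors\n",
              x$name, nrow(unique(x$entries))))
  invisible(x)
}

# minimal hsv -> rgb (h in degrees, s/v in [0,1]) with half-up rounding,
# kept local so LUT construction is bit-deterministic
hsv_to_rgb255 <- function(h, s, v) {
  h <- (h %% 360) / 60
  c_ <- v * s
  x <- c_ * (1 - abs(h %% 2 - 1))
  m <- v - c_
  sec <- floor(h)
  rgb1 <- switch(as.character(sec),
                 "0" = c(c_, x, 0), "1" = c(x, c_, 0), "2" = c(0, c_, x),
                 "3" = c(0, x, c_), "4" = c(x, 0, c_), c(c_, 0, x))
  as.integer(round_half_up(255 * (rgb1 + m)))
}

# digit -> cmap band index (0..63); digits 194-197 share band 49
cmap_band <- function(digit) pmin(pmax(round_half_up(digit / 4), 0), 63)

#' @rdname pseudocolor_lut
#' @export
lut_cmap <- function() {
  # anchor: band 49 (digits 194-197) must be exactly [192, 255, 64]
  hue_anchor <- 120 - 60 * 128 / 191
  sat_anchor <- 191 / 255
  gamma <- log(1 - sat_anchor) / log(49 / 63)
  band_rgb <- t(vapply(0:63, function(b) {
    p <- b %/% 8                      # hue progression
    h <- 270 + p * (hue_anchor - 270) / 6
    s <- 1 - (b / 63)^gamma           # white at the top of the range
    v <- if (b == 0) 0 else min(1, (b / 49)^0.6)
    hsv_to_rgb255(h, s, v)
  }, integer(3)))
  pseudocolor_lut("cmap", band_rgb[cmap_band(0:255) + 1L, ])
}

#' @rdname pseudocolor_lut
#' @export
lut_332 <- function() {
  i <- 0:255
  pseudocolor_lut("3-3-2RGB",
                  cbind(r = bitwShiftL(bitwShiftR(i, 5), 5),
                        g = bitwShiftL(bitwAnd(bitwShiftR(i, 2), 7L), 5),
                        b = bitwShiftL(bitwAnd(i, 3L), 6)))
}

#' Read / write a pseudocolor LUT CSV
#'
#' CSV with header \code{index,r,g,b} and 256 rows (index 0-255).
#'
#' @param path CSV path.
#' @param name Name for the loaded table (defaults to the file name).
#' @return A \code{\link{pseudocolor_lut}}.
#' @export
lut_from_csv <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  tab <- utils::read.csv(path)
  if (!all(c("index", "r", "g", "b") %in% names(tab)))
    stop("LUT CSV must have columns `index,r,g,b`: ", path)
  tab <- tab[order(tab$index), ]
  if (!identical(as.integer(tab$index), 0:255))
    stop("LUT CSV must contain indices 0..255 exactly once: ", path)
  pseudocolor_lut(name, as.matrix(tab[, c("r", "g", "b")]))
}

#' @rdname lut_from_csv
#' @param lut A \code{\link{pseudocolor_lut}}.
#' @export
lut_to_csv <- function(lut, path) {
  stopifnot(inherits(lut, "pseudocolor_lut"))
  utils::write.csv(data.frame(index = 0:255, lut$entries), path,
                   row.names = FALSE)
  invisible(path)
}

#' Apply a pseudocolor LUT to a log-mapped image
#'
#' Pure per-pixel table lookup: every analysis digit is replaced by its LUT
#' triplet.
#'
#' @param image A \code{\link{log_map}} result or \code{\link{digit_map}}.
#' @param lut A \code{\link{pseudocolor_lut}}.
#' @return An integer array (rows x cols x 3) of RGB values in [0, 255].
#' @export
apply_lut <- function(image, lut) {
  if (!inherits(lut, "pseudocolor_lut"))
    stop("`lut` must be a pseudocolor_lut")
  d <- if (inherits(image, "log_mapped_image")) image$digits
       else if (inherits(image, "digit_map")) image$digits
       else stop("`image` must be a log-mapped image or digit map")
  out <- array(lut$entries[as.vector(d) + 1L, ], dim = c(dim(d), 3L))
  storage.mode(out) <- "integer"
  out
}

#' Render a LUT color bar with log-luminance ticks
#'
#' A vertical bar showing all 256 LUT entries, top = digit 255 (log value
#' 0.0, the image maximum) down to digit 0 (log value -range). Tick
#' annotations link bar rows to log10 relative luminance.
#'
#' @param lut A \code{\link{pseudocolor_lut}}.
#' @param range A \code{\link{log_range}}.
#' @param width Bar width in pixels.
#' @return List with \code{bar} (256 x width x 3 RGB array, one row per LUT
#'   entry) and \code{ticks} (data.frame of digit, bar row and log10 value).
#' @export
make_colorbar <- function(lut, range = log_range(), width = 32L) {
  stopifnot(inherits(lut, "pseudocolor_lut"), inherits(range, "log_range"))
  digits <- 255:0                       # top row = max
  bar <- array(0L, dim = c(256L, width, 3L))
  for (ch in 1:3)
    bar[, , ch] <- matrix(lut$entries[digits + 1L, ch], 256L, width)
  tick_digits <- as.integer(round_half_up(seq(255, 0, length.out = 6L)))
  ticks <- data.frame(digit = tick_digits,
                      row = 256L - tick_digits,
                      log10 = -range$range_log10 * (255 - tick_digits) / 255)
  list(bar = bar, ticks = ticks)
}

#' Superpose four quarter-image sections with a boundary marker
#'
#' Builds the composite used to locate an input edge inside post-glare
#' gradients: the top-left quadrant is taken from the first image, top-right
#' from the second, bottom-right from the third, bottom-left from the fourth,
#' and every pixel of \code{boundary_mask} is painted pure red.
#'
#' @param quadrant_images List of four RGB arrays of identical shape.
#' @param boundary_mask Logical matrix of the same rows x cols (or NULL).
#' @return An RGB array of the shared shape.
#' @export
superposition <- function(quadrant_images, boundary_mask = NULL) {
  if (length(quadrant_images) != 4L)
    stop("`quadrant_images` must be a list of four RGB images")
  dims <- lapply(quadrant_images, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all four images must share one shape")
  d <- dims[[1]]
  if (length(d) != 3L || d[3] != 3L) stop("inputs must be RGB arrays")
  hr <- d[1] %/% 2L
  hc <- d[2] %/% 2L
  out <- quadrant_images[[1]]
  out[1:hr, (hc + 1L):d[2], ] <- quadrant_images[[2]][1:hr, (hc + 1L):d[2], ]
  out[(hr + 1L):d[1], (hc + 1L):d[2], ] <-
    quadrant_images[[3]][(hr + 1L):d[1], (hc + 1L):d[2], ]
  out[(hr + 1L):d[1], 1:hc, ] <- quadrant_images[[4]][(hr + 1L):d[1], 1:hc, ]
  if (!is.null(boundary_mask)) {
    if (!identical(dim(boundary_mask), d[1:2]))
      stop("`boundary_mask` shape must match the images")
    r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
    r[boundary_mask] <- 255L; g[boundary_mask] <- 0L; b[boundary_mask] <- 0L
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  }
  out
}

#' Write an RGB array (values 0-255) as PNG
#'
#' @param rgb Integer RGB array (rows x cols x 3).
#' @param path Output PNG path.
#' @return Invisibly, \code{path}.
#' @export
write_rgb_png <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  png::writePNG(rgb / 255, path)
  invisible(path)
}
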