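#' Create a digit map
#'
#' A digit map is the 8-bit grayscale stimulus file sent to the display: a
#' matrix of integers in [0, 255].
#'
#' @param digits Integer matrix with values in [0, 255].
#' @return An object of class \code{"digit_map"}.
#' @export
digit_map <- function(digits) {
  if (!is.matrix(digits)) stop("`digits` must be a matrix")
  d <- digits
  storage.mode(d) <- "integer"
  if (anyNA(d) || any(d < 0L) || any(d > 255L))
    stop("digit values must be integers in [0, 255]")
  structure(list(digits = d), class = "digit_map")
}

#' @export
print.digit_map <- function(x, ...) {
  cat(sprintf("digit map: %d x %d px, digits [%d, %d], %d level(s)\n",
              nrow(x$digits), ncol(x$digits), min(x$digits), max(x$digits),
              length(unique(as.vector(x$digits)))))
  invisible(x)
}

#' Read an 8-bit grayscale digit map from TIFF or PNG
#'
#' Accepts single-channel 8-bit files only; multi-channel (RGB/RGBA) or
#' higher bit-depth inputs are rejected, because the stimulus pipeline is
#' defined on the exact 8-bit digits sent to the display.
#'
#' @param path Path to a \code{.tif}/\code{.tiff} or \code{.png} file.
#' @return A \code{\link{digit_map}}.
#' @export
load_digit_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L)
      stop("multi-channel TIFF rejected; supply an 8-bit grayscale file: ",
           path)
    if (!is.integer(img) || max(img) > 255L || min(img) < 0L)
      stop("TIFF is not 8-bit grayscale: ", path)
    return(digit_map(img))
  }
  if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2L)
      stop("multi-channel PNG rejected; supply an 8-bit grayscale file: ",
           path)
    d <- img * 255
    if (max(abs(d - round(d))) > 1e-6)
      stop("PNG does not contain 8-bit digit values: ", path)
    return(digit_map(matrix(as.integer(round(d)), nrow(img), ncol(img))))
  }
  stop("unsupported digit-map format (need TIFF or PNG): ", path)
}

#' Write a digit map as 8-bit grayscale TIFF or PNG
#'
#' @param map A \code{\link{digit_map}}.
#' @param path Output path; format chosen from the extension.
#' @return Invisibly, \code{path}.
#' @export
write_digit_map <- function(map, path) {
  stopifnot(inherits(map, "digit_map"))
  ext <- tolower(tools::file_ext(path))
  img <- map$digits / 255
  if (ext %in% c("tif", "tiff"))
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  else if (ext == "png")
    png::writePNG(img, path)
  else stop("unsupported output format: ", path)
  invisible(path)
}

#' Display calibration: digit to luminance table
#'
#' A photometer calibration of the display: measured luminances (cd/m2) at a
#' strictly increasing set of digit values. Luminances must also be strictly
#' increasing (monotone display). Between measured points the calibration is
#' interpolated piecewise-linearly; a fully sampled 256-entry table bypasses
#' interpolation.
#'
#' @param digits Integer vector of measured digit values (strictly
#'   increasing, within [0, 255]).
#' @param cd_per_m2 Measured luminances in cd/m2 (strictly increasing, > 0).
#' @return An object of class \code{"display_calibration"}.
#' @examples
#' # the three-point table used for the Contrast+Assimilation targets:
#' display_calibration(c(21, 145, 255), c(2.24, 136, 450))
#' @export
display_calibration <- function(digits, cd_per_m2) {
  digits <- as.integer(digits)
  cd_per_m2 <- as.numeric(cd_per_m2)
  if (length(digits) < 2L || length(digits) != length(cd_per_m2))
    stop("calibration needs >= 2 (digit, luminance) pairs of equal length")
  if (any(diff(digits) <= 0L)) stop("calibration digits must strictly increase")
  if (any(!is.finite(cd_per_m2)) || any(cd_per_m2 <= 0))
    stop("calibration luminances must be finite and > 0")
  if (any(diff(cd_per_m2) <= 0))
    stop("calibration luminances must strictly increase (monotone display)")
  if (digits[1] < 0L || digits[length(digits)] > 255L)
    stop("calibration digits must lie in [0, 255]")
  structure(list(digits = digits, cd_per_m2 = cd_per_m2),
            class = "display_calibration")
}

#' @export
print.display_calibration <- function(x, ...) {
  n <- length(x$digits)
  cat(sprintf(paste0("display calibration: %d points, digits [%d, %d], ",
                     "%.3g-%.3g cd/m2 (%.3g:1, %.2f log10)\n"),
              n, x$digits[1], x$digits[n], x$cd_per_m2[1], x$cd_per_m2[n],
              x$cd_per_m2[n] / x$cd_per_m2[1],
              log10(x$cd_per_m2[n] / x$cd_per_m2[1])))
  invisible(x)
}

#' Read / write a calibration CSV
#'
#' The CSV has a header and two columns, \code{digit,cd_per_m2}.
#'
#' @param path CSV path.
#' @return For \code{read_calibration_csv}, a
#'   \code{\link{display_calibration}}.
#' @export
read_calibration_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("digit", "cd_per_m2") %in% names(tab)))
    stop("calibration CSV must have columns `digit,cd_per_m2`: ", path)
  display_calibration(tab$digit, tab$cd_per_m2)
}

#' @rdname read_calibration_csv
#' @param cal A \code{\link{display_calibration}}.
#' @export
write_calibration_csv <- function(cal, path) {
  stopifnot(inherits(cal, "display_calibration"))
  utils::write.csv(data.frame(digit = cal$digits, cd_per_m2 = cal$cd_per_m2),
                   path, row.names = FALSE)
  invisible(path)
}

#' Convert a digit map to normalized linear scene luminance
#'
#' Maps every digit through the (piecewise-linear) display calibration to
#' cd/m2, then normalizes the array by its maximum. The result is the linear
#' scene-luminance array the glare convolution consumes, held at 64-bit
#' precision, with \code{max_cd_m2} recording the normalization anchor.
#'
#' Digits below the calibrated black point are clamped to the lowest
#' calibrated luminance (with a warning) to tolerate antialiased edges;
#' digits above the calibrated white point are a coverage error.
#'
#' @param map A \code{\link{digit_map}}.
#' @param cal A \code{\link{display_calibration}} covering the digits used.
#' @return An object of class \code{"scene_luminance"}: list with
#'   \code{values} (matrix, max exactly 1), \code{max_cd_m2}, and the
#'   calibration used.
#' @export
apply_calibration <- function(map, cal) {
  stopifnot(inherits(map, "digit_map"), inherits(cal, "display_calibration"))
  d <- map$digits
  n <- length(cal$digits)
  if (max(d) > cal$digits[n])
    stop(sprintf("digit %d above calibrated span [%d, %d]",
                 max(d), cal$digits[1], cal$digits[n]))
  if (min(d) < cal$digits[1])
    warning(sprintf("digits below calibrated black point %d clamped to %.3g cd/m2",
                    cal$digits[1], cal$cd_per_m2[1]))
  # per-digit lookup table: 256 entries, piecewise-linear between samples
  lut <- stats::approx(cal$digits, cal$cd_per_m2, xout = 0:255,
                       method = "linear", rule = 2L)$y
  v <- matrix(lut[as.vector(d) + 1L], nrow(d), ncol(d))
  mx <- max(v)
  scene_luminance(v / mx, max_cd_m2 = mx)
}

#' Construct a scene-luminance object
#'
#' @param values Matrix of non-negative relative luminances; it is normalized
#'   so its maximum equals exactly 1.
#' @param max_cd_m2 Absolute luminance (cd/m2) of the normalization anchor.
#' @return An object of class \code{"scene_luminance"}.
#' @export
scene_luminance <- function(values, max_cd_m2 = NA_real_) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stop("scene luminances must be finite and non-negative")
  mx <- max(values)
  if (mx <= 0) stop("scene luminance maximum must be > 0")
  structure(list(values = values / mx, max_cd_m2 = as.numeric(max_cd_m2)),
            class = "scene_luminance")
}

#' @export
print.scene_luminance <- function(x, ...) {
  rng <- range(x$values[x$values > 0])
  cat(sprintf(paste0("scene luminance: %d x %d px, normalized max 1 ",
                     "(%.4g cd/m2), min %.4g (%.3g:1)\n"),
              nrow(x$values), ncol(x$values), x$max_cd_m2, rng[1],
              1 / rng[1]))
  invisible(x)
}
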