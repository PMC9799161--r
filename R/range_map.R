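#' Log range for 8-bit analysis renderings
#'
#' The log10 span to which linear images are scaled for 8-bit analysis
#' images and percent-of-range statistics. The default 2.3 corresponds to the
#' 200:1 display range of the illusion targets.
#'
#' @param range_log10 Positive log10 span.
#' @return An object of class \code{"log_range"}.
#' @export
log_range <- function(range_log10 = 2.3) {
  if (!is.numeric(range_log10) || length(range_log10) != 1L ||
      !is.finite(range_log10) || range_log10 <= 0)
    stop("`range_log10` must be a single finite value > 0")
  structure(list(range_log10 = as.numeric(range_log10)), class = "log_range")
}

# round half away from zero (values here are non-negative)
round_half_up <- function(x) floor(x + 0.5)

#' Map a linear image to an 8-bit log-scaled analysis image
#'
#' Each value v maps to \code{digit = round(255 * (1 + log10(v/vmax)/range))}
#' clipped to [0, 255], where vmax is the image's own maximum. Digit 255 is
#' the image maximum; digit 0 is \code{vmax * 10^-range}; values below the
#' range floor clip to 0 (the "abrupt lower range limit" seen in analyses).
#' Rounding is half-away-from-zero, applied once at quantization.
#'
#' @param image A \code{\link{scene_luminance}} or retinal-contrast object
#'   (strictly positive values).
#' @param range A \code{\link{log_range}}.
#' @return An object of class \code{"log_mapped_image"}: list with
#'   \code{digits} (integer matrix), \code{range} and \code{vmax}.
#' @export
log_map <- function(image, range = log_range()) {
  if (!inherits(range, "log_range")) stop("`range` must be a log_range()")
  v <- image$values
  vmax <- max(v)
  if (!is.finite(vmax) || vmax <= 0) stop("image maximum must be > 0")
  d <- round_half_up(255 * (1 + log10(v / vmax) / range$range_log10))
  d[d < 0] <- 0
  d[d > 255] <- 255
  storage.mode(d) <- "integer"
  structure(list(digits = d, range = range, vmax = vmax),
            class = "log_mapped_image")
}

#' @export
print.log_mapped_image <- function(x, ...) {
  cat(sprintf("log-mapped image: %d x %d px, digits [%d, %d], range %.3g log10\n",
              nrow(x$digits), ncol(x$digits), min(x$digits), max(x$digits),
              x$range$range_log10))
  invisible(x)
}

#' Write a log-mapped image as 8-bit grayscale with a JSON sidecar
#'
#' @param image A \code{\link{log_map}} result.
#' @param path Output TIFF/PNG path (by extension); sidecar at
#'   \code{paste0(path, ".json")}.
#' @return Invisibly, the file paths.
#' @export
write_log_mapped <- function(image, path) {
  stopifnot(inherits(image, "log_mapped_image"))
  write_digit_map(digit_map(image$digits), path)
  jsonlite::write_json(list(log_range = image$range$range_log10,
                            vmax = image$vmax),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".json")))
}

#' Express a value as percent of the log range
#'
#' Returns \code{100 * (1 + log10(value/vmax)/range)}, clipped to [0, 100]:
#' the percent-of-log-range convention used for all region statistics
#' (100\% = the image maximum, 0\% = \code{vmax * 10^-range}).
#'
#' @param value Positive value(s) on the image's linear scale.
#' @param vmax The image maximum (normalization anchor).
#' @param range A \code{\link{log_range}}.
#' @return Percent value(s) in [0, 100]; values above vmax clip to 100 with
#'   a warning.
#' @examples
#' percent_of_range(136 / 450, 1)   # the gray patch: 77.4% of a 2.3 range
#' @export
percent_of_range <- function(value, vmax, range = log_range()) {
  if (!inherits(range, "log_range")) stop("`range` must be a log_range()")
  stopifnot(is.numeric(value), is.numeric(vmax), vmax > 0)
  if (any(!is.finite(value)) || any(value <= 0))
    stop("`value` must be positive and finite")
  if (any(value > vmax))
    warning("value(s) above vmax clipped to 100%")
  p <- 100 * (1 + log10(value / vmax) / range$range_log10)
  pmin(pmax(p, 0), 100)
}
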