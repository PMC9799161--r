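#' Padding modes for the glare convolution
#'
#' \code{pad_replicate()} extends the image by repeating its outer rim — the
#' stimulus behaves as if embedded in a surround of its own border values
#' (for an all-white rim, a uniform white surround nine times the stimulus
#' area; for a black rim, a darkroom). This is the mode used for all
#' reproductions. \code{pad_constant(value)} embeds the stimulus in a uniform
#' field of the given relative luminance and is provided for idealized tests.
#'
#' @param value Relative luminance of the constant surround.
#' @return An object of class \code{"padding_mode"}.
#' @export
pad_replicate <- function() {
  structure(list(mode = "replicate", value = NA_real_),
            class = "padding_mode")
}

#' @rdname pad_replicate
#' @export
pad_constant <- function(value = 0) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value),
            value >= 0)
  structure(list(mode = "constant", value = as.numeric(value)),
            class = "padding_mode")
}

# smallest integer >= n whose prime factors are all in {2, 3, 5, 7};
# keeps the mixed-radix FFTs fast for arbitrary padded sizes
good_fft_size <- function(n) {
  while (TRUE) {
    m <- n
    for (p in c(2L, 3L, 5L, 7L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# 2-D linear convolution of the padded scene with the kernel, returning
# only the central (original-shape) region.
#
# The padded image (size P = N + 2R per axis) is transformed at a composite
# size L >= P; circular wrap-around then only contaminates outputs within
# the padding margin, so the cropped interior is the exact linear
# convolution.  The transforms run in compiled code (FFTW) over three
# preallocated buffers — the kernel, being even about its center, has a
# purely real spectrum stored at half size — so peak memory stays near the
# theoretical minimum even for gigapixel kernels.
fft_convolve_padded <- function(x, kernel_w, radius, padding) {
  L1 <- good_fft_size(nrow(x) + 2L * radius)
  L2 <- good_fft_size(ncol(x) + 2L * radius)
  cval <- if (padding$mode == "constant") padding$value else NA_real_
  .Call(C_glare_convolve, x, kernel_w, as.integer(radius), cval,
        L1, L2)
}

#' Convolve scene luminance with the glare kernel
#'
#' Computes the retinal contrast image: the pattern of light on the retina
#' after intraocular veiling glare, i.e. the wrap-free linear convolution of
#' the (boundary-padded) scene luminance with the unit-sum glare kernel,
#' cropped back to the input shape. All arithmetic is 64-bit; the convolution
#' runs in the frequency domain.
#'
#' Because the kernel is positive with unit sum and the padding embeds the
#' image in a surround, the output is an average of scene values: for any
#' scene the output minimum is >= the scene minimum and the output maximum
#' <= the scene maximum, and a uniform scene is reproduced unchanged.
#'
#' @param scene A \code{\link{scene_luminance}} (or
#'   \code{\link{retinal_contrast}}) object.
#' @param kernel A \code{\link{build_kernel}} result for this scene's
#'   geometry, or any odd-sided positive unit-sum weight matrix (toy kernels
#'   for testing).
#' @param padding A \code{\link{pad_replicate}} or \code{\link{pad_constant}}
#'   mode; padding width equals the kernel radius.
#' @return An object of class \code{"retinal_contrast"}: list with
#'   \code{values} (same shape as the input), \code{energy_ratio}
#'   (sum(out)/sum(in)), the padding mode and, when available, the kernel
#'   provenance.
#' @export
convolve_glare <- function(scene, kernel, padding = pad_replicate()) {
  if (!inherits(scene, c("scene_luminance", "retinal_contrast")))
    stop("`scene` must be a scene_luminance or retinal_contrast object")
  if (!inherits(padding, "padding_mode"))
    stop("`padding` must be pad_replicate() or pad_constant()")
  x <- scene$values
  if (anyNA(x) || any(!is.finite(x))) stop("scene contains non-finite values")
  if (inherits(kernel, "glare_kernel")) {
    if (!identical(kernel$geometry$shape, dim(x)))
      stop(sprintf("kernel was built for %d x %d but scene is %d x %d",
                   kernel$geometry$shape[1], kernel$geometry$shape[2],
                   nrow(x), ncol(x)))
    w <- kernel$weights
    radius <- kernel$radius_px
    prov <- list(age = kernel$params$age, pigment = kernel$params$pigment,
                 arcmin_per_pixel = kernel$geometry$arcmin_per_pixel)
  } else {
    w <- kernel
    if (!is.matrix(w) || nrow(w) %% 2L == 0L || ncol(w) %% 2L == 0L ||
        nrow(w) != ncol(w))
      stop("a raw kernel must be a square odd-sided matrix")
    if (any(w < 0) || any(!is.finite(w)))
      stop("kernel weights must be finite and non-negative")
    radius <- (nrow(w) - 1L) %/% 2L
    prov <- NULL
  }
  out <- fft_convolve_padded(x, w, radius, padding)
  # FFT round-off can leave harmless negatives of ~1e-16 in all-zero regions
  out[out < 0] <- 0
  structure(list(values = out,
                 energy_ratio = sum(out) / sum(x),
                 padding = padding$mode,
                 kernel = prov),
            class = "retinal_contrast")
}

#' @export
print.retinal_contrast <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf(paste0("retinal contrast: %d x %d px, range %.4g-%.4g ",
                     "(%.3g:1), energy ratio %.6f, padding %s\n"),
              nrow(x$values), ncol(x$values), rng[1], rng[2],
              rng[2] / rng[1], x$energy_ratio, x$padding))
  invisible(x)
}

#' Write a linear image (scene or retina) as float TIFF plus JSON sidecar
#'
#' @param image A \code{\link{scene_luminance}} or retinal-contrast object.
#' @param path Output TIFF path; the sidecar goes to
#'   \code{paste0(path, ".json")}.
#' @return Invisibly, the file paths.
#' @export
write_linear_tiff <- function(image, path) {
  v <- image$values
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(class = class(image)[1], min = min(v), max = max(v))
  if (!is.null(image$energy_ratio)) meta$energy_ratio <- image$energy_ratio
  if (!is.null(image$padding)) meta$padding <- image$padding
  if (!is.null(image$kernel)) meta$kernel <- image$kernel
  if (!is.null(image$max_cd_m2)) meta$max_cd_m2 <- image$max_cd_m2
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(c(path, paste0(path, ".json")))
}
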