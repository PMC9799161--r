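#' Observer parameters for the CIE glare spread function
#'
#' The CIE general disability glare equation is parameterized by observer age
#' (in years) and an iris-pigmentation factor \code{p} (0 for very dark eyes,
#' 0.5 for brown, ~1 for blue-green, ~1.2 for very light blue). Defaults
#' correspond to a young observer with brown eyes, i.e. minimal-glare vision.
#'
#' @param age Observer age in years (> 0).
#' @param pigment Dimensionless iris pigmentation factor (>= 0).
#' @return An object of class \code{"glare_parameters"}.
#' @examples
#' glare_parameters()          # age 25, brown eyes
#' glare_parameters(70, 1.2)   # older, light-blue eyes
#' @export
glare_parameters <- function(age = 25, pigment = 0.5) {
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age <= 0)
    stop("`age` must be a single finite value > 0, got: ", format(age))
  if (!is.numeric(pigment) || length(pigment) != 1L || !is.finite(pigment) ||
      pigment < 0)
    stop("`pigment` must be a single finite value >= 0, got: ",
         format(pigment))
  structure(list(age = as.numeric(age), pigment = as.numeric(pigment)),
            class = "glare_parameters")
}

#' @export
print.glare_parameters <- function(x, ...) {
  cat("CIE glare observer: age", x$age, "y, pigment", x$pigment, "\n")
  invisible(x)
}

# Default pixel pitch: a 2048-px image spanning 10 degrees of visual angle,
# i.e. 10 * 60 / 2048 arcmin per pixel.
DEFAULT_ARCMIN_PER_PIXEL <- 10 * 60 / 2048

#' Angular geometry of an image
#'
#' Binds an image shape to its angular calibration. The angular pitch is
#' derived from the field of view spanned by the image's larger dimension:
#' \code{arcmin_per_pixel = field_of_view_deg * 60 / max(rows, cols)}. If
#' neither a field of view nor a pitch is given, the default pitch of
#' 0.29296875 arcmin/pixel (10 degrees over 2048 pixels) is used.
#'
#' @param shape Integer vector \code{c(rows, cols)}, both >= 2.
#' @param field_of_view_deg Degrees spanned by the larger image dimension.
#' @param arcmin_per_pixel Angular pixel pitch in arcmin; overrides
#'   \code{field_of_view_deg} when given.
#' @return An object of class \code{"angular_geometry"} with fields
#'   \code{shape}, \code{field_of_view_deg} and \code{arcmin_per_pixel}.
#' @export
angular_geometry <- function(shape, field_of_view_deg = NULL,
                             arcmin_per_pixel = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 2L))
    stop("`shape` must be two integer dimensions, each >= 2")
  if (!is.null(arcmin_per_pixel)) {
    stopifnot(is.numeric(arcmin_per_pixel), arcmin_per_pixel > 0)
    pitch <- as.numeric(arcmin_per_pixel)
    fov <- pitch * max(shape) / 60
  } else {
    fov <- if (is.null(field_of_view_deg))
      DEFAULT_ARCMIN_PER_PIXEL * max(shape) / 60
    else as.numeric(field_of_view_deg)
    stopifnot(is.finite(fov), fov > 0)
    pitch <- fov * 60 / max(shape)
  }
  structure(list(shape = shape, field_of_view_deg = fov,
                 arcmin_per_pixel = pitch),
            class = "angular_geometry")
}

#' @export
print.angular_geometry <- function(x, ...) {
  cat(sprintf("angular geometry: %d x %d px, %.4g deg field, %.4g arcmin/px\n",
              x$shape[1], x$shape[2], x$field_of_view_deg,
              x$arcmin_per_pixel))
  invisible(x)
}

#' CIE glare spread function Leq/Egl
#'
#' Evaluates the CIE general disability glare equation (age- and
#' pigmentation-parameterized) at angular separation \code{theta_deg} between
#' the glare source and the receiving retinal location. The value is the
#' equivalent veiling luminance per unit glare illuminance at the eye
#' (Leq/Egl, dimensionless after unit cancellation), a strictly decreasing
#' function of angle that spans about 8 log10 units between 1 arcmin and 60
#' degrees and never reaches zero or a constant asymptote.
#'
#' The wide-angle stray-light term of the full standard (proportional to
#' theta^4, relevant beyond ~30 degrees) is omitted so that the function is
#' strictly monotone over the 60-degree field simulated here; see the
#' package vignette for the rationale.
#'
#' @param theta_deg Angular separation(s) in degrees, each > 0.
#' @param params A \code{\link{glare_parameters}} object.
#' @return Numeric vector of Leq/Egl values (> 0).
#' @examples
#' g <- gsf_value(c(1/60, 1, 60))
#' log10(g[1] / g[3])   # about 8 log10 units
#' @export
gsf_value <- function(theta_deg, params = glare_parameters()) {
  if (!inherits(params, "glare_parameters"))
    stop("`params` must be created with glare_parameters()")
  if (!is.numeric(theta_deg) || length(theta_deg) == 0L)
    stop("`theta_deg` must be numeric")
  bad <- !is.finite(theta_deg) | theta_deg <= 0
  if (any(bad))
    stop("`theta_deg` must be positive and finite; offending value(s): ",
         paste(utils::head(theta_deg[bad], 3L), collapse = ", "))
  a4 <- (params$age / 70)^4
  p <- params$pigment
  t2a <- (theta_deg / 0.0046)^2
  t2b <- (theta_deg / 0.045)^2
  t2c <- (theta_deg / 0.1)^2
  (1 - 0.08 * a4) *
    (9.2e6 / (1 + t2a)^1.5 + 1.5e5 / (1 + t2b)^1.5) +
    (1 + 1.6 * a4) *
      (400 / (1 + t2c) +
         p * (1300 / (1 + t2c)^1.5 + 0.8 / sqrt(1 + t2c))) +
    2.5e-3 * p
}

# Map a planar pixel distance to an angular separation in degrees.
#
# The glare spread function is defined on the sphere of visual directions;
# image pixels live on a plane. A pixel at planar distance d (in pixel units)
# from the line of sight subtends theta = atan(d * tan(pitch)) where pitch is
# the single-pixel angle. The zero-offset (kernel center) angle is evaluated
# at half a pixel pitch, which keeps the center weight finite and
# resolution-consistent; the kernel's unity normalization absorbs the
# absolute scale.
pixel_angle_deg <- function(dist_px, arcmin_per_pixel) {
  pitch_rad <- (arcmin_per_pixel / 60) * pi / 180
  theta <- atan(dist_px * tan(pitch_rad)) * 180 / pi
  theta[dist_px == 0] <- arcmin_per_pixel / 120
  theta
}

# kernels keyed by geometry + observer; large kernels are not retained
.kernel_cache <- new.env(parent = emptyenv())

#' Build the full-image glare convolution kernel
#'
#' Evaluates the CIE glare spread function on a 2-D grid of pixel offsets and
#' normalizes the weights to unit sum, so that convolution redistributes but
#' neither creates nor destroys light. The kernel radius is
#' \code{max(rows, cols) + 1} pixels (one extra pixel for symmetry), so that
#' a kernel centered on any image pixel covers the whole image; the kernel
#' side is \code{2 * radius + 1} and all weights are strictly positive.
#'
#' @param geometry An \code{\link{angular_geometry}} for the image the kernel
#'   will be convolved with.
#' @param params A \code{\link{glare_parameters}} object.
#' @param max_bytes Refuse to build kernels whose weight array would exceed
#'   this many bytes (resource guard; default 6e9).
#' @param cache Keep the kernel in an in-memory cache keyed by geometry and
#'   observer so repeated runs on the same geometry reuse it. Kernels with
#'   side > 5000 px are never cached.
#' @return An object of class \code{"glare_kernel"}: list with \code{weights}
#'   (matrix, sums to 1 within 1e-12), \code{radius_px}, \code{geometry},
#'   \code{params} and \code{norm_sum} (the post-normalization check sum).
#' @export
build_kernel <- function(geometry, params = glare_parameters(),
                         max_bytes = 6e9, cache = TRUE) {
  if (!inherits(geometry, "angular_geometry"))
    stop("`geometry` must be created with angular_geometry()")
  if (!inherits(params, "glare_parameters"))
    stop("`params` must be created with glare_parameters()")
  radius <- max(geometry$shape) + 1L
  side <- 2L * radius + 1L
  key <- paste(geometry$shape[1], geometry$shape[2],
               signif(geometry$arcmin_per_pixel, 12),
               params$age, params$pigment, sep = "|")
  if (cache && !is.null(.kernel_cache[[key]]))
    return(.kernel_cache[[key]])
  need <- 8 * as.numeric(side)^2
  if (need > max_bytes)
    stop(sprintf(paste0("glare kernel of side %d would need %.2f GB ",
                        "(> max_bytes = %.2f GB)"),
                 side, need / 1e9, max_bytes / 1e9))
  # evaluate one quadrant (offsets 0..radius) and mirror: the GSF is radial
  off <- 0:radius
  d2 <- outer(off^2, off^2, "+")
  q <- gsf_value(pixel_angle_deg(sqrt(d2), geometry$arcmin_per_pixel), params)
  dim(q) <- c(radius + 1L, radius + 1L)
  w <- matrix(0, side, side)
  c0 <- radius + 1L
  w[c0:side, c0:side] <- q
  w[c0:1, c0:side] <- q
  w[c0:side, c0:1] <- q
  w[c0:1, c0:1] <- q
  w <- w / sum(w)
  kern <- structure(list(weights = w, radius_px = radius,
                         geometry = geometry, params = params,
                         norm_sum = sum(w)),
                    class = "glare_kernel")
  if (cache && side <= 5000L) .kernel_cache[[key]] <- kern
  kern
}

#' @export
print.glare_kernel <- function(x, ...) {
  cat(sprintf(paste0("glare kernel: side %d (radius %d px), ",
                     "sum = %.15f, center weight = %.3e\n"),
              nrow(x$weights), x$radius_px, x$norm_sum,
              x$weights[x$radius_px + 1L, x$radius_px + 1L]))
  invisible(x)
}

#' Export a glare kernel as float TIFF plus JSON sidecar
#'
#' Writes the kernel weights as a 32-bit float TIFF (scaled by its maximum so
#' the file stays inspectable in image viewers) and a JSON sidecar recording
#' the geometry, observer parameters, normalization sum and scale factor.
#'
#' @param kernel A \code{\link{build_kernel}} result.
#' @param path Output TIFF path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return Invisibly, the two file paths.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "glare_kernel"))
  mx <- max(kernel$weights)
  tiff::writeTIFF(kernel$weights / mx, path, bits.per.sample = 32L,
                  reduce = FALSE)
  side <- jsonlite::write_json(
    list(shape = kernel$geometry$shape,
         field_of_view_deg = kernel$geometry$field_of_view_deg,
         arcmin_per_pixel = kernel$geometry$arcmin_per_pixel,
         age = kernel$params$age, pigment = kernel$params$pigment,
         radius_px = kernel$radius_px, norm_sum = kernel$norm_sum,
         tiff_scale = mx),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(c(path, paste0(path, ".json")))
}
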