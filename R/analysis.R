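#' Erode a binary mask
#'
#' Square (8-neighborhood) erosion by \code{r} pixels, used to separate a
#' region's interior from the 1-2 border pixels that carry extreme
#' edge-gradient values after glare.
#'
#' @param mask Logical matrix.
#' @param r Erosion radius in pixels.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, r = 2L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  m <- mask
  for (k in seq_len(r)) {
    p <- matrix(FALSE, nrow(m) + 2L, ncol(m) + 2L)
    p[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
    q <- m
    for (dy in -1:1) for (dx in -1:1)
      q <- q & p[(2:(nrow(m) + 1L)) + dy, (2:(ncol(m) + 1L)) + dx,
                 drop = FALSE]
    m <- q
  }
  m
}

#' Region-of-interest statistics in log10 and percent-of-range conventions
#'
#' Summarizes the masked pixels of a linear image: min/mean/max of the log10
#' relative value (relative to the image's own maximum) and the same as
#' percent of the log range. Statistics are reported both over the full mask
#' and over its interior (mask eroded by \code{erode} pixels), because after
#' glare the outermost region pixels carry extreme edge-gradient values.
#'
#' @param image A \code{\link{scene_luminance}} or retinal-contrast object.
#' @param mask Logical matrix, same shape, with at least one TRUE pixel.
#' @param range A \code{\link{log_range}}.
#' @param roi_name Label carried into the result.
#' @param erode Interior erosion radius (default 2); use 0 to skip the
#'   interior row.
#' @return A data.frame with one row per mode (\code{full},
#'   \code{interior}): pixel count, log10 min/mean/max, percent min/mean/max.
#' @export
roi_stats <- function(image, mask, range = log_range(), roi_name = "roi",
                      erode = 2L) {
  v <- image$values
  if (!is.matrix(mask) || !identical(dim(mask), dim(v)))
    stop("`mask` shape must match the image")
  if (!any(mask)) stop("empty ROI mask")
  vmax <- max(v)
  one <- function(msk, mode) {
    x <- v[msk]
    lg <- log10(x / vmax)
    pc <- percent_of_range(x, vmax, range)
    data.frame(roi = roi_name, mode = mode, pixels = length(x),
               log10_min = min(lg), log10_mean = mean(lg),
               log10_max = max(lg),
               pct_min = min(pc), pct_mean = mean(pc), pct_max = max(pc),
               stringsAsFactors = FALSE)
  }
  out <- one(mask, "full")
  if (erode > 0L) {
    em <- erode_mask(mask, erode)
    if (any(em)) out <- rbind(out, one(em, "interior"))
  }
  out
}

#' Log range spanned by an image, as percent of a reference range
#'
#' Returns \code{100 * log10(max/min) / range}, clipped to [0, 100]: the
#' fraction of the reference log range that the image actually occupies.
#' Glare only compresses the global range, so for any target the retinal
#' value is at most the scene value.
#'
#' @param image A \code{\link{scene_luminance}} or retinal-contrast object
#'   with strictly positive values.
#' @param range A \code{\link{log_range}}.
#' @return Percent of the reference log range, in [0, 100].
#' @export
image_range <- function(image, range = log_range()) {
  v <- image$values
  mn <- min(v)
  if (mn <= 0) stop("image must be strictly positive")
  min(max(100 * log10(max(v) / mn) / range$range_log10, 0), 100)
}

#' Histogram of a linear image in linear or log bins
#'
#' 256 bins: linear mode bins the linear values over [0, max]; log mode bins
#' log10 relative values over [-range, 0] (values below the floor fall into
#' the first bin). Counts are normalized to the histogram's own peak.
#'
#' @param image A \code{\link{scene_luminance}} or retinal-contrast object.
#' @param mode \code{"linear"} or \code{"log"}.
#' @param range A \code{\link{log_range}} (log mode).
#' @return List of class \code{"glare_histogram"}: \code{breaks} (257 bin
#'   edges), \code{counts}, \code{normalized} (peak = 1) and \code{mode}.
#' @export
glare_histogram <- function(image, mode = c("linear", "log"),
                            range = log_range()) {
  mode <- match.arg(mode)
  v <- as.vector(image$values)
  if (mode == "linear") {
    breaks <- seq(0, max(v), length.out = 257L)
    x <- v
  } else {
    if (min(v) <= 0) stop("log-mode histogram needs strictly positive values")
    breaks <- seq(-range$range_log10, 0, length.out = 257L)
    x <- pmax(log10(v / max(v)), -range$range_log10)
  }
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = 256L)
  structure(list(breaks = breaks, counts = counts,
                 normalized = counts / max(counts), mode = mode),
            class = "glare_histogram")
}

#' Horizontal scan-line profile of scene and retina
#'
#' Extracts one image row (1 pixel high) from the scene and the retinal
#' image as paired log10 relative profiles — the standard way to compare
#' edge sharpness and local range before and after glare.
#'
#' @param scene A \code{\link{scene_luminance}}.
#' @param retina A retinal-contrast object of the same shape.
#' @param row Row index.
#' @return A data.frame with columns \code{col}, \code{scene_log10},
#'   \code{retina_log10}.
#' @export
scan_profile <- function(scene, retina, row) {
  s <- scene$values; r <- retina$values
  if (!identical(dim(s), dim(r))) stop("scene and retina shapes differ")
  row <- as.integer(row)
  if (row < 1L || row > nrow(s)) stop("row ", row, " out of bounds")
  data.frame(col = seq_len(ncol(s)),
             scene_log10 = log10(s[row, ] / max(s)),
             retina_log10 = log10(r[row, ] / max(r)))
}

#' Glare's-Paradox report for a target's declared ROI pairs
#'
#' For every declared appearance pair of a target, compares the mean
#' retinal contrast of the ROI that appears darker with the one that appears
#' lighter. The pair exhibits Glare's Paradox when the darker-appearing ROI
#' receives the \emph{more} light after glare — the hallmark of contrast
#' illusions, absent in assimilation.
#'
#' @param retina A retinal-contrast object computed from the bundle's scene.
#' @param bundle The \code{\link{target_bundle}}, with
#'   \code{appearance_order} declared.
#' @return A data.frame with one row per pair: ROI names, illusion type,
#'   linear mean retinal contrast of each ROI, and \code{paradox}
#'   (TRUE iff mean(darker) > mean(lighter)).
#' @export
paradox_report <- function(retina, bundle) {
  stopifnot(inherits(bundle, "target_bundle"))
  ord <- bundle$appearance_order
  if (is.null(ord) || nrow(ord) == 0L)
    stop("bundle declares no appearance ordering")
  v <- retina$values
  if (!identical(dim(v), dim(bundle$map$digits)))
    stop("retina shape does not match the bundle")
  rows <- lapply(seq_len(nrow(ord)), function(i) {
    dk <- ord$darker[i]; lt <- ord$lighter[i]
    for (nm in c(dk, lt))
      if (is.null(bundle$rois[[nm]]))
        stop("ROI missing from bundle: ", nm)
    md <- mean(v[bundle$rois[[dk]]])
    ml <- mean(v[bundle$rois[[lt]]])
    data.frame(darker = dk, lighter = lt, illusion = ord$illusion[i],
               mean_darker = md, mean_lighter = ml,
               paradox = md > ml, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
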