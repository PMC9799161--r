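#' Target bundles
#'
#' A target bundle packages everything needed to run and test a
#' lightness-illusion stimulus end to end: the 8-bit digit map, the display
#' calibration, named region-of-interest masks, the declared appearance
#' ordering of equal-luminance ROI pairs, the angular geometry, and the
#' generator's chosen dimensions (metadata). The equal-luminance ROI pairs
#' always share one digit value, so their scene luminances are exactly equal
#' before convolution — glare then makes them unequal.
#'
#' @name target_bundle
NULL

new_target_bundle <- function(map, calibration, rois, appearance_order,
                              geometry, metadata, scan_rows = NULL) {
  structure(list(map = map, calibration = calibration, rois = rois,
                 appearance_order = appearance_order, geometry = geometry,
                 metadata = metadata, scan_rows = scan_rows),
            class = "target_bundle")
}

#' @export
print.target_bundle <- function(x, ...) {
  cat(sprintf("target bundle `%s`: %d x %d px, %d ROI mask(s), %d declared pair(s)\n",
              x$metadata$variant, nrow(x$map$digits), ncol(x$map$digits),
              length(x$rois),
              if (is.null(x$appearance_order)) 0L else nrow(x$appearance_order)))
  invisible(x)
}

#' Scene luminance of a target bundle
#'
#' @param bundle A target bundle.
#' @return The \code{\link{scene_luminance}} of its map under its
#'   calibration.
#' @export
bundle_scene <- function(bundle) {
  stopifnot(inherits(bundle, "target_bundle"))
  apply_calibration(bundle$map, bundle$calibration)
}

# the photometer table of the illusion displays: White digit 255 (450
# cd/m2), Gray digit 145 (136), Black digit 21 (2.24) -- a 200:1 range
#' Default display calibration of the illusion targets
#'
#' Three measured points: digit 255 -> 450 cd/m2 (White), 145 -> 136 (Gray),
#' 21 -> 2.24 (Black); a 200:1 (2.3 log10) display range.
#'
#' @return A \code{\link{display_calibration}}.
#' @export
default_calibration <- function() {
  display_calibration(c(21L, 145L, 255L), c(2.24, 136, 450))
}

DIGIT_WHITE <- 255L
DIGIT_GRAY <- 145L
DIGIT_BLACK <- 21L

# stripe row classification: partition `height` rows into `n` near-equal
# stripes (n even keeps white/black balanced); returns 0-based stripe index
stripe_index <- function(height, n) {
  edges <- round_half_up(seq(0, height, length.out = n + 1))
  findInterval(seq_len(height) - 1L, edges, rightmost.closed = TRUE) - 1L
}

#' Generate a Contrast + Assimilation target (variants A-D)
#'
#' Each 2048 x 2048 (default) target combines a simultaneous-contrast
#' illusion (top half: identical gray rectangles in uniform White and Black
#' surrounds) with a striped assimilation illusion (bottom half: identical
#' gray bars flanked by white or by black stripes), inside a constant gray
#' frame and an outer band. Variants:
#' \itemize{
#'   \item A: white outer band, large Contrast surrounds;
#'   \item B: white outer band, reduced Contrast surrounds on a striped
#'     ground;
#'   \item C: black outer band, large Contrast surrounds;
#'   \item D: black outer band, reduced Contrast surrounds.
#' }
#' Area fractions follow the design constraints: Gray segments 14\% of the
#' target in all variants (identical locations), White/Black 57\%/29\% for
#' A and B, 29\%/57\% for C and D, each held within 1\%. With equal-size
#' Contrast surrounds and balanced stripes, the White-minus-Black surplus is
#' carried entirely by the outer band, which therefore occupies 28\% of the
#' area.
#'
#' Declared appearances: the Contrast gray-in-white ROI is darker than
#' gray-in-black; the assimilation gray-in-black ROI (black flankers) is
#' darker than gray-in-white.
#'
#' @param variant One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"}.
#' @param size Image side in pixels (>= 512; default 2048).
#' @return A \code{\link{target_bundle}}.
#' @export
make_contrast_assimilation <- function(variant = c("A", "B", "C", "D"),
                                       size = 2048L) {
  variant <- match.arg(variant)
  size <- as.integer(size)
  if (size < 512L) stop("`size` must be >= 512 to honor the area fractions")
  s <- size / 2048
  outer_digit <- if (variant %in% c("A", "B")) DIGIT_WHITE else DIGIT_BLACK
  large_surrounds <- variant %in% c("A", "C")

  # outer band carries the 28% white/black surplus: fraction 1-(1-2wb/S)^2
  wb <- as.integer(round_half_up(size * (1 - sqrt(0.72)) / 2))
  wf <- max(2L, as.integer(round_half_up(40 * s)))   # gray frame width
  m <- matrix(outer_digit, size, size)

  inner <- c(wb + 1L, size - wb)                 # frame ring outer edge
  m[inner[1]:inner[2], inner[1]:inner[2]] <- DIGIT_GRAY
  c0 <- wb + wf + 1L; c1 <- size - wb - wf       # content columns
  mid <- size %/% 2L
  top_r <- c(c0, mid - wf)                       # contrast rows
  bot_r <- c(mid + wf + 1L, c1)                  # assimilation rows
  half <- (c0 + c1 - 1L) %/% 2L                  # content column split
  n_stripes <- 24L

  # --- bottom half: assimilation stripes ---------------------------------
  bh <- bot_r[2] - bot_r[1] + 1L
  sidx <- stripe_index(bh, n_stripes)
  stripe_digit <- ifelse(sidx %% 2L == 0L, DIGIT_WHITE, DIGIT_BLACK)
  m[bot_r[1]:bot_r[2], c0:c1] <- matrix(stripe_digit, bh, c1 - c0 + 1L)

  # --- top half: contrast surrounds --------------------------------------
  th <- top_r[2] - top_r[1] + 1L
  if (large_surrounds) {
    m[top_r[1]:top_r[2], c0:half] <- DIGIT_WHITE
    m[top_r[1]:top_r[2], (half + 1L):c1] <- DIGIT_BLACK
  } else {
    tidx <- stripe_index(th, n_stripes)
    m[top_r[1]:top_r[2], c0:c1] <-
      matrix(ifelse(tidx %% 2L == 0L, DIGIT_WHITE, DIGIT_BLACK),
             th, c1 - c0 + 1L)
    sq <- as.integer(round_half_up(480 * s))     # reduced surround side
    cy <- top_r[1] + th %/% 2L
    cxl <- (c0 + half) %/% 2L
    cxr <- (half + 1L + c1) %/% 2L
    ys <- (cy - sq %/% 2L):(cy - sq %/% 2L + sq - 1L)
    m[ys, (cxl - sq %/% 2L):(cxl - sq %/% 2L + sq - 1L)] <- DIGIT_WHITE
    m[ys, (cxr - sq %/% 2L):(cxr - sq %/% 2L + sq - 1L)] <- DIGIT_BLACK
  }

  # --- gray regions: frame is already gray; now the four ROI groups ------
  rois <- list()
  roi_w <- as.integer(round_half_up(380 * s))
  roi_h <- as.integer(round_half_up(120 * s))
  place_rect <- function(mm, cy, cx, h, w, dig) {
    rr <- (cy - h %/% 2L):(cy - h %/% 2L + h - 1L)
    cc <- (cx - w %/% 2L):(cx - w %/% 2L + w - 1L)
    mm[rr, cc] <- dig
    mask <- matrix(FALSE, nrow(mm), ncol(mm))
    mask[rr, cc] <- TRUE
    list(mm, mask)
  }
  cy_top <- top_r[1] + th %/% 2L
  res <- place_rect(m, cy_top, (c0 + half) %/% 2L, roi_h, roi_w, DIGIT_GRAY)
  m <- res[[1]]; rois$contrast_gray_in_white <- res[[2]]
  res <- place_rect(m, cy_top, (half + 1L + c1) %/% 2L, roi_h, roi_w,
                    DIGIT_GRAY)
  m <- res[[1]]; rois$contrast_gray_in_black <- res[[2]]

  # assimilation bars: solve the bar width from the 14% gray budget
  frame_px <- sum(m == DIGIT_GRAY) - 2L * roi_w * roi_h
  need <- round_half_up(0.14 * as.numeric(size)^2) - frame_px -
    2 * roi_w * roi_h
  bar_need <- need / 2                           # per assimilation side
  # six flanked stripes per side, centered in the bottom half
  pick_stripes <- function(parity) {
    cand <- which(sidx %% 2L == parity)          # rows with that stripe color
    runs <- split(cand, cumsum(c(1L, diff(cand) != 1L)))
    k <- length(runs)
    runs[seq.int(max(1L, k %/% 2L - 2L), length.out = min(6L, k))]
  }
  draw_bars <- function(mm, runs, cx) {
    tot_h <- sum(lengths(runs))
    wbar <- as.integer(round_half_up(bar_need / tot_h))
    mask <- matrix(FALSE, nrow(mm), ncol(mm))
    cc <- (cx - wbar %/% 2L):(cx - wbar %/% 2L + wbar - 1L)
    for (rr in runs) {
      rows <- bot_r[1] - 1L + rr
      mm[rows, cc] <- DIGIT_GRAY
      mask[rows, cc] <- TRUE
    }
    list(mm, mask)
  }
  res <- draw_bars(m, pick_stripes(1L), (c0 + half) %/% 2L)  # on black stripes
  m <- res[[1]]; rois$assim_gray_in_white <- res[[2]]
  res <- draw_bars(m, pick_stripes(0L), (half + 1L + c1) %/% 2L)
  m <- res[[1]]; rois$assim_gray_in_black <- res[[2]]
  rois$black_segments <- m == DIGIT_BLACK
  rois$white_segments <- m == DIGIT_WHITE

  # --- verify the printed area fractions ---------------------------------
  tot <- as.numeric(size)^2
  frac <- c(white = sum(m == DIGIT_WHITE) / tot,
            gray = sum(m == DIGIT_GRAY) / tot,
            black = sum(m == DIGIT_BLACK) / tot)
  want <- if (variant %in% c("A", "B")) c(white = 0.57, gray = 0.14,
                                          black = 0.29)
          else c(white = 0.29, gray = 0.14, black = 0.57)
  if (any(abs(frac - want) > 0.01))
    stop(sprintf("size %d cannot honor the area fractions within 1%% (got W %.3f G %.3f B %.3f)",
                 size, frac["white"], frac["gray"], frac["black"]))

  order_df <- data.frame(
    darker = c("contrast_gray_in_white", "assim_gray_in_black"),
    lighter = c("contrast_gray_in_black", "assim_gray_in_white"),
    illusion = c("contrast", "assimilation"),
    stringsAsFactors = FALSE)
  new_target_bundle(
    digit_map(m), default_calibration(), rois, order_df,
    angular_geometry(c(size, size), field_of_view_deg = 10),
    metadata = list(variant = variant, size = size, outer_band_px = wb,
                    frame_px = wf, roi_w = roi_w, roi_h = roi_h,
                    n_stripes = n_stripes,
                    large_surrounds = large_surrounds,
                    area_fractions = frac))
}

disk_mask <- function(nr, nc, cy, cx, r) {
  outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+") <= r^2
}

#' Generate the Todorovic circles-and-crosses target
#'
#' A 2048 x 4096 (default) panorama with eight identical gray elements on a
#' light-gray background: four circles along the top (two controls on the
#' uniform background at left, one over a Black and one over a White
#' surround panel at right) and four crosses along the bottom (two
#' controls, and two seen through cross-shaped slits cut into a solid White
#' or Black foreground panel). The four illusion panels fill the right-half
#' quadrants edge to edge. Cross arms are 380 x 25 px at the reference
#' scale; the slit leaves ~14 px (~4 arcmin) of background around each arm.
#' The scene uses four luminances only: White, Gray, Black and the
#' background.
#'
#' Declared appearances: the circle over the White surround is darker
#' (simultaneous contrast); the cross behind the Black foreground is darker
#' (assimilation).
#'
#' @param size Integer \code{c(rows, cols)}; default \code{c(2048, 4096)}.
#' @return A \code{\link{target_bundle}} with \code{scan_rows} through the
#'   circle and cross centers.
#' @export
make_todorovic <- function(size = c(2048L, 4096L)) {
  size <- as.integer(size)
  stopifnot(length(size) == 2L)
  nr <- size[1]; nc <- size[2]
  s <- nr / 2048
  arm_l <- as.integer(round_half_up(380 * s))
  arm_w <- as.integer(round_half_up(25 * s))
  if (nr < 512L || nc < 2L * arm_l + 8L)
    stop("size cannot accommodate the stated cross dimensions")
  bg <- 200L
  m <- matrix(bg, nr, nc)
  cy_circ <- as.integer(round_half_up(nr * 0.25))
  cy_cross <- as.integer(round_half_up(nr * 0.75))
  cx <- as.integer(round_half_up(nc * c(0.125, 0.375, 0.625, 0.875)))
  r_disk <- as.integer(round_half_up(157 * s))   # 46 arcmin at 0.293'/px

  # the four illusion panels fill the right-half quadrants edge to edge:
  # Black/White contrast surrounds (top), White/Black slit foregrounds
  # (bottom), with the rightmost panels touching the image border
  mid_r <- nr %/% 2L
  q3 <- (nc %/% 2L + 1L):(3L * nc %/% 4L)
  q4 <- (3L * nc %/% 4L + 1L):nc
  m[1:mid_r, q3] <- DIGIT_BLACK
  m[1:mid_r, q4] <- DIGIT_WHITE
  rois <- list()
  circ_names <- c("circle_control_1", "circle_control_2",
                  "circle_in_black", "circle_in_white")
  for (i in 1:4) {
    dm <- disk_mask(nr, nc, cy_circ, cx[i], r_disk)
    m[dm] <- DIGIT_GRAY
    rois[[circ_names[i]]] <- dm
  }

  draw_cross <- function(mm, cy, cxx) {
    hw <- arm_w %/% 2L
    hl <- arm_l %/% 2L
    mm[(cy - hw):(cy - hw + arm_w - 1L),
       (cxx - hl):(cxx - hl + arm_l - 1L)] <- DIGIT_GRAY
    mm[(cy - hl):(cy - hl + arm_l - 1L),
       (cxx - hw):(cxx - hw + arm_w - 1L)] <- DIGIT_GRAY
    mm
  }
  # the assimilation foreground is a solid square with a cross-shaped slit
  # cut into it; the gray cross sits behind the slit with ~4 arcmin of
  # background clearance around each 380 x 25 arm, and the scan row through
  # the arm centers crosses background, gray, and solid foreground
  slit_half <- as.integer(round_half_up(26 * s))   # slit half-width
  slot_half <- as.integer(round_half_up(203 * s))  # slit half-length
  cut_slit <- function(mm, cy, cxx) {
    mm[(cy - slit_half):(cy + slit_half),
       (cxx - slot_half):(cxx + slot_half)] <- bg
    mm[(cy - slot_half):(cy + slot_half),
       (cxx - slit_half):(cxx + slit_half)] <- bg
    mm
  }
  m[(mid_r + 1L):nr, q3] <- DIGIT_WHITE
  m[(mid_r + 1L):nr, q4] <- DIGIT_BLACK
  m <- cut_slit(m, cy_cross, cx[3])
  m <- cut_slit(m, cy_cross, cx[4])
  cross_names <- c("cross_control_1", "cross_control_2",
                   "cross_in_white", "cross_in_black")
  for (i in 1:4) {
    before <- m
    m <- draw_cross(m, cy_cross, cx[i])
    rois[[cross_names[i]]] <- m == DIGIT_GRAY & before != DIGIT_GRAY
  }

  order_df <- data.frame(
    darker = c("circle_in_white", "cross_in_black"),
    lighter = c("circle_in_black", "cross_in_white"),
    illusion = c("contrast", "assimilation"),
    stringsAsFactors = FALSE)
  new_target_bundle(
    digit_map(m), default_calibration(), rois, order_df,
    angular_geometry(c(nr, nc), field_of_view_deg = 20 * nc / 4096),
    metadata = list(variant = "todorovic", size = size,
                    background_digit = bg, disk_radius = r_disk,
                    arm = c(arm_l, arm_w),
                    panel = c(mid_r, length(q3)),
                    slit = c(slit_half, slot_half)),
    scan_rows = c(circles = cy_circ, crosses = cy_cross))
}

#' Generate the centered-square range fixture
#'
#' A minimum-luminance background with a centered maximum-luminance square:
#' the two-level target used to visualize how glare turns a one-pixel edge
#' into a broad gradient. Both sizes must be odd for exact centering.
#'
#' @param field Field (background) side in pixels, odd; default 2049.
#' @param square Square side in pixels, odd; default 601.
#' @return A \code{\link{target_bundle}} with a one-pixel boundary-ring
#'   mask at the square's perimeter.
#' @export
make_centered_square <- function(field = 2049L, square = 601L) {
  field <- as.integer(field); square <- as.integer(square)
  if (field %% 2L == 0L || square %% 2L == 0L)
    stop("`field` and `square` must be odd for exact centering")
  if (square >= field) stop("`square` must be smaller than `field`")
  m <- matrix(DIGIT_BLACK, field, field)
  h <- square %/% 2L
  ctr <- (field + 1L) %/% 2L
  rr <- (ctr - h):(ctr + h)
  m[rr, rr] <- DIGIT_WHITE
  sq_mask <- matrix(FALSE, field, field); sq_mask[rr, rr] <- TRUE
  ring <- sq_mask
  ring[(ctr - h + 1L):(ctr + h - 1L), (ctr - h + 1L):(ctr + h - 1L)] <- FALSE
  new_target_bundle(
    digit_map(m), default_calibration(),
    rois = list(square = sq_mask, background = !sq_mask,
                boundary_ring = ring),
    appearance_order = NULL,
    angular_geometry(c(field, field)),
    metadata = list(variant = "centered_square", field = field,
                    square = square))
}

#' Generate a black-and-white Mondrian under an illumination gradient
#'
#' A random tiling of achromatic matte "papers" (different sizes and shapes)
#' lit by a vertical illumination gradient, bright at the bottom and dim at
#' the top, with two circular ROIs: a high-reflectance paper near the top and
#' a low-reflectance paper near the bottom whose gradient-adjusted scene
#' luminances are identical, each at 80\% of the log range. The display
#' table is log-linear in digits (digit proportional to log luminance), so
#' the illumination gradient is an additive digit ramp and the two equal
#' circles share one digit exactly.
#'
#' Declared appearance: the bottom circle is darker.
#'
#' @param seed Integer seed; the map is bit-identical for a given seed.
#' @param n_patches Number of papers (>= 20; default 110).
#' @param size Image side in pixels; default 2048.
#' @return A \code{\link{target_bundle}}.
#' @export
make_mondrian <- function(seed = 1L, n_patches = 110L, size = 2048L) {
  n_patches <- as.integer(n_patches)
  if (n_patches < 20L) stop("`n_patches` must be >= 20")
  size <- as.integer(size)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(seed)
    old
  })
  on.exit(if (!is.null(rng)) assign(".Random.seed", rng, globalenv())
          else rm(list = ".Random.seed", envir = globalenv()))

  nrb <- as.integer(round_half_up(sqrt(n_patches)))
  ncb <- as.integer(ceiling(n_patches / nrb))
  rand_breaks <- function(n, len) {
    # interior breakpoints jittered around an even split, min band len/(3n)
    base <- seq(0, len, length.out = n + 1)
    jit <- stats::runif(n - 1, -0.3, 0.3) * len / n
    sort(as.integer(round_half_up(c(0, base[2:n] + jit, len))))
  }
  rbreaks <- rand_breaks(nrb, size)
  m <- matrix(0L, size, size)
  digit_lo <- 40L; digit_hi <- 210L
  for (i in seq_len(nrb)) {
    cbreaks <- rand_breaks(ncb, size)
    digs <- sample(digit_lo:digit_hi, ncb, replace = TRUE)
    if (i == nrb) digs[sample(ncb, 1L)] <- digit_hi   # a bright bottom paper
    for (j in seq_len(ncb))
      m[(rbreaks[i] + 1L):rbreaks[i + 1L],
        (cbreaks[j] + 1L):cbreaks[j + 1L]] <- digs[j]
  }
  # illumination: +35 digits (log-linear display) from top to bottom
  grad <- round_half_up(35 * (seq_len(size) - 1L) / (size - 1L))
  m <- m + matrix(as.integer(grad), size, size)
  m[m > 235L] <- 235L
  m[m < 10L] <- 10L
  if (max(m) != 235L)
    stop("gradient tuning failed: no pixel reached the range anchor")

  # the two equal-luminance papers: digit 184 = anchor 235 minus 51 digits,
  # i.e. exactly 80% of the 2.3 log range below the image maximum
  d_circ <- 184L
  r_circ <- as.integer(round_half_up(130 * size / 2048))
  top_c <- c(round_half_up(0.22 * size), round_half_up(0.62 * size))
  bot_c <- c(round_half_up(0.78 * size), round_half_up(0.38 * size))
  m_top <- disk_mask(size, size, top_c[1], top_c[2], r_circ)
  m_bot <- disk_mask(size, size, bot_c[1], bot_c[2], r_circ)
  m[m_top] <- d_circ
  m[m_bot] <- d_circ

  cal <- display_calibration(0:255, 450 * 10^(2.3 * ((0:255) / 255 - 1)))
  order_df <- data.frame(darker = "circle_bottom", lighter = "circle_top",
                         illusion = "contrast", stringsAsFactors = FALSE)
  new_target_bundle(
    digit_map(m), cal,
    rois = list(circle_top = m_top, circle_bottom = m_bot),
    appearance_order = order_df,
    angular_geometry(c(size, size), field_of_view_deg = 10),
    metadata = list(variant = "mondrian", seed = seed,
                    n_patches = n_patches, size = size,
                    circle_digit = d_circ, anchor_digit = 235L,
                    gradient_digits = 35L, circle_radius = r_circ))
}

#' Invert a target (photographic negative)
#'
#' Replaces every digit d by 255 - d, keeping the calibration, geometry and
#' ROI masks. The appearance ordering of a negative is an empirical fact
#' about the inverted stimulus, so it must be re-declared by the caller.
#' Equal-digit ROI pairs remain equal in scene luminance under any
#' calibration.
#'
#' @param bundle A \code{\link{target_bundle}}.
#' @param appearance_order Optional replacement ordering data.frame
#'   (columns darker, lighter, illusion).
#' @return The inverted \code{\link{target_bundle}}.
#' @export
invert_target <- function(bundle, appearance_order = NULL) {
  stopifnot(inherits(bundle, "target_bundle"))
  meta <- bundle$metadata
  meta$variant <- paste0(meta$variant, "_negative")
  new_target_bundle(
    digit_map(255L - bundle$map$digits), bundle$calibration, bundle$rois,
    appearance_order, bundle$geometry, meta, bundle$scan_rows)
}

#' Write a target bundle to disk
#'
#' Writes the digit map (TIFF), calibration (CSV), each ROI mask (PNG) and a
#' metadata JSON into a directory.
#'
#' @param bundle A \code{\link{target_bundle}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_target <- function(bundle, dir) {
  stopifnot(inherits(bundle, "target_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    write_digit_map(bundle$map, file.path(dir, "map.tif")),
    write_calibration_csv(bundle$calibration, file.path(dir, "calibration.csv")))
  for (nm in names(bundle$rois)) {
    p <- file.path(dir, paste0("roi_", nm, ".png"))
    png::writePNG(bundle$rois[[nm]] * 1, p)
    paths <- c(paths, p)
  }
  meta <- bundle$metadata
  meta$scan_rows <- bundle$scan_rows
  if (!is.null(bundle$appearance_order))
    meta$appearance_order <- bundle$appearance_order
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(paths, file.path(dir, "metadata.json")))
}
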