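#' Run configuration for the full glare pipeline
#'
#' Collects every knob of a reproduction run. Defaults match the reference
#' conditions: observer age 25, pigment 0.5, replicate padding, log range
#' 2.3, cmap pseudocolor.
#'
#' @param target Either a \code{\link{target_bundle}} or a list
#'   \code{list(map = <path>, calibration = <path>)} pointing at a digit-map
#'   image and a calibration CSV.
#' @param outdir Output directory.
#' @param params \code{\link{glare_parameters}}.
#' @param range \code{\link{log_range}}.
#' @param padding \code{\link{pad_replicate}} or \code{\link{pad_constant}}.
#' @param lut \code{\link{pseudocolor_lut}} for the pseudocolor renderings.
#' @param field_of_view_deg Optional field of view; defaults to the
#'   reference pixel pitch.
#' @param seed Integer seed recorded in the manifest (generators that use
#'   randomness are seeded from it).
#' @return A list of class \code{"run_config"}.
#' @export
run_config <- function(target, outdir, params = glare_parameters(),
                       range = log_range(), padding = pad_replicate(),
                       lut = lut_cmap(), field_of_view_deg = NULL,
                       seed = 1L) {
  structure(list(target = target, outdir = outdir, params = params,
                 range = range, padding = padding, lut = lut,
                 field_of_view_deg = field_of_view_deg,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized keys: \code{map}, \code{calibration} (paths) or \code{target}
#' (a generator spec: \code{name} plus its arguments), \code{outdir},
#' \code{age}, \code{pigment}, \code{log_range}, \code{padding}
#' (\code{replicate} or a number), \code{lut} (\code{cmap}, \code{332} or a
#' CSV path), \code{field_of_view_deg}, \code{seed}.
#'
#' @param path YAML file path.
#' @return A \code{\link{run_config}}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$outdir)) stop("config must set `outdir`")
  target <- if (!is.null(y$target)) {
    spec <- y$target
    nm <- spec$name
    spec$name <- NULL
    do.call(switch(nm,
                   contrast_assimilation = make_contrast_assimilation,
                   todorovic = make_todorovic,
                   centered_square = make_centered_square,
                   mondrian = make_mondrian,
                   stop("unknown target generator: ", nm)),
            spec)
  } else if (!is.null(y$map) && !is.null(y$calibration)) {
    list(map = y$map, calibration = y$calibration)
  } else stop("config must set either `target` or `map` + `calibration`")
  padding <- if (is.null(y$padding) || identical(y$padding, "replicate"))
    pad_replicate() else pad_constant(as.numeric(y$padding))
  lut <- if (is.null(y$lut) || identical(y$lut, "cmap")) lut_cmap()
         else if (identical(as.character(y$lut), "332")) lut_332()
         else lut_from_csv(y$lut)
  run_config(target, y$outdir,
             params = glare_parameters(age = y$age %||% 25,
                                       pigment = y$pigment %||% 0.5),
             range = log_range(y$log_range %||% 2.3),
             padding = padding, lut = lut,
             field_of_view_deg = y$field_of_view_deg,
             seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full glare pipeline
#'
#' Executes generate/load -> calibrate -> convolve -> log-map -> visualize
#' -> analyze and writes the eight-image analysis set plus CSV reports and a
#' JSON manifest: the 8-bit map, its display rendering, the linear scene
#' luminance and retinal contrast (float TIFF + sidecars), both log-mapped
#' grayscales, both pseudocolor renderings, ROI statistics, histograms, the
#' paradox report (when the target declares appearances) and a manifest with
#' parameter provenance and md5 checksums. Deterministic given the
#' configuration.
#'
#' @param config A \code{\link{run_config}}.
#' @param kernel Optional prebuilt \code{\link{build_kernel}} (reused across
#'   runs on the same geometry).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, kernel = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage `%s` failed: %s", what, conditionMessage(e)),
           call. = FALSE))
  }
  out <- character()
  add <- function(p) out <<- c(out, p)

  # --- inputs ------------------------------------------------------------
  bundle <- NULL
  if (inherits(config$target, "target_bundle")) {
    bundle <- config$target
    map <- bundle$map
    cal <- bundle$calibration
  } else {
    map <- stage("load", load_digit_map(config$target$map))
    cal <- stage("load", read_calibration_csv(config$target$calibration))
  }
  geom <- if (!is.null(bundle) && is.null(config$field_of_view_deg))
    bundle$geometry
  else angular_geometry(dim(map$digits),
                        field_of_view_deg = config$field_of_view_deg)

  # --- calibrate + convolve ----------------------------------------------
  scene <- stage("calibrate", apply_calibration(map, cal))
  if (is.null(kernel))
    kernel <- stage("kernel", build_kernel(geom, config$params))
  retina <- stage("convolve", convolve_glare(scene, kernel, config$padding))

  # --- the eight-image set -----------------------------------------------
  p <- function(f) file.path(config$outdir, f)
  stage("write", {
    add(write_digit_map(map, p("map.tif")))
    add(write_digit_map(map, p("display.png")))
    add(write_linear_tiff(scene, p("scene_luminance.tif")))
    add(p("scene_luminance.tif.json"))
    add(write_linear_tiff(retina, p("retinal_contrast.tif")))
    add(p("retinal_contrast.tif.json"))
  })
  slog <- log_map(scene, config$range)
  rlog <- log_map(retina, config$range)
  stage("write", {
    add(write_log_mapped(slog, p("scene_luminance_log_mapped.png"))[1])
    add(p("scene_luminance_log_mapped.png.json"))
    add(write_log_mapped(rlog, p("retinal_contrast_log_mapped.png"))[1])
    add(p("retinal_contrast_log_mapped.png.json"))
    add(write_rgb_png(apply_lut(slog, config$lut),
                      p("scene_luminance_log_pseudocolor.png")))
    add(write_rgb_png(apply_lut(rlog, config$lut),
                      p("retinal_contrast_log_pseudocolor.png")))
  })

  # --- analysis ------------------------------------------------------------
  stage("analyze", {
    if (!is.null(bundle) && length(bundle$rois)) {
      stats <- do.call(rbind, lapply(names(bundle$rois), function(nm)
        roi_stats(retina, bundle$rois[[nm]], config$range, nm)))
      utils::write.csv(stats, p("roi_stats.csv"), row.names = FALSE)
      add(p("roi_stats.csv"))
    }
    if (!is.null(bundle) && !is.null(bundle$appearance_order)) {
      utils::write.csv(paradox_report(retina, bundle), p("paradox.csv"),
                       row.names = FALSE)
      add(p("paradox.csv"))
    }
    hl <- glare_histogram(retina, "linear", config$range)
    hg <- glare_histogram(retina, "log", config$range)
    utils::write.csv(
      data.frame(bin = 1:256,
                 linear_left_edge = hl$breaks[1:256],
                 linear_count = hl$counts, linear_norm = hl$normalized,
                 log_left_edge = hg$breaks[1:256],
                 log_count = hg$counts, log_norm = hg$normalized),
      p("histograms.csv"), row.names = FALSE)
    add(p("histograms.csv"))
  })

  manifest <- list(
    parameters = list(age = config$params$age,
                      pigment = config$params$pigment,
                      log_range = config$range$range_log10,
                      padding = config$padding$mode,
                      lut = config$lut$name,
                      arcmin_per_pixel = geom$arcmin_per_pixel,
                      kernel_radius_px = kernel$radius_px,
                      kernel_norm_sum = kernel$norm_sum,
                      energy_ratio = retina$energy_ratio,
                      seed = config$seed),
    target = if (!is.null(bundle)) bundle$metadata else config$target,
    files = lapply(stats::setNames(out, basename(out)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
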