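#' End-to-end pipeline configuration
#'
#' Bundles everything one monitoring run needs: the phantom (or input file),
#' the analysis region, the slow-time window specification, the amplitude
#' threshold, the frequency estimator, the segmentation parameters, optional
#' reference dimensions, and the seed. Every field is validated on
#' construction with a named error.
#'
#' @param phantom A [phantom_config()] describing the synthetic acquisition
#'   (ignored when `run_pipeline()` is given an explicit sequence).
#' @param region A [region_spec()] or `NULL` for the full frame.
#' @param window A [slowtime_window_spec()].
#' @param threshold_ratio Amplitude threshold fraction in `[0, 1]`.
#' @param estimator `"phasediff"` or `"binmax"`.
#' @param seg_frac Segmentation fraction in (0, 1) (see [segment_lesion()]).
#' @param seg_min_pixels Minimum component size for segmentation.
#' @param reference_depth_mm,reference_width_mm Optional positive reference
#'   dimensions; default `NULL` means "use the phantom's configured lesion
#'   extents" (parameter-recovery mode).
#' @param frames Frame selection passed to [construct_doppler_frames()]
#'   (default the during-exposure phase).
#' @param seed Integer seed; overrides the phantom's seed so one number
#'   reproduces the whole run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            region = NULL,
                            window = slowtime_window_spec(),
                            threshold_ratio = 0.1,
                            estimator = c("phasediff", "binmax"),
                            seg_frac = 0.05,
                            seg_min_pixels = 10L,
                            reference_depth_mm = NULL,
                            reference_width_mm = NULL,
                            frames = "during",
                            seed = phantom$seed) {
  estimator <- match.arg(estimator)
  if (!inherits(phantom, "phantom_config")) {
    stop("phantom: must be a phantom_config", call. = FALSE)
  }
  if (!is.null(region) && !inherits(region, "region_spec")) {
    stop("region: must be a region_spec or NULL", call. = FALSE)
  }
  if (!inherits(window, "slowtime_window_spec")) {
    stop("window: must be a slowtime_window_spec", call. = FALSE)
  }
  if (!is.numeric(threshold_ratio) || threshold_ratio < 0 ||
      threshold_ratio > 1) {
    stop("threshold_ratio: must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(seg_frac) || seg_frac <= 0 || seg_frac >= 1) {
    stop("seg_frac: must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(seg_min_pixels) || seg_min_pixels < 0) {
    stop("seg_min_pixels: must be a non-negative count", call. = FALSE)
  }
  for (nm in c("reference_depth_mm", "reference_width_mm")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      stop(nm, ": must be positive (or NULL)", call. = FALSE)
    }
  }
  if (!is.numeric(seed) || length(seed) != 1L) {
    stop("seed: must be a single integer", call. = FALSE)
  }
  phantom$seed <- as.integer(seed)
  structure(
    list(phantom = phantom, region = region, window = window,
         threshold_ratio = threshold_ratio, estimator = estimator,
         seg_frac = seg_frac, seg_min_pixels = as.integer(seg_min_pixels),
         reference_depth_mm = reference_depth_mm,
         reference_width_mm = reference_width_mm,
         frames = frames, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the [pipeline_config()] fields; nested blocks `geometry`,
#' `timing`, `lesion`, `motion` populate the phantom. Unknown top-level keys
#' are rejected so typos fail loudly.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("geometry", "timing", "scatterer_density", "lesion",
             "lesion_motion", "background_motion", "lesion_echogenicity_gain",
             "noise_sigma", "pulse_cycles", "region", "window",
             "threshold_ratio", "estimator", "seg_frac", "seg_min_pixels",
             "reference_depth_mm", "reference_width_mm", "frames", "seed")
  extra <- setdiff(names(y), known)
  if (length(extra) > 0L) {
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  geometry <- if (is.null(y$geometry)) {
    acquisition_geometry(4680L, 192L, 90.10, 64.00, 6.5e6)
  } else {
    do.call(acquisition_geometry, y$geometry)
  }
  timing <- if (is.null(y$timing)) acquisition_timing() else
    do.call(acquisition_timing, y$timing)
  mk_motion <- function(m) if (is.null(m)) NULL else do.call(motion_model, m)
  lesion <- y$lesion
  ph_args <- list(
    geometry = geometry, timing = timing,
    lesion_motion = mk_motion(y$lesion_motion) %||% motion_model("jitter"),
    background_motion = mk_motion(y$background_motion) %||%
      motion_model("static")
  )
  if (!is.null(y$scatterer_density)) ph_args$scatterer_density <- y$scatterer_density
  if (!is.null(lesion$center_depth_mm)) {
    ph_args$lesion_center_mm <- c(depth = lesion$center_depth_mm,
                                  width = lesion$center_width_mm)
  }
  if (!is.null(lesion$depth_mm)) ph_args$lesion_depth_mm <- lesion$depth_mm
  if (!is.null(lesion$width_mm)) ph_args$lesion_width_mm <- lesion$width_mm
  for (nm in c("lesion_echogenicity_gain", "noise_sigma", "pulse_cycles")) {
    if (!is.null(y[[nm]])) ph_args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$seed)) ph_args$seed <- y$seed
  phantom <- do.call(phantom_config, ph_args)
  args <- list(phantom = phantom)
  if (!is.null(y$region)) args$region <- do.call(region_spec, y$region)
  if (!is.null(y$window)) args$window <- do.call(slowtime_window_spec, y$window)
  for (nm in c("threshold_ratio", "estimator", "seg_frac", "seg_min_pixels",
               "reference_depth_mm", "reference_width_mm", "frames", "seed")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full monitoring pipeline
#'
#' Chains simulate (or load) -> Doppler image construction -> lesion
#' segmentation and measurement -> aggregate statistics. Deterministic under
#' `config$seed`. The report records all parameters, the package version, and
#' a fingerprint of the input data.
#'
#' @param config A [pipeline_config()].
#' @param seq Optional [rf_sequence()] to analyse instead of generating the
#'   configured phantom.
#' @return An object of class `twinkle_report`: list with `parameters`,
#'   `provenance`, `images` (the Doppler images), `measurements` (data frame
#'   of per-image depth/width), and `stats` (a [aggregate_stats()] result;
#'   references default to the phantom's configured lesion extents).
#' @export
run_pipeline <- function(config, seq = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.null(seq)) {
    seq <- stage("simulate", generate_sequence(config$phantom))
  } else if (!inherits(seq, "rf_sequence")) {
    stop("[input] seq must be an rf_sequence", call. = FALSE)
  }
  images <- stage("doppler", construct_doppler_frames(
    seq, region = config$region, spec = config$window,
    ratio = config$threshold_ratio, estimator = config$estimator,
    frames = config$frames))
  meas <- stage("lesion", measure_images(images, config$seg_frac,
                                         config$seg_min_pixels))
  ref_d <- config$reference_depth_mm %||% config$phantom$lesion_depth_mm
  ref_w <- config$reference_width_mm %||% config$phantom$lesion_width_mm
  stats <- stage("stats", aggregate_stats(meas, ref_d, ref_w))
  mdf <- data.frame(
    image = vapply(meas, function(m) m$frame_index, integer(1L)),
    depth_mm = vapply(meas, function(m) m$depth_mm, numeric(1L)),
    width_mm = vapply(meas, function(m) m$width_mm, numeric(1L))
  )
  structure(
    list(
      parameters = list(
        seed = config$seed, estimator = config$estimator,
        window_len = config$window$window_len, step = config$window$step,
        threshold_ratio = config$threshold_ratio,
        seg_frac = config$seg_frac, seg_min_pixels = config$seg_min_pixels,
        reference_depth_mm = ref_d, reference_width_mm = ref_w,
        frames = config$frames
      ),
      provenance = list(
        package_version = as.character(utils::packageVersion("twinkledop")),
        n_frames = dim(seq$data)[1],
        data_fingerprint = c(mean = mean(seq$data), sd = stats::sd(seq$data))
      ),
      images = images,
      measurements = mdf,
      stats = stats
    ),
    class = "twinkle_report"
  )
}

#' @export
print.twinkle_report <- function(x, ...) {
  cat(sprintf("Twinkling-artifact monitoring report (seed %d, %s estimator)\n",
              x$parameters$seed, x$parameters$estimator))
  cat(sprintf("  %d Doppler images from %d RF frames\n",
              nrow(x$measurements), x$provenance$n_frames))
  print(x$stats)
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Writes the parameters, provenance, per-image measurements, and aggregate
#' statistics (masks and pixel data are omitted) as pretty-printed JSON.
#'
#' @param report A `twinkle_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "twinkle_report"))
  out <- list(
    parameters = report$parameters,
    provenance = report$provenance,
    measurements = report$measurements,
    stats = unclass(report$stats)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
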