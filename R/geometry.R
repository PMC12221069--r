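#' Acquisition geometry of a beamformed RF frame
#'
#' Describes one frame of beamformed radio-frequency (RF) data: the fast-time
#' sampling grid along depth, the scan-line grid across width, and the physical
#' constants needed to convert between the two index spaces and millimetres.
#'
#' The fast-time sampling rate is tied to the depth extent through the two-way
#' travel time: `sampling_freq_hz = n_samples / (2 * depth_extent_m / c0)`.
#' When `sampling_freq_hz` is omitted it is derived from that relation; when
#' supplied it must be consistent with it to within 1%.
#'
#' @param n_samples Number of fast-time samples per RF line.
#' @param n_lines Number of scan lines per frame.
#' @param depth_extent_mm Axial (depth) extent of a full line, millimetres.
#' @param width_extent_mm Lateral extent of a full frame, millimetres.
#' @param center_freq_hz Imaging pulse center frequency in Hz.
#' @param speed_of_sound_m_s Assumed speed of sound in the medium, m/s.
#' @param sampling_freq_hz Fast-time sampling rate in Hz, or `NULL` to derive
#'   it from the depth extent and speed of sound.
#'
#' @return An object of class `acquisition_geometry`.
#' @examples
#' g <- acquisition_geometry(4680, 192, 90.10, 64.00, 6.5e6)
#' sample_span_to_mm(1000, g)  # 19.25 mm
#' @export
acquisition_geometry <- function(n_samples, n_lines, depth_extent_mm,
                                 width_extent_mm, center_freq_hz,
                                 speed_of_sound_m_s = 1540,
                                 sampling_freq_hz = NULL) {
  stopifnot(
    is.numeric(n_samples), length(n_samples) == 1L, n_samples >= 1,
    is.numeric(n_lines), length(n_lines) == 1L, n_lines >= 1,
    is.numeric(depth_extent_mm), depth_extent_mm > 0,
    is.numeric(width_extent_mm), width_extent_mm > 0,
    is.numeric(center_freq_hz), center_freq_hz > 0,
    is.numeric(speed_of_sound_m_s), speed_of_sound_m_s > 0
  )
  n_samples <- as.integer(n_samples)
  n_lines <- as.integer(n_lines)
  fs_derived <- n_samples / (2 * (depth_extent_mm / 1000) / speed_of_sound_m_s)
  if (is.null(sampling_freq_hz)) {
    sampling_freq_hz <- fs_derived
  } else {
    stopifnot(is.numeric(sampling_freq_hz), sampling_freq_hz > 0)
    if (abs(sampling_freq_hz - fs_derived) > 0.01 * fs_derived) {
      stop("sampling_freq_hz (", format(sampling_freq_hz),
           ") inconsistent with depth extent and speed of sound (expected ~",
           format(fs_derived), " Hz)", call. = FALSE)
    }
  }
  structure(
    list(
      n_samples = n_samples,
      n_lines = n_lines,
      depth_extent_mm = depth_extent_mm,
      width_extent_mm = width_extent_mm,
      center_freq_hz = center_freq_hz,
      speed_of_sound_m_s = speed_of_sound_m_s,
      sampling_freq_hz = sampling_freq_hz
    ),
    class = "acquisition_geometry"
  )
}

#' Millimetres per fast-time sample / per scan line
#'
#' @param geometry An [acquisition_geometry()].
#' @return Length of one sample (axially) or one line pitch (laterally), mm.
#' @export
mm_per_sample <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  geometry$depth_extent_mm / geometry$n_samples
}

#' @rdname mm_per_sample
#' @export
mm_per_line <- function(geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  geometry$width_extent_mm / geometry$n_lines
}

#' Convert an index span to millimetres
#'
#' Span-based linear conversions between the sample/line grids and physical
#' length: a span of `n` samples corresponds to `n * mm_per_sample(geometry)`
#' millimetres, and likewise for lines. On the reference endocavity-probe
#' geometry (4680 samples over 90.10 mm, 192 lines over 64.00 mm) a
#' 1000-sample span is 19.25 mm and a 40-line span is 13.33 mm.
#'
#' @param n_samples_selected,n_lines_selected Non-negative span (count of
#'   samples or lines); must not exceed the geometry's counts.
#' @param geometry An [acquisition_geometry()].
#' @return Length in millimetres.
#' @export
sample_span_to_mm <- function(n_samples_selected, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            is.numeric(n_samples_selected), length(n_samples_selected) == 1L)
  if (n_samples_selected < 0 || n_samples_selected > geometry$n_samples) {
    stop("sample span ", n_samples_selected, " out of range [0, ",
         geometry$n_samples, "]", call. = FALSE)
  }
  n_samples_selected * mm_per_sample(geometry)
}

#' @rdname sample_span_to_mm
#' @export
line_span_to_mm <- function(n_lines_selected, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            is.numeric(n_lines_selected), length(n_lines_selected) == 1L)
  if (n_lines_selected < 0 || n_lines_selected > geometry$n_lines) {
    stop("line span ", n_lines_selected, " out of range [0, ",
         geometry$n_lines, "]", call. = FALSE)
  }
  n_lines_selected * mm_per_line(geometry)
}

#' Acquisition timing of a HIFU exposure sequence
#'
#' Frame counts of the four acquisition phases (before, during, immediately
#' after, and late after exposure) and the inter-frame interval during
#' exposure. The defaults reproduce the reference acquisition: 81 frames as
#' 16 pre + 40 during + 9 immediately post + 16 late post, with 40 frames over
#' the 10-second exposure, i.e. a 250 ms interval.
#'
#' @param n_pre,n_during,n_post_immediate,n_post_late Frame counts per phase.
#' @param frame_interval_s Inter-frame interval during exposure, seconds. This
#'   is the slow-time sampling interval (the pulse/frame repetition interval of
#'   the Doppler relations).
#' @return An object of class `acquisition_timing`.
#' @export
acquisition_timing <- function(n_pre = 16L, n_during = 40L,
                               n_post_immediate = 9L, n_post_late = 16L,
                               frame_interval_s = 0.25) {
  counts <- c(n_pre, n_during, n_post_immediate, n_post_late)
  if (!all(is.finite(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("phase frame counts must be non-negative integers", call. = FALSE)
  }
  stopifnot(is.numeric(frame_interval_s), frame_interval_s > 0)
  structure(
    list(
      n_pre = as.integer(n_pre),
      n_during = as.integer(n_during),
      n_post_immediate = as.integer(n_post_immediate),
      n_post_late = as.integer(n_post_late),
      frame_interval_s = frame_interval_s
    ),
    class = "acquisition_timing"
  )
}

#' Total frame count of an acquisition timing
#'
#' @param timing An [acquisition_timing()].
#' @return Integer total of the four phase counts (81 at defaults).
#' @export
n_frames_total <- function(timing) {
  stopifnot(inherits(timing, "acquisition_timing"))
  timing$n_pre + timing$n_during + timing$n_post_immediate + timing$n_post_late
}

#' Per-frame phase labels implied by a timing
#'
#' @param timing An [acquisition_timing()].
#' @return Character vector of length [n_frames_total()] with values in
#'   `"pre"`, `"during"`, `"post_immediate"`, `"post_late"`, in order.
#' @export
phase_labels_for <- function(timing) {
  stopifnot(inherits(timing, "acquisition_timing"))
  rep(c("pre", "during", "post_immediate", "post_late"),
      times = c(timing$n_pre, timing$n_during,
                timing$n_post_immediate, timing$n_post_late))
}

#' Rectangular region of interest on the line/sample grid
#'
#' Index ranges are 0-based and half-open (`[start, stop)`), matching the
#' on-disk metadata convention; a full-frame region on the reference geometry
#' is `region_spec(0, 4680, 0, 192)`.
#'
#' @param sample_start,sample_stop Fast-time index range, 0-based half-open.
#' @param line_start,line_stop Scan-line index range, 0-based half-open.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(sample_start, sample_stop, line_start, line_stop) {
  v <- c(sample_start, sample_stop, line_start, line_stop)
  if (!all(is.finite(v)) || any(v != floor(v)) || any(v < 0)) {
    stop("region indices must be non-negative integers", call. = FALSE)
  }
  if (sample_stop <= sample_start || line_stop <= line_start) {
    stop("region is empty: stop indices must exceed start indices",
         call. = FALSE)
  }
  structure(
    list(
      sample_start = as.integer(sample_start),
      sample_stop = as.integer(sample_stop),
      line_start = as.integer(line_start),
      line_stop = as.integer(line_stop)
    ),
    class = "region_spec"
  )
}

# Validate a region against a geometry; error if out of bounds.
check_region <- function(region, geometry) {
  stopifnot(inherits(region, "region_spec"),
            inherits(geometry, "acquisition_geometry"))
  if (region$sample_stop > geometry$n_samples) {
    stop("region sample_stop (", region$sample_stop,
         ") exceeds n_samples (", geometry$n_samples, ")", call. = FALSE)
  }
  if (region$line_stop > geometry$n_lines) {
    stop("region line_stop (", region$line_stop, ") exceeds n_lines (",
         geometry$n_lines, ")", call. = FALSE)
  }
  invisible(region)
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("RF acquisition geometry\n")
  cat(sprintf("  %d samples x %d lines  (%.2f mm depth x %.2f mm width)\n",
              x$n_samples, x$n_lines, x$depth_extent_mm, x$width_extent_mm))
  cat(sprintf("  fc = %.3g MHz, c0 = %g m/s, fs = %.4g MHz\n",
              x$center_freq_hz / 1e6, x$speed_of_sound_m_s,
              x$sampling_freq_hz / 1e6))
  invisible(x)
}

#' @export
print.acquisition_timing <- function(x, ...) {
  cat(sprintf(
    "Acquisition timing: %d frames (%d pre / %d during / %d post / %d late), %g ms interval\n",
    n_frames_total(x), x$n_pre, x$n_during, x$n_post_immediate, x$n_post_late,
    x$frame_interval_s * 1000))
  invisible(x)
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Region: samples [%d, %d), lines [%d, %d)\n",
              x$sample_start, x$sample_stop, x$line_start, x$line_stop))
  invisible(x)
}
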