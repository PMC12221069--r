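#' RF frame sequence
#'
#' The pipeline's sole input: a real-valued 3-D stack of beamformed RF frames
#' indexed `[frame, line, sample]`, together with its acquisition geometry,
#' timing, and per-frame phase labels ordered
#' pre -> during -> post_immediate -> post_late.
#'
#' @param data Numeric 3-D array, dimensions
#'   `c(n_frames, geometry$n_lines, geometry$n_samples)`.
#' @param geometry An [acquisition_geometry()].
#' @param timing An [acquisition_timing()].
#' @param phase_labels Optional character vector of per-frame labels; defaults
#'   to the labels implied by `timing` (see [phase_labels_for()]).
#' @return An object of class `rf_sequence`.
#' @export
rf_sequence <- function(data, geometry, timing, phase_labels = NULL) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            inherits(timing, "acquisition_timing"),
            is.array(data), length(dim(data)) == 3L, is.numeric(data))
  n_frames <- n_frames_total(timing)
  d <- dim(data)
  if (d[1] != n_frames || d[2] != geometry$n_lines || d[3] != geometry$n_samples) {
    stop("data dimensions (", paste(d, collapse = " x "),
         ") do not match timing/geometry (", n_frames, " x ",
         geometry$n_lines, " x ", geometry$n_samples, ")", call. = FALSE)
  }
  expected <- phase_labels_for(timing)
  if (is.null(phase_labels)) {
    phase_labels <- expected
  } else if (!identical(as.character(phase_labels), expected)) {
    stop("phase_labels must be ordered pre -> during -> post_immediate -> ",
         "post_late and match the timing counts", call. = FALSE)
  }
  structure(
    list(data = data, geometry = geometry, timing = timing,
         phase_labels = phase_labels),
    class = "rf_sequence"
  )
}

#' @export
print.rf_sequence <- function(x, ...) {
  cat(sprintf("RF frame sequence: %d frames x %d lines x %d samples\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3]))
  print(x$geometry)
  print(x$timing)
  invisible(x)
}

#' Resolve frame indices by phase label
#'
#' @param seq An [rf_sequence()].
#' @param frames Either a character phase label (`"pre"`, `"during"`,
#'   `"post_immediate"`, `"post_late"`), or a vector of 0-based frame indices,
#'   or `NULL` for all frames.
#' @return Integer vector of 0-based frame indices.
#' @export
resolve_frames <- function(seq, frames = NULL) {
  stopifnot(inherits(seq, "rf_sequence"))
  n <- dim(seq$data)[1]
  if (is.null(frames)) return(seq_len(n) - 1L)
  if (is.character(frames)) {
    stopifnot(length(frames) == 1L)
    idx <- which(seq$phase_labels == frames) - 1L
    if (length(idx) == 0L) stop("no frames in phase '", frames, "'", call. = FALSE)
    return(idx)
  }
  frames <- as.integer(frames)
  if (length(frames) == 0L || any(frames < 0L) || any(frames >= n)) {
    stop("frame indices out of range [0, ", n - 1L, "]", call. = FALSE)
  }
  frames
}

#' Crop a sequence to a rectangular region
#'
#' Returns a new sequence containing only the selected lines and samples. The
#' geometry extents are rescaled to the selected span (so that, e.g., a
#' 1000-sample by 40-line region of the reference 4680 x 192 geometry reports
#' 19.25 mm x 13.33 mm); frame count and timing are unchanged, as are the
#' per-sample and per-line pitches and the sampling rate.
#'
#' @param seq An [rf_sequence()].
#' @param region A [region_spec()] within the sequence's geometry bounds.
#' @return An [rf_sequence()] on the cropped grid.
#' @export
select_region <- function(seq, region) {
  stopifnot(inherits(seq, "rf_sequence"))
  check_region(region, seq$geometry)
  g <- seq$geometry
  ns <- region$sample_stop - region$sample_start
  nl <- region$line_stop - region$line_start
  new_geom <- acquisition_geometry(
    n_samples = ns,
    n_lines = nl,
    depth_extent_mm = ns * mm_per_sample(g),
    width_extent_mm = nl * mm_per_line(g),
    center_freq_hz = g$center_freq_hz,
    speed_of_sound_m_s = g$speed_of_sound_m_s,
    sampling_freq_hz = g$sampling_freq_hz
  )
  sub <- seq$data[, (region$line_start + 1L):region$line_stop,
                  (region$sample_start + 1L):region$sample_stop, drop = FALSE]
  rf_sequence(sub, new_geom, seq$timing, seq$phase_labels)
}

# Sidecar metadata fields required on disk.
.sidecar_required <- c(
  "n_samples", "n_lines", "depth_extent_mm", "width_extent_mm",
  "center_freq_hz", "speed_of_sound_m_s", "sampling_freq_hz",
  "n_pre", "n_during", "n_post_immediate", "n_post_late",
  "frame_interval_s", "dtype", "n_frames", "order"
)

sidecar_path <- function(path) paste0(sub("\\.[A-Za-z0-9]+$", "", path), ".json")

#' Write / read an RF frame sequence
#'
#' On-disk format: a raw little-endian binary file holding the RF samples
#' (`dtype` `"float64"`, the default, or `"float32"`), sample index varying
#' fastest, then line, then frame; plus a JSON sidecar (same path with a
#' `.json` extension) carrying every geometry and timing field. A write/read
#' round trip reproduces the data bit-exactly at the stored precision and all
#' metadata fields. Reading validates the sidecar and names any missing field.
#'
#' @param seq An [rf_sequence()].
#' @param path Path of the binary file (conventional extension `.rfb`); the
#'   sidecar is written next to it.
#' @param dtype Storage type, `"float64"` (lossless for R arrays) or
#'   `"float32"`.
#' @return `write_sequence()` returns `path` invisibly; `read_sequence()`
#'   returns an [rf_sequence()].
#' @export
write_sequence <- function(seq, path, dtype = c("float64", "float32")) {
  stopifnot(inherits(seq, "rf_sequence"))
  dtype <- match.arg(dtype)
  g <- seq$geometry
  t <- seq$timing
  meta <- list(
    n_samples = g$n_samples, n_lines = g$n_lines,
    depth_extent_mm = g$depth_extent_mm, width_extent_mm = g$width_extent_mm,
    center_freq_hz = g$center_freq_hz,
    speed_of_sound_m_s = g$speed_of_sound_m_s,
    sampling_freq_hz = g$sampling_freq_hz,
    n_pre = t$n_pre, n_during = t$n_during,
    n_post_immediate = t$n_post_immediate, n_post_late = t$n_post_late,
    frame_interval_s = t$frame_interval_s,
    dtype = dtype,
    n_frames = dim(seq$data)[1],
    order = "sample,line,frame",
    phase_labels = seq$phase_labels
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  # [frame, line, sample] -> sample fastest on disk
  vec <- as.vector(aperm(seq$data, c(3L, 2L, 1L)))
  writeBin(vec, con, size = if (dtype == "float32") 4L else 8L,
           endian = "little")
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    stop("sidecar metadata file not found: ", sc, call. = FALSE)
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  missing <- setdiff(.sidecar_required, names(meta))
  if (length(missing) > 0L) {
    stop("sidecar ", sc, " is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(meta$order, "sample,line,frame")) {
    stop("unsupported on-disk order: ", meta$order, call. = FALSE)
  }
  size <- switch(meta$dtype, float64 = 8L, float32 = 4L,
                 stop("unsupported dtype: ", meta$dtype, call. = FALSE))
  n_total <- meta$n_frames * meta$n_lines * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  vec <- readBin(con, what = "numeric", n = n_total, size = size,
                 endian = "little")
  if (length(vec) != n_total) {
    stop("binary file ", path, " is truncated: expected ", n_total,
         " values, got ", length(vec), call. = FALSE)
  }
  data <- aperm(array(vec, dim = c(meta$n_samples, meta$n_lines, meta$n_frames)),
                c(3L, 2L, 1L))
  geometry <- acquisition_geometry(
    meta$n_samples, meta$n_lines, meta$depth_extent_mm, meta$width_extent_mm,
    meta$center_freq_hz, meta$speed_of_sound_m_s, meta$sampling_freq_hz
  )
  timing <- acquisition_timing(meta$n_pre, meta$n_during,
                               meta$n_post_immediate, meta$n_post_late,
                               meta$frame_interval_s)
  labels <- if (!is.null(meta$phase_labels)) meta$phase_labels else NULL
  rf_sequence(data, geometry, timing, labels)
}
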