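#' Segment the lesion in a Doppler image
#'
#' Delineates the twinkling region of one Doppler frequency image:
#' \enumerate{
#'   \item the |frequency| map is smoothed with a 3x3 median filter with
#'     edge-replicating borders — this removes isolated wrapped-phase
#'     outliers and off-lesion noise pixels. A uniform solid block survives
#'     up to its four corner pixels (exactly, where it abuts the image
#'     border), so its bounding box — hence the measured dimensions — is
#'     preserved;
#'   \item pixels of the smoothed map reaching `frac` times its maximum are
#'     kept. Because the twinkling response is broadband (per-pixel
#'     frequencies spread over the slow-time band), the lesion outline is
#'     carried by the upstream amplitude gate, and `frac` is only a small
#'     guard against numerically negligible frequencies — hence the low
#'     default;
#'   \item a 3x3 morphological closing bridges single-pixel speckle gaps;
#'   \item 4-connected components are labelled and every component of at
#'     least `min_pixels` pixels is retained (small specks of surviving
#'     noise are dropped).
#' }
#' All-zero images give an empty mask.
#'
#' @param image A [doppler_image()].
#' @param frac Fraction of the smoothed per-image maximum |frequency|, in
#'   (0, 1).
#' @param min_pixels Minimum component size in pixels.
#' @return Logical matrix on the image grid (`TRUE` inside the lesion).
#' @export
segment_lesion <- function(image, frac = 0.05, min_pixels = 10L) {
  stopifnot(inherits(image, "doppler_image"),
            is.numeric(frac), length(frac) == 1L, frac > 0, frac < 1,
            is.numeric(min_pixels), min_pixels >= 0)
  a <- median_filter3(abs(image$freq_hz))
  mx <- max(a)
  empty <- matrix(FALSE, nrow(a), ncol(a))
  if (mx == 0) return(empty)
  mask <- erode3(dilate3(a >= frac * mx))
  if (!any(mask)) return(empty)
  lab <- label_components4(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_pixels)
  if (length(keep) == 0L) return(empty)
  matrix(lab %in% keep, nrow(lab), ncol(lab))
}

#' Measure lesion depth and width from a segmentation mask
#'
#' Bounding-box (caliper-style) linear extents of the mask, converted to
#' millimetres with the region geometry: depth is the spanned fast-time
#' sample count times the per-sample pitch, width the spanned line count
#' times the line pitch. An empty mask measures (0, 0).
#'
#' @param mask Logical matrix `(n_lines x n_samples)` on the region grid.
#' @param geometry The region's [acquisition_geometry()].
#' @param frame_index Optional 0-based Doppler image index, for bookkeeping.
#' @return An object of class `lesion_measurement`: list with `frame_index`,
#'   `depth_mm`, `width_mm`, and the `mask`.
#' @export
measure_dimensions <- function(mask, geometry, frame_index = NA_integer_) {
  stopifnot(is.matrix(mask), is.logical(mask),
            inherits(geometry, "acquisition_geometry"),
            nrow(mask) == geometry$n_lines, ncol(mask) == geometry$n_samples)
  if (!any(mask)) {
    depth <- 0
    width <- 0
  } else {
    rows <- range(which(rowSums(mask) > 0))          # lines
    cols <- range(which(colSums(mask) > 0))          # samples
    depth <- (cols[2] - cols[1] + 1L) * mm_per_sample(geometry)
    width <- (rows[2] - rows[1] + 1L) * mm_per_line(geometry)
  }
  structure(
    list(frame_index = frame_index, depth_mm = depth, width_mm = width,
         mask = mask),
    class = "lesion_measurement"
  )
}

#' Segment and measure every Doppler image of a sequence
#'
#' @param images List of [doppler_image()] as from
#'   [construct_doppler_frames()].
#' @param frac,min_pixels Segmentation parameters (see [segment_lesion()]).
#' @return List of [lesion_measurement()], one per image.
#' @export
measure_images <- function(images, frac = 0.05, min_pixels = 10L) {
  stopifnot(is.list(images), length(images) > 0L)
  lapply(images, function(im) {
    measure_dimensions(segment_lesion(im, frac, min_pixels), im$geometry,
                       im$window_pair_index)
  })
}

#' Aggregate lesion measurements against a reference dimension
#'
#' Summary statistics of per-frame depth/width measurements versus reference
#' (e.g. photograph-derived) dimensions: sample mean and SD (n - 1
#' denominator), 95% confidence half-width `t(0.975, n-1) * sd / sqrt(n)`,
#' percentage error `|mean - reference| / reference * 100`, and the p-value
#' of a two-sided one-sample t-test of the measurements against the
#' reference. A zero-SD sample is reported with p-value 1 when it equals the
#' reference and 0 otherwise (the t statistic degenerates).
#'
#' @param measurements List of [lesion_measurement()] (n >= 2).
#' @param reference_depth_mm,reference_width_mm Positive reference dimensions.
#' @return An object of class `lesion_stats`: means, SDs, CI half-widths,
#'   percentage errors, p-values for depth and width, and `n`.
#' @export
aggregate_stats <- function(measurements, reference_depth_mm,
                            reference_width_mm) {
  stopifnot(is.list(measurements))
  if (length(measurements) < 2L) {
    stop("need at least 2 measurements for SD/CI/p statistics", call. = FALSE)
  }
  if (!is.numeric(reference_depth_mm) || reference_depth_mm <= 0 ||
      !is.numeric(reference_width_mm) || reference_width_mm <= 0) {
    stop("reference dimensions must be positive", call. = FALSE)
  }
  depths <- vapply(measurements, function(m) m$depth_mm, numeric(1L))
  widths <- vapply(measurements, function(m) m$width_mm, numeric(1L))
  n <- length(depths)
  one_sample <- function(x, ref) {
    m <- mean(x)
    s <- stats::sd(x)
    ci <- stats::qt(0.975, n - 1L) * s / sqrt(n)
    p <- if (s == 0) as.numeric(m == ref) else
      stats::t.test(x, mu = ref)$p.value
    list(mean = m, sd = s, ci95 = ci,
         pct_error = abs(m - ref) / ref * 100, p = p)
  }
  d <- one_sample(depths, reference_depth_mm)
  w <- one_sample(widths, reference_width_mm)
  structure(
    list(mean_depth_mm = d$mean, mean_width_mm = w$mean,
         sd_depth_mm = d$sd, sd_width_mm = w$sd,
         ci95_depth = d$ci95, ci95_width = w$ci95,
         pct_error_depth = d$pct_error, pct_error_width = w$pct_error,
         p_depth = d$p, p_width = w$p,
         reference_depth_mm = reference_depth_mm,
         reference_width_mm = reference_width_mm,
         n = n),
    class = "lesion_stats"
  )
}

#' @export
print.lesion_stats <- function(x, ...) {
  cat(sprintf("Lesion statistics over %d frames\n", x$n))
  cat(sprintf(
    "  depth: mean %.2f mm (ref %.2f), SD %.2f, 95%% CI +/- %.2f, err %.2f%%, p = %.3g\n",
    x$mean_depth_mm, x$reference_depth_mm, x$sd_depth_mm, x$ci95_depth,
    x$pct_error_depth, x$p_depth))
  cat(sprintf(
    "  width: mean %.2f mm (ref %.2f), SD %.2f, 95%% CI +/- %.2f, err %.2f%%, p = %.3g\n",
    x$mean_width_mm, x$reference_width_mm, x$sd_width_mm, x$ci95_width,
    x$pct_error_width, x$p_width))
  invisible(x)
}
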