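#' Axial motion model for phantom scatterers
#'
#' Describes how a group of scatterers moves along the beam axis across the
#' exposure frames:
#' \describe{
#'   \item{`static`}{zero displacement in every frame.}
#'   \item{`coherent`}{constant axial velocity `v`, positive toward the
#'     transducer (the Doppler convention, so depth decreases for `v > 0`);
#'     cumulative displacement along the motion after `k` exposure frames is
#'     `k * v * cos(angle) * frame_interval_s`. This is the motion whose
#'     slow-time frequency the Doppler relations predict as
#'     `2 v cos(theta) fc / c0`.}
#'   \item{`jitter`}{one zero-mean Gaussian axial displacement per frame
#'     (standard deviation `jitter_sigma_m`), shared by all scatterers of the
#'     group: a bulk vibration, the surrogate for radiation-force-driven
#'     motion of coagulated tissue that produces the twinkling artifact.}
#' }
#'
#' @param kind One of `"static"`, `"coherent"`, `"jitter"`.
#' @param velocity_m_s Axial velocity for `coherent` motion, m/s.
#' @param jitter_sigma_m Per-frame displacement SD for `jitter` motion, m.
#'   The 20 micrometre default gives slow-time phase excursions of order
#'   1 rad at a 6.5 MHz carrier.
#' @param angle_rad Insonation angle between beam axis and motion, radians.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(kind = c("static", "coherent", "jitter"),
                         velocity_m_s = 0, jitter_sigma_m = 20e-6,
                         angle_rad = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(velocity_m_s), length(velocity_m_s) == 1L,
            is.numeric(jitter_sigma_m), jitter_sigma_m >= 0,
            is.numeric(angle_rad))
  structure(
    list(kind = kind, velocity_m_s = velocity_m_s,
         jitter_sigma_m = jitter_sigma_m, angle_rad = angle_rad),
    class = "motion_model"
  )
}

# Per-exposure-frame axial DEPTH offsets (metres) for a motion model.
# Velocity is positive toward the transducer, so coherent motion gives a
# cumulative negative depth offset; jitter is absolute (vibration about
# rest), one shared draw per frame. Consumes RNG only in jitter mode.
motion_displacements <- function(model, n_frames, frame_interval_s) {
  switch(model$kind,
    static = rep(0, n_frames),
    coherent = -seq_len(n_frames) * model$velocity_m_s *
      cos(model$angle_rad) * frame_interval_s,
    jitter = stats::rnorm(n_frames, 0, model$jitter_sigma_m)
  )
}

#' Configuration of a synthetic RF acquisition
#'
#' Full seeded description of a synthetic HIFU-exposure acquisition: a field
#' of randomly placed point scatterers, a rectangular lesion whose scatterers
#' move during exposure (and gain echogenicity afterwards, as coagulated
#' tissue turns hyperechoic), a pulse-echo synthesis model, and additive
#' noise. Identical config + seed yields a bit-identical sequence.
#'
#' Defaults emulate the reference acquisition: the full 4680-sample x 192-line
#' frame (90.10 mm x 64.00 mm) at 6.5 MHz, 81 frames timed
#' 16 pre / 40 during / 9 post / 16 late at 250 ms, with a jittering lesion of
#' 12 mm x 7 mm centred in the documented lesion neighbourhood (around line
#' 110, samples 3000-4500).
#'
#' @param geometry An [acquisition_geometry()].
#' @param timing An [acquisition_timing()].
#' @param scatterer_density Expected scatterers per mm^2 of the imaged plane.
#' @param lesion_center_mm Numeric length-2 `(depth, width)` centre in mm.
#' @param lesion_depth_mm,lesion_width_mm True lesion extents in mm.
#' @param lesion_motion [motion_model()] applied to lesion scatterers during
#'   exposure frames.
#' @param background_motion [motion_model()] for non-lesion scatterers
#'   (default static).
#' @param lesion_echogenicity_gain Amplitude multiplier for lesion scatterers
#'   in post-exposure frames.
#' @param noise_sigma Additive white Gaussian noise SD, relative to the RMS
#'   echo amplitude of the noiseless pre-exposure frame.
#' @param pulse_cycles Carrier cycles within the Gaussian pulse envelope
#'   (full width at half maximum).
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(geometry = acquisition_geometry(4680L, 192L, 90.10,
                                                           64.00, 6.5e6),
                           timing = acquisition_timing(),
                           scatterer_density = 20,
                           lesion_center_mm = c(
                             depth = 3750 * geometry$depth_extent_mm /
                               geometry$n_samples,
                             width = 110 * geometry$width_extent_mm /
                               geometry$n_lines),
                           lesion_depth_mm = 12,
                           lesion_width_mm = 7,
                           lesion_motion = motion_model("jitter"),
                           background_motion = motion_model("static"),
                           lesion_echogenicity_gain = 2,
                           noise_sigma = 0.05,
                           pulse_cycles = 3,
                           seed = 1L) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            inherits(timing, "acquisition_timing"),
            inherits(lesion_motion, "motion_model"),
            inherits(background_motion, "motion_model"),
            is.numeric(scatterer_density), scatterer_density >= 0,
            length(lesion_center_mm) == 2L,
            is.numeric(lesion_depth_mm), lesion_depth_mm > 0,
            is.numeric(lesion_width_mm), lesion_width_mm > 0,
            is.numeric(lesion_echogenicity_gain), lesion_echogenicity_gain > 0,
            is.numeric(noise_sigma), noise_sigma >= 0,
            is.numeric(pulse_cycles), pulse_cycles > 0,
            is.numeric(seed), length(seed) == 1L)
  lc <- unname(as.numeric(lesion_center_mm))
  if (lc[1] - lesion_depth_mm / 2 < 0 ||
      lc[1] + lesion_depth_mm / 2 > geometry$depth_extent_mm ||
      lc[2] - lesion_width_mm / 2 < 0 ||
      lc[2] + lesion_width_mm / 2 > geometry$width_extent_mm) {
    stop("lesion rectangle extends outside the field of view", call. = FALSE)
  }
  structure(
    list(geometry = geometry, timing = timing,
         scatterer_density = scatterer_density,
         lesion_center_mm = c(depth = lc[1], width = lc[2]),
         lesion_depth_mm = lesion_depth_mm,
         lesion_width_mm = lesion_width_mm,
         lesion_motion = lesion_motion,
         background_motion = background_motion,
         lesion_echogenicity_gain = lesion_echogenicity_gain,
         noise_sigma = noise_sigma,
         pulse_cycles = pulse_cycles,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

#' Draw the random scatterer field of a phantom
#'
#' Scatterer count is Poisson with mean `scatterer_density * field area`;
#' axial positions and lateral positions are uniform over the field;
#' reflectivities are standard Gaussian. Each scatterer is assigned to the
#' scan line containing its lateral position and flagged as in-lesion when it
#' falls inside the configured lesion rectangle.
#'
#' @param config A [phantom_config()].
#' @param seeded If `TRUE` (default) the draw is made under `config$seed`
#'   (restoring the caller's RNG state); internal callers that manage the RNG
#'   stream themselves pass `FALSE`.
#' @return A data frame with columns `depth_m` (axial position, metres),
#'   `line` (0-based line index), `lateral_mm`, `reflectivity`, `in_lesion`.
#' @export
generate_scatterers <- function(config, seeded = TRUE) {
  stopifnot(inherits(config, "phantom_config"))
  if (seeded) return(with_seed(config$seed, generate_scatterers(config, FALSE)))
  g <- config$geometry
  area_mm2 <- g$depth_extent_mm * g$width_extent_mm
  n <- stats::rpois(1L, config$scatterer_density * area_mm2)
  depth_mm <- stats::runif(n, 0, g$depth_extent_mm)
  lateral_mm <- stats::runif(n, 0, g$width_extent_mm)
  refl <- stats::rnorm(n)
  line <- pmin(as.integer(floor(lateral_mm / mm_per_line(g))), g$n_lines - 1L)
  lc <- config$lesion_center_mm
  in_lesion <- abs(depth_mm - lc[["depth"]]) <= config$lesion_depth_mm / 2 &
    abs(lateral_mm - lc[["width"]]) <= config$lesion_width_mm / 2
  data.frame(depth_m = depth_mm / 1000, line = line, lateral_mm = lateral_mm,
             reflectivity = refl, in_lesion = in_lesion)
}

#' Synthesize one RF frame from point scatterers
#'
#' Pulse-echo convolution model: each RF line is the sum, over the scatterers
#' assigned to that line, of `reflectivity * exp(-0.5 ((t - tau)/sigma)^2) *
#' cos(2 pi fc (t - tau))` where `tau = 2 (depth + displacement) / c0` is the
#' two-way echo time and `sigma` is set by `pulse_cycles` cycles FWHM.
#' Displacements are applied as continuous delays, so sub-sample motion is
#' rendered exactly in phase. Scatterers displaced outside the field of view
#' are silently excluded. Optional additive white Gaussian noise is appended.
#'
#' @param scatterers Data frame as from [generate_scatterers()].
#' @param geometry An [acquisition_geometry()].
#' @param displacements Per-scatterer axial offset in metres (scalar or vector
#'   recycled to the scatterer count).
#' @param pulse_cycles Carrier cycles FWHM of the Gaussian envelope.
#' @param amplitude Per-scatterer amplitude multiplier (scalar or vector),
#'   applied on top of reflectivity.
#' @param noise_sd Absolute SD of additive white Gaussian noise (0 for none;
#'   consumes RNG when positive).
#' @return Numeric matrix `n_lines x n_samples`.
#' @export
synthesize_frame <- function(scatterers, geometry, displacements = 0,
                             pulse_cycles = 3, amplitude = 1, noise_sd = 0) {
  stopifnot(inherits(geometry, "acquisition_geometry"),
            is.data.frame(scatterers))
  g <- geometry
  frame <- matrix(0, g$n_lines, g$n_samples)
  n <- nrow(scatterers)
  if (n > 0L) {
    disp <- rep_len(displacements, n)
    amp <- rep_len(amplitude, n) * scatterers$reflectivity
    z <- scatterers$depth_m + disp
    depth_extent_m <- g$depth_extent_mm / 1000
    keep <- z >= 0 & z <= depth_extent_m
    if (any(keep)) {
      z <- z[keep]; amp <- amp[keep]; line <- scatterers$line[keep]
      fs <- g$sampling_freq_hz
      fc <- g$center_freq_hz
      sigma_t <- (pulse_cycles / fc) / (2 * sqrt(2 * log(2)))
      halfw <- as.integer(ceiling(4 * sigma_t * fs))
      offs <- -halfw:halfw
      tau <- 2 * z / g$speed_of_sound_m_s
      idx0 <- tau * fs                      # continuous 0-based sample index
      base <- floor(idx0)
      for (l in unique(line)) {
        sel <- which(line == l)
        k <- length(sel)
        jmat <- matrix(offs, length(offs), k) +
          matrix(base[sel], length(offs), k, byrow = TRUE)
        tdiff <- (jmat - matrix(idx0[sel], length(offs), k, byrow = TRUE)) / fs
        val <- matrix(amp[sel], length(offs), k, byrow = TRUE) *
          exp(-0.5 * (tdiff / sigma_t)^2) * cos(2 * pi * fc * tdiff)
        ok <- jmat >= 0L & jmat < g$n_samples
        if (any(ok)) {
          sums <- rowsum(val[ok], jmat[ok])
          frame[l + 1L, as.integer(rownames(sums)) + 1L] <-
            frame[l + 1L, as.integer(rownames(sums)) + 1L] + as.vector(sums)
        }
      }
    }
  }
  if (noise_sd > 0) {
    frame <- frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                            nrow(frame), ncol(frame))
  }
  frame
}

#' Generate a full synthetic RF frame sequence
#'
#' Renders every frame of the configured acquisition. Pre-exposure and
#' post-exposure frames use the background motion state (scatterers at rest);
#' during-exposure frames apply the lesion motion model cumulatively (coherent)
#' or per frame (jitter) to lesion scatterers; both post phases multiply the
#' lesion scatterers' amplitude by `lesion_echogenicity_gain`. White noise at
#' `noise_sigma` times the noiseless pre-frame RMS amplitude is added to every
#' frame. The whole draw is made under `config$seed`, so the result is
#' bit-reproducible; at the default timing the sequence has
#' 16 + 40 + 9 + 16 = 81 frames.
#'
#' @param config A [phantom_config()].
#' @return An [rf_sequence()] with phase labels set from the timing.
#' @export
generate_sequence <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    g <- config$geometry
    t <- config$timing
    sc <- generate_scatterers(config, seeded = FALSE)
    les <- sc[sc$in_lesion, , drop = FALSE]
    bg <- sc[!sc$in_lesion, , drop = FALSE]

    les_disp <- motion_displacements(config$lesion_motion, t$n_during,
                                     t$frame_interval_s)
    bg_disp <- motion_displacements(config$background_motion, t$n_during,
                                    t$frame_interval_s)
    bg_static <- config$background_motion$kind == "static"
    les_static <- config$lesion_motion$kind == "static"

    pc <- config$pulse_cycles
    bg_rest <- synthesize_frame(bg, g, 0, pc)
    les_rest <- synthesize_frame(les, g, 0, pc)
    pre_frame <- bg_rest + les_rest
    post_frame <- bg_rest + config$lesion_echogenicity_gain * les_rest
    noise_sd <- config$noise_sigma * sqrt(mean(pre_frame^2))

    n_frames <- n_frames_total(t)
    data <- array(0, dim = c(n_frames, g$n_lines, g$n_samples))
    labels <- phase_labels_for(t)
    k_during <- 0L
    for (fi in seq_len(n_frames)) {
      phase <- labels[fi]
      if (phase == "pre") {
        fr <- pre_frame
      } else if (phase == "during") {
        k_during <- k_during + 1L
        fr <- if (bg_static) bg_rest else
          synthesize_frame(bg, g, bg_disp[k_during], pc)
        fr <- fr + if (les_static) les_rest else
          synthesize_frame(les, g, les_disp[k_during], pc)
      } else {
        fr <- post_frame
      }
      if (noise_sd > 0) {
        fr <- fr + matrix(stats::rnorm(length(fr), 0, noise_sd),
                          nrow(fr), ncol(fr))
      }
      data[fi, , ] <- fr
    }
    rf_sequence(data, g, t)
  })
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Synthetic RF phantom configuration\n")
  print(x$geometry)
  print(x$timing)
  cat(sprintf("  scatterers: %g / mm^2; lesion %g x %g mm at (%.1f, %.1f) mm\n",
              x$scatterer_density, x$lesion_depth_mm, x$lesion_width_mm,
              x$lesion_center_mm[["depth"]], x$lesion_center_mm[["width"]]))
  cat(sprintf("  lesion motion: %s; noise sigma %g; seed %d\n",
              x$lesion_motion$kind, x$noise_sigma, x$seed))
  invisible(x)
}
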