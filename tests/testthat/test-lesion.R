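# A doppler_image wrapper around a bare frequency matrix, for segmentation
# tests on hand-built inputs.
image_of <- function(freq, g = NULL) {
  nl <- nrow(freq); ns <- ncol(freq)
  if (is.null(g)) g <- tiny_geometry(ns, nl)
  doppler_image(freq, 0L, region_spec(0, ns, 0, nl), g, "phasediff", 0.25)
}

test_that("neighbourhood filters match their brute-force oracles", {
  set.seed(91)
  for (i in 1:8) {
    m <- matrix(rnorm(12 * 9), 12, 9)
    expect_equal(twinkledop:::median_filter3(m), brute_median3(m))
    mask <- matrix(runif(12 * 9) < 0.45, 12, 9)
    lab <- twinkledop:::label_components4(mask)
    ref <- brute_label4(mask)
    # same partition: component memberships agree up to label renaming
    expect_identical(lab > 0L, mask)
    expect_identical(length(unique(lab[mask])), length(unique(ref[mask])))
    split_lab <- unname(split(seq_along(lab)[mask], lab[mask]))
    split_ref <- unname(split(seq_along(ref)[mask], ref[mask]))
    expect_setequal(lapply(split_lab, sort), lapply(split_ref, sort))
  }
})

test_that("segmentation keeps a uniform block (up to corners) and drops specks", {
  # all-zero image -> empty mask
  expect_false(any(segment_lesion(image_of(matrix(0, 12, 20)))))
  # full-height block (all corners on the border) -> recovered exactly,
  # thanks to the clamped-border median
  fb <- matrix(0, 15, 30)
  fb[1:15, 3:20] <- 1.2
  expect_identical(segment_lesion(image_of(fb)), fb != 0)
  # interior uniform block: the 3x3 median shaves the 4 corner pixels but
  # never the bounding box, so measured dimensions are exact
  f <- matrix(0, 15, 30)
  f[4:10, 8:25] <- 1.2
  seg <- segment_lesion(image_of(f))
  block <- f != 0
  corners <- matrix(FALSE, 15, 30)
  corners[c(4, 10), c(8, 25)] <- TRUE
  expect_identical(seg, block & !corners)
  g <- tiny_geometry(30L, 15L)
  m <- measure_dimensions(seg, g)
  expect_equal(m$depth_mm, 18 * mm_per_sample(g))
  expect_equal(m$width_mm, 7 * mm_per_line(g))
  # two components, sizes 50 and 8, min_pixels 10 -> only the large one
  # (corner erosion leaves 46 and 4 pixels)
  f2 <- matrix(0, 20, 30)
  f2[3:7, 3:12] <- 0.9             # 5 x 10 = 50 px
  f2[14:17, 20:21] <- 0.9          # 4 x 2 = 8 px
  seg2 <- segment_lesion(image_of(f2), min_pixels = 10)
  expect_true(all(which(seg2) %in% which(f2 == 0.9 & row(f2) <= 7)))
  expect_gte(sum(seg2), 46)
  expect_false(any(seg2[14:17, 20:21]))
  # min_pixels larger than every component -> empty mask
  expect_false(any(segment_lesion(image_of(f2), min_pixels = 100)))
  expect_error(segment_lesion(image_of(f2), frac = 1.2), "frac")
})

test_that("dimension measurement converts bounding boxes to millimetres", {
  g <- table_geometry()
  empty <- matrix(FALSE, 192, 4680)
  m0 <- measure_dimensions(empty, g)
  expect_identical(c(m0$depth_mm, m0$width_mm), c(0, 0))
  # mask spanning 1000 samples x 40 lines on the reference geometry
  mask <- empty
  mask[91:130, 3401:4400] <- TRUE
  m <- measure_dimensions(mask, g)
  expect_equal(m$depth_mm, 19.25, tolerance = 1e-3)
  expect_equal(m$width_mm, 13.33, tolerance = 1e-3)
  # single pixel spans one sample and one line
  mask1 <- empty
  mask1[5, 7] <- TRUE
  m1 <- measure_dimensions(mask1, g)
  expect_equal(m1$depth_mm, mm_per_sample(g))
  expect_equal(m1$width_mm, mm_per_line(g))
  # the bounding box ignores holes: an L-shape spans its extremes
  maskL <- empty
  maskL[10, 100:200] <- TRUE
  maskL[10:20, 200] <- TRUE
  mL <- measure_dimensions(maskL, g)
  expect_equal(mL$depth_mm, 101 * mm_per_sample(g))
  expect_equal(mL$width_mm, 11 * mm_per_line(g))
})

test_that("depth scales with the per-sample pitch (equivariance)", {
  g1 <- tiny_geometry(100L, 10L)
  g2 <- acquisition_geometry(100L, 10L, 2 * g1$depth_extent_mm,
                             g1$width_extent_mm, 6.5e6)
  mask <- matrix(FALSE, 10, 100)
  mask[3:6, 20:60] <- TRUE
  expect_equal(measure_dimensions(mask, g2)$depth_mm,
               2 * measure_dimensions(mask, g1)$depth_mm)
  expect_equal(measure_dimensions(mask, g2)$width_mm,
               measure_dimensions(mask, g1)$width_mm)
})

test_that("aggregate statistics reproduce hand computations", {
  g <- tiny_geometry(10L, 4L)
  mk <- function(d, w) structure(list(frame_index = 0L, depth_mm = d,
                                      width_mm = w,
                                      mask = matrix(TRUE, 1, 1)),
                                 class = "lesion_measurement")
  ms <- list(mk(11.8, 5.9), mk(12.0, 6.0), mk(12.2, 6.1))
  st <- aggregate_stats(ms, 12.0, 6.0)
  expect_equal(st$mean_depth_mm, 12.0)
  expect_equal(st$sd_depth_mm, 0.2)
  expect_equal(st$pct_error_depth, 0)
  expect_equal(st$ci95_depth, qt(0.975, 2) * 0.2 / sqrt(3))
  expect_equal(st$p_depth, 1)
  expect_identical(st$n, 3L)
  # percentage-error identity on published-style numbers:
  # mean 12.00 vs reference 11.43 -> 4.99%
  ms2 <- list(mk(12.0 - 0.22, 7), mk(12.0, 7), mk(12.0 + 0.22, 7))
  st2 <- aggregate_stats(ms2, 11.43, 7)
  expect_equal(st2$pct_error_depth, abs(12 - 11.43) / 11.43 * 100)
  expect_equal(st2$pct_error_depth, 4.99, tolerance = 1e-3)
  expect_equal(st2$pct_error_width, 0)
  expect_equal(st2$p_width, 1)   # constant at the reference
  # constant away from the reference: degenerate t -> p = 0
  st3 <- aggregate_stats(list(mk(5, 5), mk(5, 5)), 6, 5)
  expect_equal(st3$p_depth, 0)
  expect_equal(st3$sd_depth_mm, 0)
  # the CI identity holds at each n, and the half-width shrinks roughly as
  # 1/sqrt(n) (exactly, up to the t quantile and n-1 SD correction)
  x <- c(rep(c(11.8, 12.2), 8))
  ms4 <- lapply(x, function(d) mk(d, 6))
  ms8 <- lapply(c(x, x, x, x), function(d) mk(d, 6))
  s4 <- aggregate_stats(ms4, 12, 6)
  s8 <- aggregate_stats(ms8, 12, 6)
  expect_equal(s4$ci95_depth, qt(0.975, 15) * s4$sd_depth_mm / sqrt(16))
  expect_equal(s8$ci95_depth, qt(0.975, 63) * s8$sd_depth_mm / sqrt(64))
  ratio <- s8$ci95_depth / s4$ci95_depth
  expect_gt(ratio, 0.42)
  expect_lt(ratio, 0.52)
  # errors
  expect_error(aggregate_stats(list(mk(1, 1)), 1, 1), "at least 2")
  expect_error(aggregate_stats(ms, -1, 6), "positive")
})

test_that("p-values come from the two-sided one-sample t-test", {
  mk <- function(d) structure(list(frame_index = 0L, depth_mm = d,
                                   width_mm = d, mask = matrix(TRUE, 1, 1)),
                              class = "lesion_measurement")
  set.seed(12)
  x <- rnorm(16, mean = 12.1, sd = 0.2)
  st <- aggregate_stats(lapply(x, mk), 12.0, 12.0)
  expect_equal(st$p_depth, t.test(x, mu = 12)$p.value)
})
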