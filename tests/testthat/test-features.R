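# The five ROI feature quantifications against brute-force oracles.

test_that("the noise floor is the background amplitude s.d.", {
  z <- array(0, dim = c(10, 4, 4))
  expect_equal(estimate_noise_floor(z, 1:10), 0)
  set.seed(1)
  g <- array(stats::rnorm(10 * 50 * 50, 0, 2), dim = c(10, 50, 50))
  expect_equal(estimate_noise_floor(g, 1:10), 2, tolerance = 0.02)
  expect_equal(estimate_noise_floor(g + 100, 1:10), 2, tolerance = 0.02)
  expect_equal(estimate_noise_floor(g, 1:10, mode = "variance"),
               estimate_noise_floor(g, 1:10)^2)
  const <- array(7, dim = c(5, 3, 3))
  expect_equal(estimate_noise_floor(const, 1:5), 0)   # constant offset
  expect_error(estimate_noise_floor(g, integer(0)), "empty background")
})

enface_with <- function(data, pitch_mm) {
  enface_image(data, depth_range_um = c(100, 200), projection = "average",
               coords = "polar", pitch_mm = pitch_mm, radius_mm = 6.25)
}

test_that("grid coefficient of variation matches the direct formula", {
  # constant ROI
  img <- enface_with(matrix(5, 40, 60), pitch_mm = c(0.1, 0.1))
  roi <- roi_rect(c(0, 4), c(0, 6))
  expect_equal(epithelial_inhomogeneity(img, roi), 0)
  # one 2-pixel cell holding the values 10 and 20: C_v = sd/mean = 7.0711/15
  img2 <- enface_with(matrix(c(10, 20), 2, 1), pitch_mm = c(1.5, 2))
  roi2 <- roi_rect(c(0, 3), c(0, 2))
  expect_equal(epithelial_inhomogeneity(img2, roi2), sqrt(50) / 15,
               tolerance = 1e-12)
  # multi-cell ROI: mean of per-cell sd/mean over complete cells
  set.seed(42)
  m <- matrix(stats::rgamma(120 * 80, 4, 1), 120, 80)
  img3 <- enface_with(m, pitch_mm = c(0.1, 0.05))
  roi3 <- roi_rect(c(0, 12), c(0, 4))
  cvs <- c()
  for (xi in seq(1, 120 - 29, by = 30)) for (fi in seq(1, 80 - 39, by = 40)) {
    cell <- m[xi:(xi + 29), fi:(fi + 39)]
    cvs <- c(cvs, stats::sd(cell) / mean(cell))
  }
  expect_equal(epithelial_inhomogeneity(img3, roi3), mean(cvs))
  expect_error(epithelial_inhomogeneity(img2, roi_rect(c(0, 0.5), c(0, 0.5))),
               "smaller than grid cell")
})

test_that("C_v is invariant to multiplicative gain", {
  set.seed(7)
  m <- matrix(stats::rgamma(60 * 80, 4, 1), 60, 80)
  img <- enface_with(m, pitch_mm = c(0.05, 0.05))
  img2 <- enface_with(3.7 * m, pitch_mm = c(0.05, 0.05))
  roi <- roi_rect(c(0, 3), c(0, 4))
  expect_equal(epithelial_inhomogeneity(img, roi),
               epithelial_inhomogeneity(img2, roi))
})

hfb_toy <- function(peaks, nz = 50) {
  # one A-scan per column; peaks = vector of max amplitudes
  arr <- array(0.1, dim = c(nz, length(peaks), 1))
  for (j in seq_along(peaks)) arr[10 + j, j, 1] <- peaks[j]
  scan_volume(arr, modality = "opam", pixel_um = 3.5,
              angle_pitch_rad = 2 * pi / 360, frame_pitch_um = 50,
              radius_mm = 6.25, band = "HFB")
}

test_that("vascular density and depth follow the counting oracle", {
  v <- hfb_toy(c(10, 10, 10, 1, 1, 1, 1, 1, 1, 1))   # 3 of 10 above 5x floor
  roi <- roi_rect(c(0, 10 * 2 * pi * 6.25 / 360), c(0, 0.05))
  vm <- vascular_metrics(v, roi, k = 5, noise_floor = 1.5, surface = 1L)
  expect_equal(vm$density, 0.3)
  # depth oracle: argmax rows are 11..13 for the valid columns
  expect_equal(vm$depth_um, mean((c(11, 12, 13) - 1) * 3.5))
  # all sub-threshold: density 0, depth missing
  v0 <- hfb_toy(rep(1, 10))
  vm0 <- vascular_metrics(v0, roi, k = 5, noise_floor = 1.5, surface = 1L)
  expect_equal(vm0$density, 0)
  expect_true(is.na(vm0$depth_um))
  expect_error(vascular_metrics(v, roi_rect(c(20, 21), c(20, 21))),
               "empty ROI")
})

test_that("raising the threshold multiplier cannot increase density", {
  sim <- shared_sim("IM")
  hfb <- resample_to_grid(reconstruct_opam(sim$opam_raw, band_spec("HFB")),
                          sim$oct$pixel_um)
  roi <- default_roi()
  fl <- estimate_noise_floor(sim$opam_raw, 1:16)
  d <- vapply(c(3, 5, 8, 12), function(k)
    vascular_metrics(hfb, roi, k = k, noise_floor = fl, surface = 6L)$density,
    numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("penetration depth reproduces index arithmetic", {
  # suprathreshold down to depth index 200 (0-based), surface at index 0
  nz <- 320
  aline <- c(rep(0, 3), rep(100, 198), rep(0, nz - 201))   # supra to idx 200
  arr <- array(rep(aline, 8 * 6), dim = c(nz, 8, 6))
  set.seed(3)
  arr[1:3, , ] <- stats::rnorm(3 * 8 * 6)                  # background band
  v <- scan_volume(arr, modality = "oct", pixel_um = 3.5,
                   angle_pitch_rad = 2 * pi / 360, frame_pitch_um = 50,
                   radius_mm = 6.25)
  roi <- roi_rect(c(0, 8 * 2 * pi * 6.25 / 360), c(0, 0.3))
  pen <- oct_penetration_depth(v, roi, k = 3, frame_avg = 5,
                               surface = matrix(1L, 8, 6))
  expect_equal(pen, 700, tolerance = 0.02)
  # all-noise ROI: no valid A-scans
  noise <- scan_volume(array(stats::rnorm(nz * 8 * 6), dim = c(nz, 8, 6)),
                       modality = "oct", pixel_um = 3.5,
                       angle_pitch_rad = 2 * pi / 360, frame_pitch_um = 50,
                       radius_mm = 6.25)
  expect_error(oct_penetration_depth(noise, roi, k = 30,
                                     surface = matrix(1L, 8, 6)),
               "no valid A-scans")
  expect_error(oct_penetration_depth(v, roi, frame_avg = 10),
               "at least 10 frames")
})

gland_fixture <- function(levels, upper = 65535) {
  # two frames, one circular gland of constant level
  arr <- array(30000, dim = c(100, 30, 2))
  z_um <- (seq_len(100) - 1) * 3.5
  x_mm <- (seq_len(30) - 0.5) * 2 * pi * 6.25 / 360
  for (f in 1:2) {
    m <- outer((z_um - 170)^2, (x_mm * 1000 - 1500)^2, "+") <= 90^2
    arr[, , f][m] <- levels[f]
  }
  vol <- scan_volume(arr, modality = "oct", pixel_um = 3.5,
                     angle_pitch_rad = 2 * pi / 360, frame_pitch_um = 50,
                     radius_mm = 6.25, meta = list(upper_limit = upper))
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ann <- gland_annotation(frame = 1:2,
                          x_mm = rep(list(1.5 + 0.09 * cos(th)), 2),
                          z_um = rep(list(170 + 90 * sin(th)), 2),
                          gland_id = c(1L, 1L))
  list(vol = vol, glands = merge_glands(ann))
}

test_that("gland transparency follows its defining equation", {
  fx <- gland_fixture(c(0, 0))
  tr <- gland_transparency(fx$vol, fx$glands)
  expect_equal(tr$mean_transparency, 100, tolerance = 1e-6)   # empty lumen
  fx2 <- gland_fixture(c(65535, 65535))
  expect_equal(gland_transparency(fx2$vol, fx2$glands)$mean_transparency, 0,
               tolerance = 1e-6)                              # saturated lumen
  fx3 <- gland_fixture(c(51, 51), upper = 255)
  tr3 <- gland_transparency(fx3$vol, fx3$glands, upper_limit = 255)
  expect_equal(tr3$mean_transparency, 80, tolerance = 1e-6)   # 1 - 51/255
  expect_true(tr3$has_transparent_gland)                      # >= 80 inclusive
  # frames of one merged gland pool their pixels
  fx4 <- gland_fixture(c(0, 65535))
  expect_equal(gland_transparency(fx4$vol, fx4$glands)$mean_transparency, 50,
               tolerance = 1)
})

test_that("consecutive-frame lumens merge by the centroid rule", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  circle <- function(x0, r) list(x_mm = x0 + r * cos(th),
                                 z_um = 200 + r * 1000 * sin(th))
  a <- circle(1.0, 0.09); b <- circle(1.02, 0.09)  # overlap, frames 1-2
  c <- circle(2.5, 0.09)                            # far away, frame 2
  ann <- gland_annotation(frame = c(1L, 2L, 2L),
                          x_mm = list(a$x_mm, b$x_mm, c$x_mm),
                          z_um = list(a$z_um, b$z_um, c$z_um))
  m <- merge_glands(ann)
  expect_equal(m$merged_id[1], m$merged_id[2])
  expect_false(m$merged_id[3] == m$merged_id[1])
  # same location two frames apart (non-consecutive) stays separate
  ann2 <- gland_annotation(frame = c(1L, 3L),
                           x_mm = list(a$x_mm, a$x_mm),
                           z_um = list(a$z_um, a$z_um))
  expect_equal(length(unique(merge_glands(ann2)$merged_id)), 2)
})

test_that("feature records assemble, validate and round-trip CSV", {
  rec <- assemble_feature_record("roi1", inhomogeneity = 0.098,
                                 vascular_density = 0.1,
                                 vascular_depth_um = 534,
                                 penetration_um = 726,
                                 stratification_visible = TRUE,
                                 class_label = "NSM")
  expect_false(rec$glands_present)
  expect_true(rec$stratification_visible)
  path <- tempfile(fileext = ".csv")
  write_feature_records(rec, path)
  back <- read_feature_records(path)
  expect_equal(back$penetration_um, rec$penetration_um)
  expect_equal(back$roi_id, rec$roi_id)
  expect_equal(back$tumour_pattern, rec$tumour_pattern)
  # depth must be missing when density is zero
  expect_error(assemble_feature_record("r", 0.1, vascular_density = 0,
                                       vascular_depth_um = 100,
                                       penetration_um = 500),
               "missing when density")
})
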