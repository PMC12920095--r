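# Two-stage rule-based classification.

record_with <- function(...) {
  defaults <- list(roi_id = "r", inhomogeneity = 0.1, vascular_density = 0.3,
                   vascular_depth_um = 500, penetration_um = 600,
                   mean_gland_transparency = NA_real_,
                   has_transparent_gland = FALSE, glands_present = FALSE,
                   stratification_visible = TRUE, tumour_pattern = FALSE)
  do.call(assemble_feature_record, utils::modifyList(defaults, list(...)))
}

test_that("screening separates normal from abnormal feature profiles", {
  th <- rule_thresholds()
  # published normal-squamous cohort means: deep vessels, homogeneous EP
  expect_equal(classify_normal_abnormal(
    record_with(vascular_depth_um = 534, inhomogeneity = 0.098), th), "normal")
  # intestinal-metaplasia cohort mean vascular depth
  expect_equal(classify_normal_abnormal(
    record_with(vascular_depth_um = 264, inhomogeneity = 0.098), th), "abnormal")
  # high epithelial inhomogeneity alone suffices
  expect_equal(classify_normal_abnormal(
    record_with(vascular_depth_um = 534, inhomogeneity = 0.19), th), "abnormal")
  # boundary ties call abnormal (screening bias)
  expect_equal(classify_normal_abnormal(
    record_with(vascular_depth_um = 400, inhomogeneity = 0.05), th), "abnormal")
  # density fallback when depth is missing
  r <- record_with(vascular_density = 0.5, inhomogeneity = 0.05)
  r$vascular_depth_um <- NA_real_
  expect_equal(classify_normal_abnormal(r, th), "abnormal")
  r$vascular_density <- NA_real_; r$inhomogeneity <- NA_real_
  expect_error(classify_normal_abnormal(r, th), "must carry")
})

test_that("five-class assignment follows the documented flowchart", {
  tt <- utils::read.csv(test_path("fixtures", "flowchart_truth_table.csv"))
  th <- rule_thresholds()
  for (i in seq_len(nrow(tt))) {
    rec <- record_with(
      tumour_pattern = tt$tumour_pattern[i] == 1,
      glands_present = tt$glands_present[i] == 1,
      has_transparent_gland = tt$has_transparent_gland[i] == 1,
      mean_gland_transparency = tt$mean_transparency[i],
      penetration_um = tt$penetration_um[i],
      stratification_visible = tt$stratification_visible[i] == 1)
    cl <- classify_mucosal_type(rec, th)
    expect_equal(as.character(cl), tt$expected[i],
                 info = paste("fixture row", i))
    expect_equal(isTRUE(attr(cl, "indeterminate")), tt$indeterminate[i] == 1,
                 info = paste("fixture row", i))
  }
})

test_that("classification matches the published per-class feature profiles", {
  th <- rule_thresholds()
  # dysplasia: glands with one >= 80% transparent gland
  expect_equal(as.character(classify_mucosal_type(record_with(
    glands_present = TRUE, has_transparent_gland = TRUE,
    mean_gland_transparency = 85), th)), "D")
  # intestinal metaplasia: glands at 69% mean transparency
  expect_equal(as.character(classify_mucosal_type(record_with(
    glands_present = TRUE, mean_gland_transparency = 69), th)), "IM")
  # gastric metaplasia: no glands, shallow 316 um penetration
  expect_equal(as.character(classify_mucosal_type(record_with(
    penetration_um = 316), th)), "GM")
  # tumour pattern takes precedence over the shallow-penetration branch
  expect_equal(as.character(classify_mucosal_type(record_with(
    tumour_pattern = TRUE, penetration_um = 346), th)), "IMC")
  # normal squamous mucosa: deep penetration, stratified
  expect_equal(as.character(classify_mucosal_type(record_with(
    penetration_um = 726), th)), "NSM")
  rec <- record_with(); rec$penetration_um <- NA_real_
  expect_error(classify_mucosal_type(rec, th), "penetration_um")
})

test_that("every complete record maps to exactly one class", {
  set.seed(5)
  for (i in 1:50) {
    rec <- record_with(
      tumour_pattern = stats::runif(1) < 0.3,
      glands_present = stats::runif(1) < 0.5,
      has_transparent_gland = stats::runif(1) < 0.3,
      mean_gland_transparency = stats::runif(1, 40, 95),
      penetration_um = stats::runif(1, 200, 900),
      stratification_visible = stats::runif(1) < 0.5)
    cl <- classify_mucosal_type(rec)
    expect_true(as.character(cl) %in% c("NSM", "GM", "IM", "D", "IMC"))
  }
})

test_that("threshold validation rejects impossible cutoffs", {
  expect_error(rule_thresholds(transparent_gland_cutoff = 120), "\\(0, 100\\]")
  expect_error(rule_thresholds(penetration_cutoff = -1), "positive")
})

test_that("the tumour-pattern surrogate needs dilated loops and lacunae", {
  px <- 0.05   # Cartesian grid, mm
  base <- matrix(0, 120, 120)
  mkimg <- function(m) enface_image(m, depth_range_um = "full",
                                    projection = "maximum",
                                    coords = "cartesian",
                                    pitch_mm = c(px, px), radius_mm = 6.25)
  # vessel-free image
  expect_false(detect_tumour_vascular_pattern(mkimg(base),
                                              noise_floor = 1)$flag)
  # heavily dilated ring (11 px ~ 550 um wide, enclosing a ~700 um lacuna)
  ring <- base
  th <- seq(0, 2 * pi, length.out = 500)
  for (r in seq(8, 18, by = 0.5))
    ring[cbind(round(60 + r * cos(th)), round(60 + r * sin(th)))] <- 20
  res <- detect_tumour_vascular_pattern(mkimg(ring), noise_floor = 1)
  expect_true(res$flag)
  # thin honeycomb mesh: single-pixel walls, sub-lacuna holes
  mesh <- base
  mesh[seq(6, 114, by = 5), ] <- 20
  mesh[, seq(6, 114, by = 5)] <- 20
  expect_false(detect_tumour_vascular_pattern(mkimg(mesh),
                                              noise_floor = 1)$flag)
})

test_that("tumour and stratification surrogates match generator ground truth", {
  reg <- shared_registration()
  flags <- sapply(c("IMC", "IM", "GM2", "NSM"), function(cl) {
    sim <- shared_sim(cl)
    fl <- estimate_noise_floor(sim$opam_raw, 1:16)
    hfb <- apply_axial_shift(
      resample_to_grid(reconstruct_opam(sim$opam_raw, band_spec("HFB")),
                       sim$oct$pixel_um), -reg$shift_px)
    ef <- project_en_face(hfb, "full", "maximum", surface = 6L)
    c(tum = detect_tumour_vascular_pattern(ef, default_roi(),
                                           noise_floor = fl)$flag,
      strat = detect_stratification(sim$oct, default_roi()))
  })
  expect_true(flags["tum", "IMC"])
  expect_false(flags["tum", "IM"])     # honeycomb is not a tumour pattern
  expect_false(flags["tum", "GM2"])
  expect_true(flags["strat", "NSM"])
  expect_false(flags["strat", "GM2"])  # effaced stratification
  expect_false(flags["strat", "IMC"])
  # pure noise shows no stratification
  noise <- scan_volume(array(stats::rnorm(320 * 30 * 10), dim = c(320, 30, 10)),
                       modality = "oct", pixel_um = 3.5,
                       angle_pitch_rad = 2 * pi / 360, frame_pitch_um = 50,
                       radius_mm = 6.25)
  expect_false(detect_stratification(noise))
})
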