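# End-to-end region-of-interest simulation and feature extraction.

#' Desk-scale scan configuration for ROI patches
#'
#' The default study condition for synthetic cohorts: a 2.6 x 7 mm mucosal
#' patch scanned at the specimen operating point (20 Hz rotation, 1 mm/s
#' pullback, so 50 um pullback pitch), 360 angular OCT samples per full
#' turn (the patch spans 64 of them) and the OPAM channel at half the
#' angular rate.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [scan_config()].
#' @return a [scan_config()].
#' @export
roi_scan_config <- function(seed = 1L, ...) {
  scan_config(pullback_mm = 2.6, seed = seed, ...)
}

#' Default ROI patch extent (pullback, arc), mm
#' @export
ROI_EXTENT_MM <- c(2.6, 7)

#' Simulate one synthetic ROI of a mucosal class
#'
#' Builds the class phantom on the default patch extent and scans it with
#' both modalities.
#'
#' @param class_label mucosal class (see [MUCOSAL_CLASSES]).
#' @param seed integer seed controlling phantom and scan noise.
#' @param config a [scan_config()]; its seed is overridden by `seed`.
#' @param extent_mm patch extent.
#' @return list with `phantom`, `oct` (OCT volume), `opam_raw` (raw OPAM),
#'   `glands` (ground-truth [gland_annotation()]), `config`, `class_label`.
#' @export
simulate_roi <- function(class_label, seed = 1L, config = NULL,
                         extent_mm = ROI_EXTENT_MM) {
  config <- config %||% roi_scan_config(seed = seed)
  config$seed <- as.integer(seed)
  profile <- class_profile(class_label)
  phantom <- build_phantom(profile, extent_mm = extent_mm, seed = seed,
                           label_grid = FALSE)
  oct <- simulate_oct_scan(phantom, config)
  opam_raw <- simulate_opam_scan(phantom, config)
  list(phantom = phantom, oct = oct, opam_raw = opam_raw,
       glands = phantom_gland_annotations(phantom, config),
       config = config, class_label = class_label)
}

#' Estimate the fixed OPAM-to-OCT transform from a simulated mesh scan
#'
#' Mirrors the calibration-phantom workflow: scan the metal mesh target with
#' both modalities under the given configuration, reconstruct the OPAM
#' full-band envelope, and search the axial shift. The result is applied as
#' a fixed transform to tissue scans acquired under the same configuration.
#'
#' @param config a [scan_config()].
#' @return a `registration_result` (see [find_axial_shift()]).
#' @export
calibrate_registration <- function(config = roi_scan_config()) {
  mesh <- make_calibration_target("mesh", extent_mm = c(2.6, 7))
  oct <- simulate_oct_scan(mesh, config)
  opam <- reconstruct_opam(simulate_opam_scan(mesh, config), band_spec("FFB"))
  register_on_mesh(oct, opam, max_shift = 40)
}

#' Default analysis ROI for a simulated patch
#'
#' A rectangle inset from the patch border so that boundary effects of the
#' simulation do not enter the features, large enough to contain two
#' 2 x 3 mm inhomogeneity grid cells.
#'
#' @param extent_mm the patch extent.
#' @param margin_mm inset margin.
#' @param id,class_label passed to [roi_rect()].
#' @return a [roi_annotation()].
#' @export
default_roi <- function(extent_mm = ROI_EXTENT_MM, margin_mm = 0.15,
                        id = "roi", class_label = NA_character_) {
  roi_rect(x_range_mm = c(margin_mm, extent_mm[2] - margin_mm),
           f_range_mm = c(margin_mm, extent_mm[1] - margin_mm),
           id = id, class_label = class_label)
}

#' Extract the full feature record of a simulated ROI
#'
#' Runs the analysis chain on one simulated ROI: high-frequency-band OPAM
#' reconstruction, nearest-neighbour resampling to the OCT axial grid,
#' application of the fixed mesh-calibrated axial shift, surface detection,
#' en-face projection, the five quantitative features and the two
#' qualitative flag detectors, assembled into a [assemble_feature_record()].
#'
#' @param sim output of [simulate_roi()].
#' @param registration a `registration_result` from
#'   [calibrate_registration()] (computed on the fly when `NULL`; pass it
#'   explicitly when processing cohorts).
#' @param roi a [roi_annotation()]; default [default_roi()].
#' @param th a [rule_thresholds()] (for the transparent-gland cutoff).
#' @return a `feature_record` row.
#' @export
extract_roi_features <- function(sim, registration = NULL, roi = NULL,
                                 th = rule_thresholds()) {
  roi <- roi %||% default_roi(class_label = sim$class_label)
  registration <- registration %||% calibrate_registration(sim$config)

  oct <- sim$oct
  # OPAM noise floor: amplitude s.d. of the raw background band before the
  # first possible absorber arrival (the DAQ noise level)
  n_bg <- max(4L, floor(sim$opam_raw$axial_offset_um / sim$opam_raw$pixel_um) - 2L)
  opam_floor <- estimate_noise_floor(sim$opam_raw, seq_len(n_bg))
  hfb <- reconstruct_opam(sim$opam_raw, band_spec("HFB"))
  hfb <- resample_to_grid(hfb, oct$pixel_um)
  hfb <- apply_axial_shift(hfb, -registration$shift_px)

  surface <- detect_surface(oct)
  sfc_med <- as.integer(round(stats::median(surface)))

  ef_oct <- project_en_face(oct, c(100, 200), "average", surface = surface)
  inhom <- epithelial_inhomogeneity(ef_oct, roi)

  vm <- vascular_metrics(hfb, roi, k = 5, noise_floor = opam_floor,
                         surface = sfc_med)
  pen <- oct_penetration_depth(oct, roi, k = 3, frame_avg = 5)

  glands <- merge_glands(sim$glands)
  tr <- gland_transparency(oct, glands,
                           transparent_cutoff = th$transparent_gland_cutoff)

  ef_hfb <- project_en_face(hfb, "full", "maximum", surface = sfc_med)
  tum <- detect_tumour_vascular_pattern(ef_hfb, roi, noise_floor = opam_floor)
  strat <- detect_stratification(oct, roi)

  assemble_feature_record(
    roi_id = roi$id,
    inhomogeneity = inhom,
    vascular_density = vm$density,
    vascular_depth_um = vm$depth_um,
    penetration_um = pen,
    mean_gland_transparency = tr$mean_transparency,
    has_transparent_gland = tr$has_transparent_gland,
    glands_present = nrow(sim$glands) > 0,
    stratification_visible = strat,
    tumour_pattern = tum$flag,
    class_label = sim$class_label)
}

#' Simulate a cohort of ROIs and extract their features
#'
#' The workhorse for calibration-recovery and classification experiments:
#' simulates `length(seeds)` independent ROIs of one class and runs
#' [extract_roi_features()] on each, sharing one mesh-calibrated
#' registration.
#'
#' @param class_label mucosal class.
#' @param seeds integer vector of ROI seeds (one ROI per seed).
#' @param registration optional shared `registration_result`.
#' @param th a [rule_thresholds()].
#' @return a `feature_record` data.frame with one row per ROI.
#' @export
simulate_cohort_features <- function(class_label, seeds = 1:30,
                                     registration = NULL,
                                     th = rule_thresholds()) {
  registration <- registration %||% calibrate_registration(roi_scan_config())
  recs <- lapply(seeds, function(s) {
    sim <- simulate_roi(class_label, seed = s)
    rec <- extract_roi_features(sim, registration = registration, th = th)
    rec$roi_id <- sprintf("%s_%03d", class_label, s)
    rec
  })
  out <- do.call(rbind, recs)
  class(out) <- c("feature_record", "data.frame")
  out
}
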