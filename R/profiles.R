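# Default generative profiles for the six mucosal classes.
#
# The cohort feature statistics each profile is calibrated against (class
# means +/- s.d. of epithelial inhomogeneity, OCT penetration, vascular depth
# and gland transparency) are carried in `calibration_targets`. Optical and
# acoustic tissue constants are not measured quantities: they were
# inverse-designed once so that the full pipeline (simulation -> band
# reconstruction -> registration -> feature extraction) reproduces those
# cohort statistics, and are versioned here.

#' Mucosal class labels
#'
#' `NSM` normal squamous mucosa, `GM1`/`GM2` gastric metaplasia with/without
#' prominent superficial pits, `IM` intestinal metaplasia, `D` dysplasia,
#' `IMC` intramucosal cancer. The classifier merges GM1/GM2 into `GM`.
#'
#' @export
MUCOSAL_CLASSES <- c("NSM", "GM1", "GM2", "IM", "D", "IMC")

#' Default generative profile for a mucosal class
#'
#' Returns the versioned default [class_profile] for one of the six mucosal
#' classes: ordered optical layer stack (thickness, backscatter, attenuation),
#' gland/crypt specification, pit flag, vessel population (density, diameter,
#' depth distribution, morphology), lateral texture amplitude, and the cohort
#' calibration targets the profile was designed against.
#'
#' @param class_label one of `"NSM"`, `"GM1"`, `"GM2"`, `"IM"`, `"D"`, `"IMC"`.
#' @return an object of class `class_profile`. Key fields:
#' \describe{
#'   \item{layer_spec}{data.frame with `name`, `thickness_um`,
#'     `backscatter` (arbitrary units, 0-1), `attenuation_mm1`.}
#'   \item{gland_spec}{list with `density_mm2`, `radius_um_mean`,
#'     `radius_um_sd`, `lumen_level` (observed lumen intensity as a fraction
#'     of the numerical upper pixel limit), `lumen_level_sd`,
#'     `lumen_reflectivity` (lumen/surround fraction, in `[0,1]`).}
#'   \item{vessel_spec}{list with `density_mm2`, `diam_um_mean`, `diam_um_sd`,
#'     `depth_um_mean`, `depth_um_sd`, `morphology`.}
#'   \item{stratification_present}{logical; whether the class shows a layered
#'     mucosa in cross-section.}
#'   \item{calibration_targets}{cohort mean/s.d. the defaults target.}
#' }
#' @examples
#' p <- class_profile("NSM")
#' p$vessel_spec$depth_um_mean   # 534
#' @export
class_profile <- function(class_label) {
  if (!is.character(class_label) || length(class_label) != 1L ||
      !(class_label %in% MUCOSAL_CLASSES))
    stop(sprintf("unknown class label %s; valid labels: %s",
                 deparse(class_label), paste(MUCOSAL_CLASSES, collapse = ", ")),
         call. = FALSE)
  p <- .default_profiles[[class_label]]
  validate_class_profile(p)
  p
}

new_class_profile <- function(class_label, layer_spec, gland_spec, pit_spec,
                              vessel_spec, stratification_present, texture_cv,
                              calibration_targets) {
  structure(list(
    class_label = class_label,
    layer_spec = layer_spec,
    gland_spec = gland_spec,
    pit_spec = pit_spec,
    vessel_spec = vessel_spec,
    stratification_present = stratification_present,
    texture_cv = texture_cv,
    calibration_targets = calibration_targets
  ), class = "class_profile")
}

validate_class_profile <- function(p) {
  stopifnot(inherits(p, "class_profile"))
  if (any(p$layer_spec$thickness_um <= 0))
    stop("layer thicknesses must be positive", call. = FALSE)
  gl <- p$gland_spec
  if (gl$density_mm2 > 0 &&
      (gl$lumen_reflectivity < 0 || gl$lumen_reflectivity > 1))
    stop("lumen reflectivity fraction must lie in [0,1]", call. = FALSE)
  if (p$vessel_spec$depth_um_mean < 0)
    stop("vessel depth mean must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.class_profile <- function(x, ...) {
  cat(sprintf("<class_profile> %s\n", x$class_label))
  cat(sprintf("  layers: %s\n", paste(x$layer_spec$name, collapse = " / ")))
  cat(sprintf("  glands: %s   vessels: %s (depth %g +/- %g um)\n",
              if (x$gland_spec$density_mm2 > 0) "yes" else "no",
              x$vessel_spec$morphology,
              x$vessel_spec$depth_um_mean, x$vessel_spec$depth_um_sd))
  cat(sprintf("  stratified: %s\n", x$stratification_present))
  invisible(x)
}

layers <- function(names, thickness_um, backscatter, attenuation_mm1) {
  data.frame(name = names, thickness_um = thickness_um,
             backscatter = backscatter, attenuation_mm1 = attenuation_mm1,
             stringsAsFactors = FALSE)
}

no_glands <- list(density_mm2 = 0, radius_um_mean = 0, radius_um_sd = 0,
                  lumen_level = 0, lumen_level_sd = 0, lumen_reflectivity = 0)

targets <- function(inhom, inhom_sd, pen, pen_sd, vdep, vdep_sd,
                    transp = NA_real_, tumour = FALSE, strat = FALSE,
                    glands = FALSE, transparent_glands = FALSE) {
  list(inhomogeneity = inhom, inhomogeneity_sd = inhom_sd,
       penetration_um = pen, penetration_um_sd = pen_sd,
       vascular_depth_um = vdep, vascular_depth_um_sd = vdep_sd,
       transparency_pct = transp, tumour_pattern = tumour,
       stratification = strat, glands_present = glands,
       transparent_glands = transparent_glands)
}

.default_profiles <- list(
  NSM = new_class_profile(
    "NSM",
    layer_spec = layers(c("surface interface", "epithelium",
                          "lamina propria", "muscularis"),
                        c(20, 280, 250, 2000),
                        c(0.50, 0.16, 0.85, 0.45),
                        c(0.8, 1.0, 2.2, 10.7)),
    gland_spec = no_glands, pit_spec = FALSE,
    vessel_spec = list(density_mm2 = 8, diam_um_mean = 25, diam_um_sd = 8,
                       depth_um_mean = 534, depth_um_sd = 114,
                       morphology = "mesh"),
    stratification_present = TRUE, texture_cv = 0,
    calibration_targets = targets(0.098, 0.02, 726, 43, 534, 114,
                                  strat = TRUE)
  ),
  GM1 = new_class_profile(
    "GM1",
    layer_spec = layers(c("surface interface", "columnar epithelium",
                          "deep mucosa"),
                        c(20, 430, 2000),
                        c(0.75, 0.75, 0.40),
                        c(13.6, 13.6, 13.6)),
    gland_spec = no_glands, pit_spec = TRUE,
    vessel_spec = list(density_mm2 = 30, diam_um_mean = 20, diam_um_sd = 6,
                       depth_um_mean = 328, depth_um_sd = 87,
                       morphology = "capillary-loop"),
    stratification_present = FALSE, texture_cv = 0,
    calibration_targets = targets(0.14, 0.04, 316, 35, 328, 87)
  ),
  GM2 = new_class_profile(
    "GM2",
    layer_spec = layers(c("surface interface", "columnar epithelium",
                          "deep mucosa"),
                        c(20, 430, 2000),
                        c(0.75, 0.75, 0.40),
                        c(13.6, 13.6, 13.6)),
    gland_spec = no_glands, pit_spec = FALSE,
    vessel_spec = list(density_mm2 = 30, diam_um_mean = 20, diam_um_sd = 6,
                       depth_um_mean = 328, depth_um_sd = 87,
                       morphology = "capillary-loop"),
    stratification_present = FALSE, texture_cv = 0.046,
    calibration_targets = targets(0.14, 0.04, 316, 35, 328, 87)
  ),
  IM = new_class_profile(
    "IM",
    layer_spec = layers(c("surface interface", "glandular epithelium",
                          "lamina propria"),
                        c(20, 380, 2000),
                        c(0.60, 0.60, 0.75),
                        c(1.0, 1.0, 14.8)),
    gland_spec = list(density_mm2 = 4, radius_um_mean = 90, radius_um_sd = 25,
                      lumen_level = 0.31, lumen_level_sd = 0.025,
                      lumen_reflectivity = 0.31 / 0.60),
    pit_spec = FALSE,
    vessel_spec = list(density_mm2 = 40, diam_um_mean = 15, diam_um_sd = 5,
                       depth_um_mean = 264, depth_um_sd = 59,
                       morphology = "honeycomb"),
    stratification_present = TRUE, texture_cv = 0.12,
    calibration_targets = targets(0.15, 0.02, 599, 29, 264, 59,
                                  transp = 69, strat = TRUE, glands = TRUE)
  ),
  D = new_class_profile(
    "D",
    layer_spec = layers(c("surface interface", "glandular epithelium",
                          "lamina propria"),
                        c(20, 380, 2000),
                        c(0.60, 0.60, 0.75),
                        c(1.0, 1.0, 14.1)),
    gland_spec = list(density_mm2 = 6, radius_um_mean = 110, radius_um_sd = 30,
                      lumen_level = 0.15, lumen_level_sd = 0.05,
                      lumen_reflectivity = 0.15 / 0.60),
    pit_spec = FALSE,
    vessel_spec = list(density_mm2 = 35, diam_um_mean = 18, diam_um_sd = 6,
                       depth_um_mean = 284, depth_um_sd = 92,
                       morphology = "irregular"),
    stratification_present = FALSE, texture_cv = 0,
    calibration_targets = targets(0.19, 0.08, 584, 27, 284, 92,
                                  transp = 85, glands = TRUE,
                                  transparent_glands = TRUE)
  ),
  IMC = new_class_profile(
    "IMC",
    layer_spec = layers(c("surface interface", "tumour mucosa"),
                        c(20, 2430),
                        c(0.70, 0.70),
                        c(11.25, 11.25)),
    gland_spec = no_glands, pit_spec = FALSE,
    vessel_spec = list(density_mm2 = 25, diam_um_mean = 70, diam_um_sd = 15,
                       depth_um_mean = 276, depth_um_sd = 35,
                       morphology = "tumour-loop"),
    stratification_present = FALSE, texture_cv = 0.074,
    calibration_targets = targets(0.14, 0.02, 346, 24, 276, 35,
                                  tumour = TRUE)
  )
)
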