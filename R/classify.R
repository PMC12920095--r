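# Two-stage rule-based mucosal-type classification.

#' Rule thresholds of the flowchart classifier
#'
#' The 80% transparent-gland hallmark is fixed by the feature definition;
#' the numeric cutoffs sit midway between the adjacent class cohort means
#' (penetration 450 um between 346 and 584; vascular depth 400 um between
#' 328 and 534; inhomogeneity 0.12 between 0.098 and 0.14; mean transparency
#' 77% between 69 and 85). All are configurable.
#'
#' @param transparent_gland_cutoff per-gland transparency, percent.
#' @param mean_transparency_cutoff ROI mean gland transparency, percent.
#' @param penetration_cutoff OCT penetration, um.
#' @param vascular_depth_cutoff mean vascular depth, um.
#' @param inhomogeneity_cutoff grid coefficient of variation.
#' @param density_cutoff vascular density fraction (used when depth missing).
#' @return object of class `rule_thresholds`.
#' @export
rule_thresholds <- function(transparent_gland_cutoff = 80,
                            mean_transparency_cutoff = 77,
                            penetration_cutoff = 450,
                            vascular_depth_cutoff = 400,
                            inhomogeneity_cutoff = 0.12,
                            density_cutoff = 0.2) {
  th <- list(transparent_gland_cutoff = transparent_gland_cutoff,
             mean_transparency_cutoff = mean_transparency_cutoff,
             penetration_cutoff = penetration_cutoff,
             vascular_depth_cutoff = vascular_depth_cutoff,
             inhomogeneity_cutoff = inhomogeneity_cutoff,
             density_cutoff = density_cutoff)
  if (any(unlist(th) <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (transparent_gland_cutoff > 100)
    stop("transparent_gland_cutoff must lie in (0, 100]", call. = FALSE)
  structure(th, class = "rule_thresholds")
}

#' Screening test: normal vs abnormal mucosa
#'
#' En-face screening rule: a region is abnormal when its mean vascular depth
#' is shallow (below the cutoff; columnarized mucosae are densely
#' vascularized in the epithelium) or its epithelial inhomogeneity is high.
#' Boundary ties call abnormal (screening bias). When the vascular depth is
#' missing (no valid A-scans), the vascular criterion falls back to the
#' density cutoff.
#'
#' @param record a `feature_record` row.
#' @param th a [rule_thresholds()].
#' @return `"normal"` or `"abnormal"`.
#' @export
classify_normal_abnormal <- function(record, th = rule_thresholds()) {
  dep <- record$vascular_depth_um
  inh <- record$inhomogeneity
  den <- record$vascular_density
  if ((is.null(dep) || is.na(dep)) && (is.null(inh) || is.na(inh)) &&
      (is.null(den) || is.na(den)))
    stop("record must carry vascular depth (or density) or inhomogeneity",
         call. = FALSE)
  vasc_abn <- if (!is.na(dep)) dep <= th$vascular_depth_cutoff
              else if (!is.na(den)) den >= th$density_cutoff else FALSE
  inhom_abn <- !is.na(inh) && inh >= th$inhomogeneity_cutoff
  if (isTRUE(vasc_abn) || inhom_abn) "abnormal" else "normal"
}

#' Five-class mucosal-type assignment
#'
#' Flowchart decision order:
#' \enumerate{
#'   \item tumour vascular pattern present -> `IMC` (the optoacoustic
#'     disambiguation of cancer from gastric metaplasia type 2);
#'   \item glands present -> `D` when a transparent (>= 80%) gland exists or
#'     the mean gland transparency reaches the cutoff, else `IM`;
#'   \item OCT penetration below the cutoff -> `GM`;
#'   \item otherwise `NSM`; when mucosal stratification is not visible the
#'     call carries an `indeterminate` attribute.
#' }
#'
#' @param record a `feature_record` row with complete fields.
#' @param th a [rule_thresholds()].
#' @return one of `"NSM"`, `"GM"`, `"IM"`, `"D"`, `"IMC"`; attribute
#'   `indeterminate` is `TRUE` for an unstratified NSM call.
#' @export
classify_mucosal_type <- function(record, th = rule_thresholds()) {
  for (f in c("tumour_pattern", "glands_present", "penetration_um",
              "stratification_visible"))
    if (is.null(record[[f]]) || is.na(record[[f]]))
      stop(sprintf("missing required field `%s`", f), call. = FALSE)
  if (isTRUE(record$tumour_pattern)) return("IMC")
  if (isTRUE(record$glands_present)) {
    tr <- record$mean_gland_transparency
    if (isTRUE(record$has_transparent_gland) ||
        (!is.na(tr) && tr >= th$mean_transparency_cutoff)) return("D")
    return("IM")
  }
  if (record$penetration_um < th$penetration_cutoff) return("GM")
  out <- "NSM"
  if (!isTRUE(record$stratification_visible)) attr(out, "indeterminate") <- TRUE
  out
}

#' Classify a table of feature records
#'
#' @param records `feature_record` data.frame (one row per ROI).
#' @param th a [rule_thresholds()].
#' @return data.frame with `roi_id`, `screen` (normal/abnormal), `call`
#'   (five-class), `indeterminate`.
#' @export
classify_records <- function(records, th = rule_thresholds()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    cl <- classify_mucosal_type(rec, th)
    data.frame(roi_id = rec$roi_id,
               screen = classify_normal_abnormal(rec, th),
               call = as.character(cl),
               indeterminate = isTRUE(attr(cl, "indeterminate")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Detect the tumour superficial vascular pattern
#'
#' Algorithmic surrogate for the qualitative hallmark of intramucosal
#' cancer: dilated vessels forming meandering loops around avascular areas.
#' The en-face vessel map is binarized at `k` times the noise floor on a
#' square-pixel Cartesian grid; the flag requires both (a) a typical vessel
#' width (2x distance-transform maximum per vessel component, area-weighted
#' across components) of at least
#' `width_cutoff_um`, and (b) at least one enclosed avascular lacuna -
#' a background connected component of equivalent diameter at least
#' `lacuna_diam_um` that does not touch the image border. The continuous
#' score is `(median width / cutoff) * (largest enclosed lacuna diameter /
#' cutoff)`, for threshold tuning.
#'
#' @param hfb_enface maximum-projection HFB [enface_image()] (polar or
#'   Cartesian).
#' @param roi optional [roi_annotation()] restricting the analysis.
#' @param k binarization threshold in noise-floor multiples.
#' @param noise_floor background amplitude; default = s.d. of the lowest
#'   intensity quartile of the image.
#' @param width_cutoff_um dilated-vessel cutoff.
#' @param lacuna_diam_um minimum lacuna equivalent diameter.
#' @return list with `flag` (logical) and `score` (numeric).
#' @export
detect_tumour_vascular_pattern <- function(hfb_enface, roi = NULL, k = 5,
                                           noise_floor = NULL,
                                           width_cutoff_um = 185,
                                           lacuna_diam_um = 300) {
  stopifnot(inherits(hfb_enface, "enface_image"))
  img <- hfb_enface
  if (img$coords == "polar") img <- unwrap_to_cartesian(img)
  px_um <- img$pitch_mm[1] * 1000
  dat <- img$data
  if (!is.null(roi)) {
    x <- (seq_len(nrow(dat)) - 0.5) * img$pitch_mm[1]
    f <- (seq_len(ncol(dat)) - 0.5) * img$pitch_mm[2]
    keep_x <- x >= min(roi$x_mm) & x <= max(roi$x_mm)
    keep_f <- f >= min(roi$f_mm) & f <= max(roi$f_mm)
    dat <- dat[keep_x, keep_f, drop = FALSE]
  }
  if (is.null(noise_floor)) {
    q <- stats::quantile(dat, 0.25)
    noise_floor <- stats::sd(dat[dat <= q])
    if (!is.finite(noise_floor) || noise_floor == 0)
      noise_floor <- stats::sd(dat) / 10 + .Machine$double.eps
  }
  vess <- dat >= k * noise_floor
  if (!any(vess)) return(list(flag = FALSE, score = 0))

  # typical vessel width from the distance transform: twice the mean
  # distance-to-background over vessel pixels. Pixel-level (rather than
  # per-component) statistics are robust to reticular patterns merging into
  # one large connected component.
  vm <- EBImage::Image(vess * 1)
  dt <- EBImage::distmap(vm)
  med_width <- 2 * mean(dt[vess]) * px_um

  # enclosed avascular lacunae: background components off the border
  bg <- EBImage::bwlabel(EBImage::Image((!vess) * 1))
  border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  ids <- setdiff(seq_len(max(bg)), border_ids)
  lac_diam <- 0
  if (length(ids)) {
    areas <- tabulate(as.integer(bg), nbins = max(bg))[ids]
    lac_diam <- 2 * sqrt(max(areas) * px_um^2 / pi)
  }
  flag <- (med_width >= width_cutoff_um) && (lac_diam >= lacuna_diam_um)
  score <- (med_width / width_cutoff_um) * (lac_diam / lacuna_diam_um)
  list(flag = flag, score = score, median_width_um = med_width,
       largest_lacuna_um = lac_diam)
}

#' Detect mucosal stratification in cross-sections
#'
#' Surrogate for the visual judgement that a layered mucosa (hypo-reflective
#' epithelium over hyper-reflective lamina propria) is visible: the
#' laterally averaged depth profile within the ROI is smoothed and scanned
#' for alternating significant extrema within the first `max_depth_um`
#' below the surface; stratification is called when at least `min_extrema`
#' extrema with prominence above `prom_frac` of the profile range are found.
#'
#' @param oct_vol OCT [scan_volume()].
#' @param roi optional [roi_annotation()].
#' @param max_depth_um depth window below the surface.
#' @param prom_frac prominence threshold as a fraction of the profile range.
#' @param min_extrema extrema count required.
#' @return logical flag.
#' @export
detect_stratification <- function(oct_vol, roi = NULL, max_depth_um = 600,
                                  prom_frac = 0.18, min_extrema = 2) {
  stopifnot(inherits(oct_vol, "scan_volume"))
  d <- dim(oct_vol$data)
  sel <- if (is.null(roi)) matrix(TRUE, d[2], d[3]) else roi_mask(oct_vol, roi)
  x <- matrix(oct_vol$data, nrow = d[1])
  prof_all <- rowMeans(x[, as.vector(sel), drop = FALSE])
  sfc <- round(stats::median(detect_surface(oct_vol)))
  nmax <- min(d[1], sfc + round(max_depth_um / oct_vol$pixel_um))
  prof <- running_mean(prof_all[sfc:nmax], 5)
  rng <- diff(range(prof))
  floor_amp <- estimate_noise_floor(oct_vol, background_region = 1:3)
  if (rng < 3 * floor_amp) return(FALSE)
  ext <- local_extrema(prof, min_prominence = prom_frac * rng)
  nrow(ext) >= min_extrema
}
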