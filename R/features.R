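# Quantification of the five ROI features.

#' ROI annotation
#'
#' A simple (non-self-intersecting is assumed, not checked beyond area > 0)
#' polygon in en-face coordinates: `x_mm` along the circumference (arc
#' length), `f_mm` along the pullback axis.
#'
#' @param x_mm,f_mm polygon vertex coordinates, mm.
#' @param id identifier string.
#' @param class_label optional true class label (evaluation only).
#' @return object of class `roi_annotation`.
#' @export
roi_annotation <- function(x_mm, f_mm, id = "roi", class_label = NA_character_) {
  if (length(x_mm) < 3L || length(x_mm) != length(f_mm))
    stop("polygon needs >= 3 (x, f) vertices", call. = FALSE)
  if (polygon_area(x_mm, f_mm) <= 0)
    stop("polygon area must be positive", call. = FALSE)
  structure(list(x_mm = x_mm, f_mm = f_mm, id = id, class_label = class_label),
            class = "roi_annotation")
}

#' Rectangular ROI helper
#' @param x_range_mm,f_range_mm length-2 extents of the rectangle, mm.
#' @inheritParams roi_annotation
#' @return a [roi_annotation()].
#' @export
roi_rect <- function(x_range_mm, f_range_mm, id = "roi",
                     class_label = NA_character_) {
  roi_annotation(x_mm = x_range_mm[c(1, 2, 2, 1)],
                 f_mm = f_range_mm[c(1, 1, 2, 2)], id = id,
                 class_label = class_label)
}

# lateral (angle, frame) index mask of a volume covered by an ROI polygon
roi_mask <- function(vol, roi) {
  d <- dim(vol$data)
  ap_mm <- vol$angle_pitch_rad * vol$radius_mm
  fp_mm <- vol$frame_pitch_um / 1000
  x <- (seq_len(d[2]) - 0.5) * ap_mm
  f <- (seq_len(d[3]) - 0.5) * fp_mm
  px <- rep(x, times = d[3]); pf <- rep(f, each = d[2])
  m <- matrix(points_in_polygon(px, pf, roi$x_mm, roi$f_mm), d[2], d[3])
  if (!any(m)) stop("empty ROI: polygon covers no A-scans", call. = FALSE)
  m
}

#' Estimate the noise floor of a volume
#'
#' Standard deviation of the samples in a background region known to contain
#' no tissue signal (default, amplitude scale). A strict-variance mode is
#' provided for the literal reading of a variance-based floor; the two differ
#' by units and the amplitude mode is the one used by the thresholding
#' features.
#'
#' @param vol a [scan_volume()] or numeric array.
#' @param background_region depth row indices of the background band.
#' @param mode `"sd"` (default) or `"variance"`.
#' @return scalar noise floor.
#' @export
estimate_noise_floor <- function(vol, background_region, mode = c("sd", "variance")) {
  mode <- match.arg(mode)
  x <- if (inherits(vol, "scan_volume")) vol$data else vol
  if (length(background_region) == 0)
    stop("empty background region", call. = FALSE)
  bg <- x[background_region, , , drop = FALSE]
  if (length(bg) < 2) stop("background region too small", call. = FALSE)
  s <- stats::sd(bg)
  if (mode == "sd") s else s^2
}

#' Epithelial inhomogeneity (grid coefficient of variation)
#'
#' On the 100-200 um OCT en-face projection, the ROI is tiled with 2 x 3 mm
#' rectangular grid cells (2 mm along the pullback axis, 3 mm along the
#' circumference, anchored at the ROI bounding-box origin). Per cell the
#' coefficient of variation `C_v = sd / mean` of the pixel values is
#' computed (sample standard deviation); the ROI inhomogeneity is the mean
#' `C_v` over all cells lying fully inside the ROI.
#'
#' @param enface an [enface_image()] (the 100-200 um OCT average projection).
#' @param roi a [roi_annotation()].
#' @param cell_mm grid cell size `(pullback, circumference)`, mm.
#' @return scalar mean coefficient of variation.
#' @export
epithelial_inhomogeneity <- function(enface, roi, cell_mm = c(2, 3)) {
  stopifnot(inherits(enface, "enface_image"))
  d <- dim(enface$data)
  ap <- enface$pitch_mm[1]; fp <- enface$pitch_mm[2]
  x <- (seq_len(d[1]) - 0.5) * ap
  f <- (seq_len(d[2]) - 0.5) * fp
  x0 <- min(roi$x_mm); f0 <- min(roi$f_mm)
  nx_cell <- max(1L, round(cell_mm[2] / ap))
  nf_cell <- max(1L, round(cell_mm[1] / fp))
  inside <- matrix(points_in_polygon(rep(x, d[2]), rep(f, each = d[1]),
                                     roi$x_mm, roi$f_mm), d[1], d[2])
  cvs <- numeric(0)
  cx0 <- which(x >= x0)[1]; cf0 <- which(f >= f0)[1]
  if (is.na(cx0) || is.na(cf0)) stop("ROI smaller than grid cell", call. = FALSE)
  xi <- cx0
  while (xi + nx_cell - 1 <= d[1]) {
    fi <- cf0
    while (fi + nf_cell - 1 <= d[2]) {
      cell_in <- inside[xi:(xi + nx_cell - 1), fi:(fi + nf_cell - 1)]
      if (all(cell_in)) {
        v <- enface$data[xi:(xi + nx_cell - 1), fi:(fi + nf_cell - 1)]
        m <- mean(v)
        cvs <- c(cvs, if (m == 0) 0 else stats::sd(v) / m)
      }
      fi <- fi + nf_cell
    }
    xi <- xi + nx_cell
  }
  if (!length(cvs)) stop("ROI smaller than grid cell", call. = FALSE)
  mean(cvs)
}

#' Vascular density and mean vascular depth
#'
#' On the high-frequency-band OPAM envelope volume, A-scans within the ROI
#' are valid when their maximum envelope amplitude reaches at least `k`
#' times the noise floor. Vascular density is the fraction of valid A-scans;
#' vascular depth is the mean depth of the envelope maximum over valid
#' A-scans, measured from the tissue surface. Depth is `NA` when no A-scan
#' is valid.
#'
#' @param hfb_vol registered HFB OPAM [scan_volume()] (envelope).
#' @param roi a [roi_annotation()].
#' @param k threshold in noise-floor multiples.
#' @param noise_floor background amplitude; estimated from the shallow
#'   background band when `NULL`.
#' @param surface surface depth index (matrix or scalar) on the volume grid.
#' @return list with `density` (fraction) and `depth_um`.
#' @export
vascular_metrics <- function(hfb_vol, roi, k = 5, noise_floor = NULL,
                             surface = 1L) {
  stopifnot(inherits(hfb_vol, "scan_volume"))
  m <- roi_mask(hfb_vol, roi)
  d <- dim(hfb_vol$data)
  noise_floor <- noise_floor %||%
    estimate_noise_floor(hfb_vol, background_region = 2:5)
  x <- matrix(hfb_vol$data, nrow = d[1])
  sel <- as.vector(m)
  pk <- apply(x[, sel, drop = FALSE], 2, max)
  pk_i <- apply(x[, sel, drop = FALSE], 2, which.max)
  if (length(surface) == 1L) sfc <- rep(as.integer(surface), sum(sel))
  else sfc <- as.vector(surface)[sel]
  valid <- pk >= k * noise_floor
  density <- mean(valid)
  depth <- if (any(valid))
    mean((pk_i[valid] - sfc[valid]) * hfb_vol$pixel_um) else NA_real_
  list(density = density, depth_um = depth, n_ascan = sum(sel),
       n_valid = sum(valid))
}

#' OCT penetration depth
#'
#' Cross-sectional frames are averaged over `frame_avg` consecutive frames
#' to reduce speckle and detector noise. A-scans in the ROI are valid when
#' their maximum amplitude reaches `k` times the noise floor of the averaged
#' volume; per valid A-scan the penetration is the depth of the deepest
#' pixel still at `k` times the floor, measured from the tissue surface. The
#' ROI value is the mean over valid A-scans.
#'
#' @param oct_vol OCT [scan_volume()].
#' @param roi a [roi_annotation()].
#' @param k threshold in noise-floor multiples.
#' @param frame_avg rolling window length, frames.
#' @param surface optional surface index map; auto-detected when `NULL`.
#' @return scalar mean penetration depth, um.
#' @export
oct_penetration_depth <- function(oct_vol, roi, k = 3, frame_avg = 5,
                                  surface = NULL) {
  stopifnot(inherits(oct_vol, "scan_volume"))
  d <- dim(oct_vol$data)
  if (d[3] < frame_avg)
    stop(sprintf("need at least %d frames in the ROI", frame_avg), call. = FALSE)
  # rolling average over frames
  avg <- array(0, dim = c(d[1], d[2], d[3] - frame_avg + 1))
  acc <- array(0, dim = c(d[1], d[2]))
  for (f in 1:frame_avg) acc <- acc + oct_vol$data[, , f]
  avg[, , 1] <- acc / frame_avg
  if (dim(avg)[3] > 1) {
    for (f in 2:dim(avg)[3]) {
      acc <- acc - oct_vol$data[, , f - 1] + oct_vol$data[, , f + frame_avg - 1]
      avg[, , f] <- acc / frame_avg
    }
  }
  avol <- oct_vol
  avol$data <- avg
  floor_amp <- estimate_noise_floor(avol, background_region = 1:3)
  if (is.null(surface)) surface <- detect_surface(avol, k = 3)
  m <- roi_mask(avol, roi)
  th <- k * floor_amp
  x <- matrix(avg, nrow = d[1])
  sel <- as.vector(m)
  xs <- x[, sel, drop = FALSE]
  sfc <- as.vector(surface)[sel]
  pen <- rep(NA_real_, ncol(xs))
  for (j in seq_len(ncol(xs))) {
    supra <- which(xs[, j] >= th)
    supra <- supra[supra >= sfc[j]]
    if (length(supra)) pen[j] <- (max(supra) - sfc[j]) * oct_vol$pixel_um
  }
  valid <- !is.na(pen) & apply(xs, 2, max) >= th
  if (!any(valid)) stop("no valid A-scans in ROI", call. = FALSE)
  mean(pen[valid])
}

#' Gland annotations
#'
#' Per-frame gland-lumen outlines: a data.frame with one row per (frame,
#' lumen) giving the frame index, a polygon (list-columns `x_mm`, `z_um`)
#' and, optionally, a ground-truth gland id. [merge_glands()] assigns merged
#' gland identities across consecutive frames.
#'
#' @param frame integer frame indices.
#' @param x_mm,z_um list of numeric vectors (one polygon per row).
#' @param gland_id optional known identity.
#' @return object of class `gland_annotation` (a data.frame).
#' @export
gland_annotation <- function(frame, x_mm, z_um, gland_id = NA_integer_) {
  df <- data.frame(frame = as.integer(frame))
  df$x_mm <- x_mm
  df$z_um <- z_um
  df$gland_id <- gland_id
  class(df) <- c("gland_annotation", "data.frame")
  df
}

#' Ground-truth gland annotations of a phantom on a scan grid
#'
#' Intersects each gland sphere with each frame plane and returns the lumen
#' cross-section outlines (16-gons) as a [gland_annotation()].
#'
#' @param phantom a `phantom_volume`.
#' @param config the [scan_config()] used to scan it.
#' @return a [gland_annotation()] (possibly zero rows).
#' @export
phantom_gland_annotations <- function(phantom, config) {
  g <- scan_geometry(phantom, config, "oct")
  rows <- list()
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  if (nrow(phantom$glands)) {
    for (i in seq_len(nrow(phantom$glands))) {
      gl <- phantom$glands[i, ]
      for (f in seq_len(g$nf)) {
        df_um <- abs(g$f_mm[f] - gl$f_mm) * 1000
        if (df_um >= gl$radius_um) next
        r_um <- sqrt(gl$radius_um^2 - df_um^2)
        if (r_um < 60) next   # slivers thinner than the angular pitch
        rows[[length(rows) + 1L]] <- list(
          frame = f,
          x_mm = list(gl$x_mm + r_um / 1000 * cos(th)),
          z_um = list(phantom$surface_um + gl$z_um + r_um * sin(th)),
          gland_id = gl$id)
      }
    }
  }
  if (!length(rows))
    return(gland_annotation(integer(), list(), list(), integer()))
  gland_annotation(
    frame = vapply(rows, `[[`, integer(1), "frame"),
    x_mm = lapply(rows, function(r) r$x_mm[[1]]),
    z_um = lapply(rows, function(r) r$z_um[[1]]),
    gland_id = vapply(rows, `[[`, numeric(1), "gland_id"))
}

#' Merge gland lumen outlines across consecutive frames
#'
#' Lumen outlines in consecutive frames are treated as the same gland when
#' their centroids lie closer than the mean lumen radius of the pair.
#'
#' @param glands a [gland_annotation()].
#' @return the annotation with a `merged_id` column added.
#' @export
merge_glands <- function(glands) {
  n <- nrow(glands)
  if (n == 0) { glands$merged_id <- integer(0); return(glands) }
  cx <- vapply(glands$x_mm, mean, numeric(1))
  cz <- vapply(glands$z_um, mean, numeric(1))
  # effective lumen radius from the outline area (robust to shape)
  r_um <- vapply(seq_len(n), function(i)
    1000 * sqrt(polygon_area(glands$x_mm[[i]], glands$z_um[[i]] / 1000) / pi),
    numeric(1))
  id <- seq_len(n)                      # union-find over consecutive frames
  find <- function(i) { while (id[i] != i) i <- id[i]; i }
  ord <- order(glands$frame)
  for (a in ord) for (b in ord) {
    if (glands$frame[b] != glands$frame[a] + 1L) next
    d_mm <- sqrt((cx[a] - cx[b])^2 + ((cz[a] - cz[b]) / 1000)^2)
    if (d_mm * 1000 < mean(c(r_um[a], r_um[b]))) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) id[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  glands$merged_id <- as.integer(factor(roots))
  glands
}

#' Gland OCT transparency
#'
#' `Transparency = (1 - mean pixel value within the gland / numerical upper
#' limit of pixel values) * 100%`, pooling the lumen pixels of one merged
#' gland across all frames it appears in. The ROI summary is the unweighted
#' mean over glands; a gland at >= 80% transparency is flagged.
#'
#' @param oct_vol OCT [scan_volume()].
#' @param glands a merged [gland_annotation()] (see [merge_glands()]).
#' @param upper_limit numerical upper limit of pixel values; defaults to the
#'   volume's recorded `meta$upper_limit`.
#' @param transparent_cutoff per-gland transparency defining a "transparent
#'   gland", percent (boundary inclusive).
#' @return list with `per_gland` (percent, one per merged gland),
#'   `mean_transparency`, `has_transparent_gland`.
#' @export
gland_transparency <- function(oct_vol, glands, upper_limit = NULL,
                               transparent_cutoff = 80) {
  stopifnot(inherits(oct_vol, "scan_volume"))
  upper_limit <- upper_limit %||% oct_vol$meta$upper_limit
  if (is.null(upper_limit) || upper_limit <= 0)
    stop("`upper_limit` must be positive", call. = FALSE)
  if (nrow(glands) == 0 || is.null(glands$merged_id))
    return(list(per_gland = numeric(0), mean_transparency = NA_real_,
                has_transparent_gland = FALSE))
  d <- dim(oct_vol$data)
  ap_mm <- oct_vol$angle_pitch_rad * oct_vol$radius_mm
  x_mm <- (seq_len(d[2]) - 0.5) * ap_mm
  z_um <- (seq_len(d[1]) - 1) * oct_vol$pixel_um
  per_gland <- sapply(sort(unique(glands$merged_id)), function(gid) {
    rows <- which(glands$merged_id == gid)
    px <- numeric(0)
    for (i in rows) {
      f <- glands$frame[i]
      xi <- which(x_mm >= min(glands$x_mm[[i]]) & x_mm <= max(glands$x_mm[[i]]))
      zi <- which(z_um >= min(glands$z_um[[i]]) & z_um <= max(glands$z_um[[i]]))
      if (!length(xi) || !length(zi)) next
      grid_x <- rep(x_mm[xi], times = length(zi))
      grid_z <- rep(z_um[zi], each = length(xi))
      inside <- points_in_polygon(grid_x, grid_z,
                                  glands$x_mm[[i]], glands$z_um[[i]])
      vals <- t(oct_vol$data[zi, xi, f])   # x fastest, matching grid order
      px <- c(px, as.vector(vals)[inside])
    }
    if (!length(px)) return(NA_real_)   # outline thinner than the pixel grid
    (1 - mean(px) / upper_limit) * 100
  })
  per_gland <- per_gland[!is.na(per_gland)]
  if (!length(per_gland)) stop("empty gland mask", call. = FALSE)
  list(per_gland = per_gland,
       mean_transparency = mean(per_gland),
       has_transparent_gland = any(per_gland >= transparent_cutoff))
}

#' Assemble a per-ROI feature record
#'
#' Combines the five quantitative features and the qualitative flags into the
#' flat record consumed by the two-stage classifier; CSV-serialisable via
#' [write_feature_records()].
#'
#' @param roi_id identifier; all inputs must describe the same ROI.
#' @param inhomogeneity,vascular_density,vascular_depth_um,penetration_um
#'   quantitative features ([epithelial_inhomogeneity()],
#'   [vascular_metrics()], [oct_penetration_depth()]).
#' @param mean_gland_transparency,has_transparent_gland gland summary
#'   ([gland_transparency()]); `NA`/`FALSE` when no glands.
#' @param glands_present,stratification_visible,tumour_pattern flags.
#' @param class_label optional true label (evaluation only).
#' @return object of class `feature_record` (one-row data.frame).
#' @export
assemble_feature_record <- function(roi_id, inhomogeneity, vascular_density,
                                    vascular_depth_um, penetration_um,
                                    mean_gland_transparency = NA_real_,
                                    has_transparent_gland = FALSE,
                                    glands_present = FALSE,
                                    stratification_visible = FALSE,
                                    tumour_pattern = FALSE,
                                    class_label = NA_character_) {
  if (!is.na(vascular_density) && vascular_density == 0 &&
      !is.na(vascular_depth_um))
    stop("vascular depth must be missing when density is 0", call. = FALSE)
  rec <- data.frame(
    roi_id = as.character(roi_id),
    inhomogeneity = inhomogeneity,
    vascular_density = vascular_density,
    vascular_depth_um = vascular_depth_um,
    penetration_um = penetration_um,
    mean_gland_transparency = mean_gland_transparency,
    has_transparent_gland = isTRUE(has_transparent_gland),
    glands_present = isTRUE(glands_present),
    stratification_visible = isTRUE(stratification_visible),
    tumour_pattern = isTRUE(tumour_pattern),
    class_label = class_label,
    stringsAsFactors = FALSE)
  class(rec) <- c("feature_record", "data.frame")
  rec
}

#' Write / read feature records as CSV
#' @param records a `feature_record` data.frame (rows may be several ROIs).
#' @param path CSV path.
#' @return `read_feature_records` returns the records; the writer its path.
#' @export
write_feature_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_records
#' @export
read_feature_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("feature_record", "data.frame")
  df
}
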