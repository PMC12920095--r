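# Cross-sectional and en-face view generation.

#' Detect the tissue surface per A-line
#'
#' First depth sample exceeding `k` times the noise floor (noise floor =
#' standard deviation of the shallow background band above the tissue).
#'
#' @param vol an OCT [scan_volume()].
#' @param k threshold multiplier.
#' @param bg_rows depth rows assumed to lie above the tissue surface.
#' @return integer matrix `angle x frame` of surface depth indices.
#' @export
detect_surface <- function(vol, k = 3, bg_rows = 1:3) {
  stopifnot(inherits(vol, "scan_volume"))
  floor_amp <- stats::sd(vol$data[bg_rows, , ])
  th <- k * floor_amp
  d <- dim(vol$data)
  x <- matrix(vol$data, nrow = d[1])
  y <- x > th
  idx <- apply(y, 2, which.max)          # first TRUE per column
  idx[colSums(y) == 0] <- 1L
  matrix(as.integer(idx), d[2], d[3])
}

#' Align consecutive circumferential frames on the cap marker
#'
#' Detects the carbon-fibre cap marker per frame as the angular maximum of a
#' near-cap depth band and circularly rotates each frame so the marker sits
#' at angle index 1. The per-frame marker trace is kept in
#' `meta$marker_trace` for quality control.
#'
#' @param vol a full-circumference [scan_volume()].
#' @param depth_band depth rows scanned for the marker.
#' @param min_snr minimum ratio of the marker peak to the median angular
#'   profile for a detection.
#' @return the aligned [scan_volume()].
#' @export
align_frames_by_marker <- function(vol, depth_band = 1:4, min_snr = 4) {
  stopifnot(inherits(vol, "scan_volume"))
  d <- dim(vol$data)
  prof <- apply(vol$data[depth_band, , , drop = FALSE], c(2, 3), max)
  peaks <- apply(prof, 2, which.max)
  snr <- vapply(seq_len(d[3]), function(f)
    prof[peaks[f], f] / (stats::median(prof[, f]) + .Machine$double.eps),
    numeric(1))
  ok <- snr >= min_snr
  if (mean(!ok) > 0.10) {
    bad <- which(!ok)
    stop(sprintf(
      "marker not detected in %d/%d frames (>10%%); failing frames: %s",
      length(bad), d[3], paste(utils::head(bad, 20), collapse = ", ")),
      call. = FALSE)
  }
  out <- vol
  for (f in seq_len(d[3])) {
    s <- peaks[f] - 1L
    if (s > 0) out$data[, , f] <- vol$data[, c((s + 1):d[2], 1:s), f]
  }
  out$meta$marker_trace <- peaks
  out$meta$marker_aligned <- TRUE
  out
}

#' Depth-range en-face projection
#'
#' Average-intensity (OCT) or maximum-intensity (OPAM) projection over a
#' stated depth window. Depth is measured from the detected tissue surface of
#' each A-line (or from a supplied surface map, e.g. the registered OCT
#' surface for OPAM volumes); `depth_range_um = "full"` projects the whole
#' volume from the surface down.
#'
#' @param vol a [scan_volume()] image volume.
#' @param depth_range_um length-2 `(start, end)` window in um below the
#'   surface, or `"full"`.
#' @param projection `"average"` or `"maximum"`.
#' @param surface surface index matrix from [detect_surface()], a single
#'   index, or `NULL` to auto-detect (OCT) / use depth origin 1 (other
#'   modalities).
#' @return an [enface_image()] (`angle x frame`, polar coordinates).
#' @export
project_en_face <- function(vol, depth_range_um = "full",
                            projection = c("average", "maximum"),
                            surface = NULL) {
  stopifnot(inherits(vol, "scan_volume"))
  projection <- match.arg(projection)
  d <- dim(vol$data)
  px <- vol$pixel_um
  if (is.null(surface))
    surface <- if (vol$modality == "oct") detect_surface(vol) else 1L
  if (length(surface) == 1L) surface <- matrix(as.integer(surface), d[2], d[3])
  full <- is.character(depth_range_um)
  if (!full) {
    if (depth_range_um[2] <= depth_range_um[1])
      stop("empty depth slab", call. = FALSE)
    i0 <- round(depth_range_um[1] / px)
    i1 <- round(depth_range_um[2] / px) - 1L
    if (i0 >= d[1]) stop("depth range outside the volume", call. = FALSE)
  }
  x <- matrix(vol$data, nrow = d[1])
  out <- numeric(ncol(x))
  sfc <- as.vector(surface)
  for (j in seq_len(ncol(x))) {
    rng <- if (full) sfc[j]:d[1]
           else (sfc[j] + i0):min(sfc[j] + i1, d[1])
    rng <- rng[rng >= 1 & rng <= d[1]]
    if (!length(rng)) stop("empty depth slab", call. = FALSE)
    out[j] <- if (projection == "average") mean(x[rng, j]) else max(x[rng, j])
  }
  enface_image(matrix(out, d[2], d[3]),
               depth_range_um = if (full) "full" else depth_range_um,
               projection = projection, coords = "polar",
               pitch_mm = c((vol$angle_pitch_rad %||% NA) * (vol$radius_mm %||% NA),
                            (vol$frame_pitch_um %||% NA) / 1000),
               radius_mm = vol$radius_mm,
               meta = c(vol$meta, list(modality = vol$modality, band = vol$band)))
}

#' Depth-coded en-face OPAM rendering
#'
#' Per lateral position, brightness encodes the envelope maximum and hue the
#' depth of that maximum through a two-segment colormap: vessels at 0-300 um
#' run green to yellow, deeper vessels red to magenta. Positions whose peak
#' stays below `k` times the noise floor render black.
#'
#' @param opam_vol reconstructed OPAM envelope [scan_volume()].
#' @param boundary_um depth separating the two colour segments.
#' @param surface surface index map (see [project_en_face()]).
#' @param k sub-threshold cut in noise-floor multiples.
#' @param max_depth_um deepest depth of the second segment (display
#'   saturation); defaults to the volume depth.
#' @return an RGB [enface_image()] (`angle x frame x 3`, values in `[0,1]`).
#' @export
depth_code <- function(opam_vol, boundary_um = 300, surface = 1L, k = 5,
                       max_depth_um = NULL) {
  stopifnot(inherits(opam_vol, "scan_volume"))
  d <- dim(opam_vol$data)
  px <- opam_vol$pixel_um
  max_depth_um <- max_depth_um %||% (d[1] * px)
  if (length(surface) == 1L) surface <- matrix(as.integer(surface), d[2], d[3])
  x <- matrix(opam_vol$data, nrow = d[1])
  floor_amp <- estimate_noise_floor(opam_vol, background_region = 1:2)
  pk <- apply(x, 2, max)
  pk_i <- apply(x, 2, which.max)
  depth <- (pk_i - as.vector(surface)) * px
  bright <- pmin(pk / (stats::quantile(pk, 0.995) + .Machine$double.eps), 1)
  bright[pk < k * floor_amp] <- 0
  seg1 <- depth <= boundary_um
  t1 <- pmin(pmax(depth / boundary_um, 0), 1)
  t2 <- pmin(pmax((depth - boundary_um) / max(max_depth_um - boundary_um, 1), 0), 1)
  hue <- ifelse(seg1, (120 - 60 * t1) / 360, ((360 - 60 * t2) %% 360) / 360)
  col <- grDevices::hsv(h = hue, s = 1, v = bright)
  rgb <- t(grDevices::col2rgb(col)) / 255
  enface_image(array(rgb, dim = c(d[2], d[3], 3)),
               depth_range_um = "full", projection = "maximum",
               coords = "polar",
               pitch_mm = c((opam_vol$angle_pitch_rad %||% NA) *
                              (opam_vol$radius_mm %||% NA),
                            (opam_vol$frame_pitch_um %||% NA) / 1000),
               radius_mm = opam_vol$radius_mm,
               meta = list(boundary_um = boundary_um, k = k))
}

# linear resampling of a matrix to new pixel pitches (per axis)
resample_image_linear <- function(img, pitch_in, pitch_out) {
  n <- dim(img)
  resample_axis <- function(m, p_in, p_out) {
    n_in <- nrow(m)
    n_out <- max(2L, round(n_in * p_in / p_out))
    xi <- (seq_len(n_out) - 0.5) * p_out / p_in + 0.5
    xi <- pmin(pmax(xi, 1), n_in)
    lo <- pmin(floor(xi), n_in - 1L); t <- xi - lo
    m[lo, , drop = FALSE] * (1 - t) + m[lo + 1L, , drop = FALSE] * t
  }
  out <- resample_axis(img, pitch_in[1], pitch_out[1])
  t(resample_axis(t(out), pitch_in[2], pitch_out[2]))
}

#' Unwrap a polar en-face image to Cartesian coordinates
#'
#' Scales the angular axis to arc length at the capsule radius and the frame
#' axis to the pullback pitch, producing a square-pixel Cartesian image.
#'
#' @param img a polar [enface_image()] with `pitch_mm` and `radius_mm` set.
#' @param pixel_mm output square pixel size; defaults to the frame pitch.
#' @return a Cartesian [enface_image()].
#' @export
unwrap_to_cartesian <- function(img, pixel_mm = NULL) {
  stopifnot(inherits(img, "enface_image"))
  if (img$coords != "polar") stop("input must be polar", call. = FALSE)
  if (is.null(img$pitch_mm) || any(!is.finite(img$pitch_mm)) ||
      is.null(img$radius_mm))
    stop("missing geometry: pitch_mm and radius_mm are required", call. = FALSE)
  pixel_mm <- pixel_mm %||% img$pitch_mm[2]
  if (all(abs(img$pitch_mm - pixel_mm) < 1e-12)) {
    out <- img
    out$coords <- "cartesian"
    return(out)
  }
  dat <- resample_image_linear(img$data, img$pitch_mm, c(pixel_mm, pixel_mm))
  enface_image(dat, depth_range_um = img$depth_range_um,
               projection = img$projection, coords = "cartesian",
               pitch_mm = c(pixel_mm, pixel_mm), radius_mm = img$radius_mm,
               meta = img$meta)
}
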