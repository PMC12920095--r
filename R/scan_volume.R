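#' Scan volume container
#'
#' A `scan_volume` holds a cylindrical-coordinate capsule-scan image volume as
#' a 3-D numeric array with dimensions `depth x angle x frame`, plus the
#' metadata needed to interpret it physically: the axial pixel size (or, for
#' raw optoacoustic time series, the DAQ sampling rate), the angular pitch, the
#' pullback pitch and the capsule radius.
#'
#' @param data numeric 3-D array, `depth x angle x frame`.
#' @param modality one of `"oct"`, `"opam_raw"`, `"opam"`.
#' @param pixel_um axial pixel size in micrometres (image volumes). For
#'   `"opam_raw"` this is the equivalent one-way depth per sample and is
#'   derived from `sampling_rate_hz` and `speed_of_sound`.
#' @param angle_pitch_rad angular sampling pitch in radians.
#' @param frame_pitch_um pullback distance between consecutive frames, um.
#' @param radius_mm capsule outer radius in millimetres.
#' @param sampling_rate_hz DAQ sampling rate (raw OPAM only).
#' @param band reconstruction band name, if any (`"FFB"`, `"LFB"`, `"HFB"`).
#' @param axial_offset_um known instrumental axial offset of the OPAM depth
#'   axis relative to the OCT depth axis (simulation bookkeeping; estimated
#'   from a mesh scan by [find_axial_shift()] in real use).
#' @param meta list of further metadata (seed, class label, config hash ...).
#' @return an object of class `scan_volume`.
#' @export
scan_volume <- function(data, modality = c("oct", "opam_raw", "opam"),
                        pixel_um = NULL, angle_pitch_rad = NULL,
                        frame_pitch_um = NULL, radius_mm = NULL,
                        sampling_rate_hz = NULL, band = NULL,
                        axial_offset_um = 0, meta = list()) {
  modality <- match.arg(modality)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (depth x angle x frame)", call. = FALSE)
  if (modality == "opam_raw") {
    if (is.null(sampling_rate_hz))
      stop("raw OPAM volumes need `sampling_rate_hz`", call. = FALSE)
  } else if (is.null(pixel_um)) {
    stop("image volumes need `pixel_um`", call. = FALSE)
  }
  structure(list(
    data = data, modality = modality, pixel_um = pixel_um,
    angle_pitch_rad = angle_pitch_rad, frame_pitch_um = frame_pitch_um,
    radius_mm = radius_mm, sampling_rate_hz = sampling_rate_hz,
    band = band, axial_offset_um = axial_offset_um, meta = meta
  ), class = "scan_volume")
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scan_volume> %s%s  %d depth x %d angle x %d frames\n",
              x$modality, if (!is.null(x$band)) paste0(" [", x$band, "]") else "",
              d[1], d[2], d[3]))
  if (!is.null(x$pixel_um))
    cat(sprintf("  axial pixel: %.3g um (depth span %.0f um)\n",
                x$pixel_um, d[1] * x$pixel_um))
  if (!is.null(x$sampling_rate_hz))
    cat(sprintf("  sampling rate: %.3g MHz\n", x$sampling_rate_hz / 1e6))
  if (!is.null(x$frame_pitch_um))
    cat(sprintf("  pullback pitch: %.3g um/frame\n", x$frame_pitch_um))
  invisible(x)
}

#' @export
dim.scan_volume <- function(x) dim(x$data)

#' Display a cross-sectional frame of a scan volume
#'
#' @param x a [scan_volume()].
#' @param frame frame index to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.scan_volume <- function(x, frame = 1, ...) {
  img <- x$data[, , frame]
  graphics::image(t(img)[, rev(seq_len(nrow(img)))],
                  col = grDevices::gray.colors(256), axes = FALSE,
                  main = sprintf("%s frame %d", x$modality, frame), ...)
  invisible(x)
}

#' En-face image container
#'
#' A 2-D projection of a scan volume over a stated depth range. Stored as an
#' `angle x frame` matrix in polar (cylindrical) coordinates, or as a
#' square-pixel Cartesian matrix after [unwrap_to_cartesian()]. Depth-coded
#' renderings carry an `angle x frame x 3` RGB array.
#'
#' @param data matrix (intensity) or 3-D array (`... x 3`, RGB in `[0,1]`).
#' @param depth_range_um numeric length-2 (start, end) in micrometres, or the
#'   string `"full"`.
#' @param projection `"average"` or `"maximum"`.
#' @param coords `"polar"` or `"cartesian"`.
#' @param pitch_mm length-2 pixel pitch (angle/x, frame/y) in millimetres.
#' @param radius_mm capsule radius, needed to unwrap polar images.
#' @param meta list of further metadata.
#' @return an object of class `enface_image`.
#' @export
enface_image <- function(data, depth_range_um = "full",
                         projection = c("average", "maximum"),
                         coords = c("polar", "cartesian"),
                         pitch_mm = NULL, radius_mm = NULL, meta = list()) {
  projection <- match.arg(projection)
  coords <- match.arg(coords)
  if (!is.character(depth_range_um)) {
    if (length(depth_range_um) != 2L || depth_range_um[2] <= depth_range_um[1])
      stop("`depth_range_um` must be (start, end) with end > start, or \"full\"",
           call. = FALSE)
  }
  if (!is.null(pitch_mm) && any(pitch_mm <= 0))
    stop("pixel pitch must be positive", call. = FALSE)
  structure(list(data = data, depth_range_um = depth_range_um,
                 projection = projection, coords = coords,
                 pitch_mm = pitch_mm, radius_mm = radius_mm, meta = meta),
            class = "enface_image")
}

#' @export
print.enface_image <- function(x, ...) {
  d <- dim(x$data)
  rng <- if (is.character(x$depth_range_um)) "full depth"
         else sprintf("%g-%g um", x$depth_range_um[1], x$depth_range_um[2])
  cat(sprintf("<enface_image> %s projection, %s, %s, %d x %d%s\n",
              x$projection, rng, x$coords, d[1], d[2],
              if (length(d) == 3) " (RGB)" else ""))
  invisible(x)
}

#' @export
plot.enface_image <- function(x, ...) {
  if (length(dim(x$data)) == 3) {
    img <- x$data
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(aperm(img, c(2, 1, 3))),
                          0, 0, 1, 1)
  } else {
    graphics::image(x$data, col = grDevices::gray.colors(256), axes = FALSE, ...)
  }
  invisible(x)
}
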