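# OPAM / OCT co-registration: pixel-size matching + axial shift search.

#' Resample a volume's depth axis to a target pixel size
#'
#' Nearest-neighbour resampling along the axial axis only, used to bring OPAM
#' volumes onto the OCT pixel grid before the axial shift search.
#'
#' @param vol a [scan_volume()] (image volume with `pixel_um` set).
#' @param target_pixel_um target axial pixel size, um.
#' @return a [scan_volume()] with `pixel_um = target_pixel_um`.
#' @export
resample_to_grid <- function(vol, target_pixel_um) {
  stopifnot(inherits(vol, "scan_volume"))
  stopifnot_scalar_pos(target_pixel_um, "target_pixel_um")
  src <- vol$pixel_um
  if (is.null(src)) stop("volume has no axial pixel size", call. = FALSE)
  if (abs(src - target_pixel_um) < 1e-12) return(vol)
  d <- dim(vol$data)
  ratio <- target_pixel_um / src
  n_out <- max(1L, floor(d[1] * src / target_pixel_um))
  src_idx <- pmin(d[1], pmax(1L, floor((seq_len(n_out) - 1 + 0.5) * ratio) + 1L))
  out <- vol
  out$data <- vol$data[src_idx, , , drop = FALSE]
  out$pixel_um <- target_pixel_um
  out
}

#' Search the axial shift aligning two co-planar images
#'
#' Exhaustive search over integer axial shifts of the normalized
#' cross-correlation between the binarized images (intended for mesh-phantom
#' scans where both modalities see the same wires). The returned shift is the
#' translation to apply to the *first* image's depth axis so that it best
#' matches the second: `first(z + shift) ~ second(z)`. Ties break toward the
#' smaller absolute shift.
#'
#' @param opam_img depth x lateral matrix (moving image, typically the
#'   resampled OPAM mesh scan).
#' @param oct_img depth x lateral matrix on the same grid (reference).
#' @param max_shift search range in pixels (`-max_shift .. max_shift`).
#' @param binarize_frac binarization threshold as a fraction of the
#'   median-to-maximum intensity range (half-maximum by default).
#' @return an object of class `registration_result`: fields `shift_px`
#'   (signed integer), `score` (correlation at the optimum),
#'   `resampling_factor`, `search_range`.
#' @export
find_axial_shift <- function(opam_img, oct_img, max_shift = 20,
                             binarize_frac = 0.5) {
  a <- as.matrix(opam_img); b <- as.matrix(oct_img)
  if (!all(dim(a) == dim(b)))
    stop("images must share the same grid after resampling", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("degenerate registration input: image has zero variance", call. = FALSE)
  ab <- a > stats::median(a) + binarize_frac * (max(a) - stats::median(a))
  bb <- b > stats::median(b) + binarize_frac * (max(b) - stats::median(b))
  storage.mode(ab) <- "double"; storage.mode(bb) <- "double"
  n <- nrow(a)
  shifts <- seq(-max_shift, max_shift)
  shifts <- shifts[order(abs(shifts), shifts)]   # ties -> smaller |shift|
  best <- -Inf; best_s <- 0L
  for (s in shifts) {
    if (s >= 0) {
      za <- (1 + s):n; zb <- 1:(n - s)
    } else {
      za <- 1:(n + s); zb <- (1 - s):n
    }
    if (length(za) < 2) next
    va <- as.vector(ab[za, , drop = FALSE])
    vb <- as.vector(bb[zb, , drop = FALSE])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    sc <- stats::cor(va, vb)
    if (sc > best + 1e-12) { best <- sc; best_s <- s }
  }
  structure(list(shift_px = as.integer(best_s), score = best,
                 resampling_factor = 1, search_range = c(-max_shift, max_shift)),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> axial shift %+d px (NCC %.3f, range +/-%d)\n",
              x$shift_px, x$score, x$search_range[2]))
  invisible(x)
}

#' Apply an axial shift to a volume
#'
#' Translates the depth axis by `shift_px` pixels (positive = content moves
#' deeper), zero-padding the vacated samples.
#'
#' @param vol a [scan_volume()].
#' @param shift_px signed integer shift.
#' @return shifted [scan_volume()].
#' @export
apply_axial_shift <- function(vol, shift_px) {
  stopifnot(inherits(vol, "scan_volume"))
  s <- as.integer(round(shift_px))
  if (s == 0L) return(vol)
  d <- dim(vol$data)
  out <- array(0, dim = d)
  if (s > 0) out[(1 + s):d[1], , ] <- vol$data[1:(d[1] - s), , ]
  else out[1:(d[1] + s), , ] <- vol$data[(1 - s):d[1], , ]
  vol$data <- out
  vol$axial_offset_um <- vol$axial_offset_um + s * (vol$pixel_um %||% 0)
  vol
}

#' Estimate the OPAM-to-OCT registration transform from a mesh scan
#'
#' Runs the calibration-phantom workflow: simulate or load paired mesh scans,
#' resample the reconstructed OPAM volume to the OCT axial grid, and search
#' the axial shift on the central frame's binarized images. The returned
#' transform (resampling target + axial shift) is then applied as a fixed
#' transform to tissue scans.
#'
#' @param oct_mesh OCT [scan_volume()] of the mesh target.
#' @param opam_mesh reconstructed OPAM [scan_volume()] of the same target.
#' @param max_shift search range, px.
#' @return a `registration_result` with `target_pixel_um` recorded.
#' @export
register_on_mesh <- function(oct_mesh, opam_mesh, max_shift = 40) {
  opam_rs <- resample_to_grid(opam_mesh, oct_mesh$pixel_um)
  f <- max(1L, dim(oct_mesh$data)[3] %/% 2L)
  nz <- min(dim(oct_mesh$data)[1], dim(opam_rs$data)[1])
  na <- min(dim(oct_mesh$data)[2], dim(opam_rs$data)[2])
  # OPAM has half the angular sampling: compare on the OPAM lateral grid
  ai_oct <- round(seq(1, dim(oct_mesh$data)[2], length.out = na))
  res <- find_axial_shift(opam_rs$data[1:nz, 1:na, f],
                          oct_mesh$data[1:nz, ai_oct, f], max_shift = max_shift)
  res$target_pixel_um <- oct_mesh$pixel_um
  res
}
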