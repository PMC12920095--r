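# Digital Barrett's-mucosa phantoms and calibration targets.

#' Capsule scan configuration
#'
#' Geometry and acquisition parameters of the helical capsule scan, plus the
#' simulator's noise model constants. Defaults follow the instrument
#' operating point for specimen scans (20 Hz rotation, 1 mm/s pullback,
#' 85 kHz OCT A-scan rate with the optoacoustic channel triggered at half
#' that rate, 400 MHz DAQ clock) with desk-scale angular sampling.
#'
#' @param rotation_hz capsule rotation rate (frames per second).
#' @param pullback_mm_s pullback speed, mm/s.
#' @param pullback_mm total pullback distance, mm.
#' @param oct_ascan_hz OCT A-scan rate, Hz.
#' @param opam_ascan_hz optoacoustic A-scan rate, Hz; must equal half the OCT
#'   rate (the OPAM laser is triggered at half the OCT sweep rate).
#' @param daq_hz DAQ sampling rate for raw optoacoustic time series, Hz.
#' @param radius_mm capsule outer radius, mm.
#' @param angle_samples_oct synthetic angular samples per OCT frame (>= 64);
#'   the OPAM frame uses half as many.
#' @param axial_samples_oct OCT depth samples per A-line.
#' @param time_samples_opam raw OPAM time samples per A-line.
#' @param oct_pixel_um OCT axial pixel size, um.
#' @param speed_of_sound speed of sound used for time-depth conversion, m/s.
#' @param oct_noise_sd additive OCT detector noise s.d., as a fraction of the
#'   numerical upper pixel limit.
#' @param speckle_shape gamma shape of the multiplicative unit-mean OCT
#'   speckle (smaller = grainier).
#' @param opam_noise_sd additive white noise s.d. of the raw OPAM channel
#'   (arbitrary pressure units).
#' @param opam_amp0 raw OPAM pulse amplitude of a reference 15-um vessel at
#'   zero depth (arbitrary pressure units).
#' @param fluence_mm1 effective optical fluence decay rate for OPAM, mm^-1.
#' @param opam_axial_offset_um instrumental axial offset of the OPAM time
#'   origin relative to the OCT depth origin (recovered by registration).
#' @param upper_limit numerical upper limit of stored pixel values.
#' @param seed default seed recorded in volume metadata.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(rotation_hz = 20, pullback_mm_s = 1,
                        pullback_mm = 2.6,
                        oct_ascan_hz = 85e3, opam_ascan_hz = oct_ascan_hz / 2,
                        daq_hz = 400e6, radius_mm = 6.25,
                        angle_samples_oct = 360, axial_samples_oct = 320,
                        time_samples_opam = 512, oct_pixel_um = 3.5,
                        speed_of_sound = 1500,
                        oct_noise_sd = 0.006, speckle_shape = 3.7,
                        opam_noise_sd = 1.0, opam_amp0 = 30,
                        fluence_mm1 = 0.5, opam_axial_offset_um = 75,
                        upper_limit = 65535, seed = 1L) {
  for (nm in c("rotation_hz", "pullback_mm_s", "pullback_mm", "oct_ascan_hz",
               "opam_ascan_hz", "daq_hz", "radius_mm", "oct_pixel_um",
               "speed_of_sound"))
    stopifnot_scalar_pos(get(nm), nm)
  if (abs(opam_ascan_hz - oct_ascan_hz / 2) > 1e-6 * oct_ascan_hz)
    stop("OPAM A-scan rate must be half the OCT A-scan rate", call. = FALSE)
  if (angle_samples_oct < 64)
    stop("angle_samples_oct must be >= 64", call. = FALSE)
  cfg <- list(rotation_hz = rotation_hz, pullback_mm_s = pullback_mm_s,
              pullback_mm = pullback_mm, oct_ascan_hz = oct_ascan_hz,
              opam_ascan_hz = opam_ascan_hz, daq_hz = daq_hz,
              radius_mm = radius_mm, angle_samples_oct = angle_samples_oct,
              axial_samples_oct = axial_samples_oct,
              time_samples_opam = time_samples_opam,
              oct_pixel_um = oct_pixel_um, speed_of_sound = speed_of_sound,
              oct_noise_sd = oct_noise_sd, speckle_shape = speckle_shape,
              opam_noise_sd = opam_noise_sd, opam_amp0 = opam_amp0,
              fluence_mm1 = fluence_mm1,
              opam_axial_offset_um = opam_axial_offset_um,
              upper_limit = upper_limit, seed = as.integer(seed))
  cfg$frame_pitch_um <- pullback_mm_s / rotation_hz * 1000
  cfg$n_frames <- max(1L, round(pullback_mm * 1000 / cfg$frame_pitch_um))
  cfg$angle_pitch_rad <- 2 * pi / angle_samples_oct
  cfg$angle_pitch_mm <- radius_mm * cfg$angle_pitch_rad
  class(cfg) <- "scan_config"
  cfg
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf("<scan_config> %g Hz rotation, %g mm/s pullback (%g mm)\n",
              x$rotation_hz, x$pullback_mm_s, x$pullback_mm))
  cat(sprintf("  OCT %g kHz / OPAM %g kHz A-scans, DAQ %g MHz\n",
              x$oct_ascan_hz / 1e3, x$opam_ascan_hz / 1e3, x$daq_hz / 1e6))
  cat(sprintf("  %d angular x %d frames, axial %d px x %g um\n",
              x$angle_samples_oct, x$n_frames, x$axial_samples_oct,
              x$oct_pixel_um))
  invisible(x)
}

# exact truncated-normal (lower bound) draw via the probability integral
# transform, so that draws are deterministic given the RNG state
rtnorm_pos <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(rep(mean, n))
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

#' Build a digital mucosa phantom
#'
#' Lays out a patch of mucosa of the given class: optical layer stack below a
#' flat tissue surface, gland lumens (spheres), superficial pits (vertical
#' tubes, gastric metaplasia type 1), and a depth-distributed vessel
#' population whose lateral arrangement follows the class morphology
#' (random mesh, capillary dots, honeycomb walls with sub-resolution holes,
#' irregular cords, or dilated tumour loops around avascular lacunae).
#' Vessel depths are drawn from a truncated normal distribution.
#'
#' @param profile a [class_profile()].
#' @param extent_mm length-2: pullback extent and circumferential arc extent,
#'   in mm. Must hold at least one 2 x 3 mm feature grid cell.
#' @param seed integer seed; phantoms are bit-identical for a fixed seed.
#' @param marker_angle_rad angular position of the carbon-fibre cap marker in
#'   `[0, 2*pi)`, or `NA` for no marker (region-of-interest patches).
#' @param label_grid build the voxel label grid (depth x lateral x frame)?
#' @return an object of class `phantom_volume` with fields `labels`
#'   (integer voxel grid; 0 above surface, 1..n layer, 6 wire, 7 pit,
#'   8 gland lumen, 9 vessel), `glands`, `pits`, `vessels` (data.frames of
#'   continuous-coordinate primitives), `voxel_um`, `surface_um`,
#'   `marker_angle_rad` and the generating `profile`.
#' @export
build_phantom <- function(profile, extent_mm = c(2.6, 7), seed = 1L,
                          marker_angle_rad = NA_real_, label_grid = TRUE) {
  stopifnot(inherits(profile, "class_profile"))
  if (length(extent_mm) != 2L || extent_mm[1] < 2 || extent_mm[2] < 3)
    stop("extent too small: the phantom must hold at least one 2 x 3 mm feature grid cell",
         call. = FALSE)
  if (!is.na(marker_angle_rad) &&
      (marker_angle_rad < 0 || marker_angle_rad >= 2 * pi))
    stop("marker angle must lie in [0, 2*pi)", call. = FALSE)
  set.seed(as.integer(seed))
  area <- prod(extent_mm)
  surface_um <- 17.5

  glands <- empty_glands()
  gl <- profile$gland_spec
  if (gl$density_mm2 > 0) {
    n <- stats::rpois(1, gl$density_mm2 * area)
    if (n > 0) {
      r <- pmax(30, stats::rnorm(n, gl$radius_um_mean, gl$radius_um_sd))
      glands <- data.frame(
        id = seq_len(n),
        f_mm = stats::runif(n, 0, extent_mm[1]),
        x_mm = stats::runif(n, 0, extent_mm[2]),
        z_um = stats::runif(n, 140, 340),
        radius_um = r,
        lumen_level = pmin(0.9, pmax(0.02,
          stats::rnorm(n, gl$lumen_level, gl$lumen_level_sd)))
      )
    }
  }

  pits <- data.frame(f_mm = numeric(), x_mm = numeric(), radius_um = numeric(),
                     depth_um = numeric(), lumen_level = numeric())
  if (isTRUE(profile$pit_spec)) {
    n <- stats::rpois(1, 12 * area)
    pits <- data.frame(
      f_mm = stats::runif(n, 0, extent_mm[1]),
      x_mm = stats::runif(n, 0, extent_mm[2]),
      radius_um = stats::runif(n, 18, 32),
      depth_um = stats::runif(n, 120, 220),
      lumen_level = stats::runif(n, 0.015, 0.03)
    )
  }

  vessels <- draw_vessels(profile$vessel_spec, extent_mm)

  ph <- structure(list(
    kind = "tissue", profile = profile, extent_mm = extent_mm,
    surface_um = surface_um, voxel_um = c(z = 3.5, x = 50, f = 50),
    glands = glands, pits = pits, vessels = vessels,
    marker_angle_rad = marker_angle_rad, seed = as.integer(seed),
    edge_x_mm = NA_real_, wires = NULL
  ), class = "phantom_volume")
  if (label_grid) ph$labels <- build_label_grid(ph)
  ph
}

empty_glands <- function() {
  data.frame(id = integer(), f_mm = numeric(), x_mm = numeric(),
             z_um = numeric(), radius_um = numeric(), lumen_level = numeric())
}

# vessel populations by morphology; returns point absorbers with diameters
draw_vessels <- function(vs, extent_mm) {
  area <- prod(extent_mm)
  out <- switch(vs$morphology,
    "mesh" = , "capillary-loop" = {
      n <- stats::rpois(1, vs$density_mm2 * area)
      data.frame(
        f_mm = stats::runif(n, 0, extent_mm[1]),
        x_mm = stats::runif(n, 0, extent_mm[2]),
        z_um = rtnorm_pos(n, vs$depth_um_mean, vs$depth_um_sd),
        diam_um = pmax(5, stats::rnorm(n, vs$diam_um_mean, vs$diam_um_sd))
      )
    },
    "honeycomb" = {
      # contiguous walls on a jittered square lattice; the enclosed holes
      # stay below the 300-um lacuna scale of the tumour pattern
      cell_mm <- 0.26
      step_mm <- 0.06
      fs <- seq(0, extent_mm[1], by = cell_mm)
      xs <- seq(0, extent_mm[2], by = cell_mm)
      pts_f <- expand.grid(f = fs, x = seq(0, extent_mm[2], by = step_mm))
      pts_x <- expand.grid(f = seq(0, extent_mm[1], by = step_mm), x = xs)
      f_mm <- c(pts_f$f, pts_x$f) + stats::rnorm(nrow(pts_f) + nrow(pts_x), 0, 0.012)
      x_mm <- c(pts_f$x, pts_x$x) + stats::rnorm(length(f_mm), 0, 0.012)
      n <- length(f_mm)
      data.frame(
        f_mm = f_mm, x_mm = x_mm,
        z_um = rtnorm_pos(n, vs$depth_um_mean, vs$depth_um_sd),
        diam_um = pmax(5, stats::rnorm(n, vs$diam_um_mean, vs$diam_um_sd))
      )
    },
    "irregular" = {
      n_seg <- max(1, stats::rpois(1, vs$density_mm2 * area / 5))
      segs <- lapply(seq_len(n_seg), function(i) {
        f0 <- stats::runif(1, 0, extent_mm[1])
        x0 <- stats::runif(1, 0, extent_mm[2])
        th <- stats::runif(1, 0, 2 * pi)
        len <- stats::runif(1, 0.1, 0.4)
        tt <- seq(0, len, by = 0.06)
        z0 <- rtnorm_pos(1, vs$depth_um_mean, vs$depth_um_sd)
        data.frame(f_mm = f0 + tt * cos(th), x_mm = x0 + tt * sin(th),
                   z_um = z0 + stats::rnorm(length(tt), 0, 15),
                   diam_um = pmax(5, stats::rnorm(length(tt),
                                                  vs$diam_um_mean, vs$diam_um_sd)))
      })
      do.call(rbind, segs)
    },
    "tumour-loop" = {
      # dilated (>= 50 um) vessel loops encircling avascular lacunae of
      # >= 300 um diameter, plus sparse dilated connectors
      fs <- seq(0.5, extent_mm[1] - 0.3, by = 0.95)
      xs <- seq(0.5, extent_mm[2] - 0.3, by = 0.95)
      ctr <- expand.grid(f = fs, x = xs)
      ctr$f <- ctr$f + stats::rnorm(nrow(ctr), 0, 0.06)
      ctr$x <- ctr$x + stats::rnorm(nrow(ctr), 0, 0.06)
      loops <- lapply(seq_len(nrow(ctr)), function(i) {
        rr <- max(0.24, stats::rnorm(1, 0.32, 0.05))   # loop radius, mm
        z0 <- rtnorm_pos(1, vs$depth_um_mean, vs$depth_um_sd)
        th <- seq(0, 2 * pi, length.out = max(10, round(2 * pi * rr / 0.055)))
        th <- th[-length(th)]
        data.frame(
          f_mm = ctr$f[i] + rr * cos(th), x_mm = ctr$x[i] + rr * sin(th),
          z_um = z0 + stats::rnorm(length(th), 0, 10),
          diam_um = pmax(50, stats::rnorm(length(th),
                                          vs$diam_um_mean, vs$diam_um_sd))
        )
      })
      n_extra <- stats::rpois(1, 2 * area)
      extra <- data.frame(
        f_mm = stats::runif(n_extra, 0, extent_mm[1]),
        x_mm = stats::runif(n_extra, 0, extent_mm[2]),
        z_um = rtnorm_pos(n_extra, vs$depth_um_mean, vs$depth_um_sd),
        diam_um = pmax(50, stats::rnorm(n_extra, vs$diam_um_mean, vs$diam_um_sd))
      )
      rbind(do.call(rbind, loops), extra)
    },
    stop("unknown vessel morphology: ", vs$morphology, call. = FALSE)
  )
  out <- out[out$f_mm >= 0 & out$f_mm <= extent_mm[1] &
             out$x_mm >= 0 & out$x_mm <= extent_mm[2], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# integer voxel label grid at the phantom's native voxel size
build_label_grid <- function(ph) {
  vz <- ph$voxel_um["z"]; vx <- ph$voxel_um["x"]; vf <- ph$voxel_um["f"]
  nz <- 320L
  nx <- max(1L, round(ph$extent_mm[2] * 1000 / vx))
  nf <- max(1L, round(ph$extent_mm[1] * 1000 / vf))
  z_um <- (seq_len(nz) - 1) * vz
  depth <- z_um - ph$surface_um        # depth below tissue surface
  lab_z <- integer(nz)                  # 0 above surface, else layer index
  if (ph$kind == "tissue") {
    bounds <- cumsum(ph$profile$layer_spec$thickness_um)
    lab_z[depth >= 0] <- findInterval(depth[depth >= 0], c(0, bounds),
                                      rightmost.closed = FALSE)
    lab_z <- pmin(lab_z, nrow(ph$profile$layer_spec))
  }
  labs <- array(rep(lab_z, times = nx * nf), dim = c(nz, nx, nf))

  paint_sphere <- function(labs, f_mm, x_mm, z_um0, r_um, code) {
    zi <- which(abs(z_um - z_um0) <= r_um)
    xi <- which(abs((seq_len(nx) - 0.5) * vx - x_mm * 1000) <= r_um)
    fi <- which(abs((seq_len(nf) - 0.5) * vf - f_mm * 1000) <= r_um)
    if (!length(zi) || !length(xi) || !length(fi)) return(labs)
    dz2 <- (z_um[zi] - z_um0)^2
    dx2 <- ((xi - 0.5) * vx - x_mm * 1000)^2
    df2 <- ((fi - 0.5) * vf - f_mm * 1000)^2
    m <- outer(outer(dz2, dx2, "+"), df2, "+") <= r_um^2
    sub <- labs[zi, xi, fi, drop = FALSE]
    sub[m] <- code
    labs[zi, xi, fi] <- sub
    labs
  }
  if (nrow(ph$glands))
    for (i in seq_len(nrow(ph$glands)))
      labs <- paint_sphere(labs, ph$glands$f_mm[i], ph$glands$x_mm[i],
                           ph$surface_um + ph$glands$z_um[i],
                           ph$glands$radius_um[i], 8L)
  if (nrow(ph$pits)) {
    for (i in seq_len(nrow(ph$pits))) {
      xi <- which(abs((seq_len(nx) - 0.5) * vx - ph$pits$x_mm[i] * 1000) <=
                    ph$pits$radius_um[i])
      fi <- which(abs((seq_len(nf) - 0.5) * vf - ph$pits$f_mm[i] * 1000) <=
                    ph$pits$radius_um[i])
      zi <- which(depth >= 0 & depth <= ph$pits$depth_um[i])
      if (length(zi) && length(xi) && length(fi)) labs[zi, xi, fi] <- 7L
    }
  }
  if (nrow(ph$vessels)) {
    for (i in seq_len(nrow(ph$vessels)))
      labs <- paint_sphere(labs, ph$vessels$f_mm[i], ph$vessels$x_mm[i],
                           ph$surface_um + ph$vessels$z_um[i],
                           max(ph$vessels$diam_um[i] / 2, ph$voxel_um["z"]), 9L)
  }
  if (!is.null(ph$wires) && nrow(ph$wires)) {
    for (i in seq_len(nrow(ph$wires))) {
      w <- ph$wires[i, ]
      zi <- which(abs(z_um - w$z_um) <= w$diam_um / 2)
      if (is.finite(w$x_mm)) {        # wire along the pullback axis
        xi <- which(abs((seq_len(nx) - 0.5) * vx - w$x_mm * 1000) <= w$diam_um / 2)
        if (length(zi) && length(xi)) labs[zi, xi, ] <- 6L
      } else {                         # wire along the circumferential axis
        fi <- which(abs((seq_len(nf) - 0.5) * vf - w$f_mm * 1000) <= w$diam_um / 2)
        if (length(zi) && length(fi)) labs[zi, , fi] <- 6L
      }
    }
  }
  labs
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s, %g x %g mm\n",
              if (x$kind == "tissue") x$profile$class_label else x$kind,
              x$extent_mm[1], x$extent_mm[2]))
  cat(sprintf("  %d glands, %d pits, %d vessel absorbers\n",
              nrow(x$glands), nrow(x$pits), nrow(x$vessels)))
  invisible(x)
}

#' Calibration target phantoms
#'
#' Builds the instrument calibration scenes: a metal `mesh` of wires used for
#' axial OPAM/OCT co-registration, a reflective half-plane `edge` for
#' edge-spread-function resolution measurements, a single 7-um `point`
#' absorber for axial-resolution and bandwidth characterisation, and the
#' longitudinal `carbon-fibre` cap marker used for frame alignment.
#'
#' @param kind one of `"mesh"`, `"edge"`, `"point"`, `"carbon-fibre"`.
#' @param extent_mm patch extent (pullback, arc), mm.
#' @param pitch_mm mesh wire pitch, mm (mesh only).
#' @param z_um target depth below the tissue/cap surface, um.
#' @param marker_angle_rad marker angle (carbon-fibre only).
#' @return a `phantom_volume` with `profile = NULL` and `kind` set.
#' @export
make_calibration_target <- function(kind = c("mesh", "edge", "point",
                                             "carbon-fibre"),
                                    extent_mm = c(2.6, 7), pitch_mm = 1,
                                    z_um = 150, marker_angle_rad = 0) {
  kind <- match.arg(kind)
  ph <- structure(list(
    kind = kind, profile = NULL, extent_mm = extent_mm, surface_um = 17.5,
    voxel_um = c(z = 3.5, x = 50, f = 50),
    glands = empty_glands(),
    pits = data.frame(), vessels = data.frame(f_mm = numeric(),
                                              x_mm = numeric(), z_um = numeric(),
                                              diam_um = numeric()),
    marker_angle_rad = NA_real_, seed = NA_integer_,
    edge_x_mm = NA_real_, wires = NULL
  ), class = "phantom_volume")
  if (kind == "mesh") {
    xw <- seq(pitch_mm / 2, extent_mm[2], by = pitch_mm)
    fw <- seq(pitch_mm / 2, extent_mm[1], by = pitch_mm)
    ph$wires <- rbind(
      data.frame(x_mm = xw, f_mm = NA_real_, z_um = ph$surface_um + z_um,
                 diam_um = 50),
      data.frame(x_mm = NA_real_, f_mm = fw, z_um = ph$surface_um + z_um,
                 diam_um = 50))
    # absorber points along each wire for the optoacoustic channel
    step <- 0.05
    pts <- lapply(seq_len(nrow(ph$wires)), function(i) {
      w <- ph$wires[i, ]
      if (is.finite(w$x_mm))
        data.frame(f_mm = seq(0, extent_mm[1], by = step), x_mm = w$x_mm,
                   z_um = z_um, diam_um = w$diam_um)
      else
        data.frame(f_mm = w$f_mm, x_mm = seq(0, extent_mm[2], by = step),
                   z_um = z_um, diam_um = w$diam_um)
    })
    ph$vessels <- do.call(rbind, pts)
    ph$mesh_pitch_mm <- pitch_mm
  } else if (kind == "edge") {
    ph$edge_x_mm <- extent_mm[2] / 2
  } else if (kind == "point") {
    ph$vessels <- data.frame(f_mm = extent_mm[1] / 2, x_mm = extent_mm[2] / 2,
                             z_um = z_um, diam_um = 7)
  } else {                              # carbon-fibre cap marker
    if (marker_angle_rad < 0 || marker_angle_rad >= 2 * pi)
      stop("marker angle must lie in [0, 2*pi)", call. = FALSE)
    ph$marker_angle_rad <- marker_angle_rad
  }
  ph$labels <- build_label_grid(ph)
  ph
}
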