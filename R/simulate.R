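# Forward models: OCT intensity volumes and raw OPAM time series from a
# digital phantom under a helical capsule scan.

# A-line lateral geometry shared by both simulators
scan_geometry <- function(phantom, config, modality = c("oct", "opam")) {
  modality <- match.arg(modality)
  full_arc <- 2 * pi * config$radius_mm
  na_full <- config$angle_samples_oct
  pitch_mm <- config$angle_pitch_mm
  if (modality == "opam") {
    na_full <- na_full %/% 2L
    pitch_mm <- pitch_mm * 2
  }
  arc <- min(phantom$extent_mm[2], full_arc)
  na <- if (arc >= full_arc - 1e-9) na_full else max(1L, round(arc / pitch_mm))
  nf <- max(1L, round(phantom$extent_mm[1] * 1000 / config$frame_pitch_um))
  list(na = na, nf = nf, pitch_mm = pitch_mm,
       x_mm = (seq_len(na) - 0.5) * pitch_mm,
       f_mm = (seq_len(nf) - 0.5) * config$frame_pitch_um / 1000)
}

# per-depth backscatter and attenuation profiles for a tissue phantom
layer_profiles <- function(phantom, z_um) {
  nz <- length(z_um)
  b <- numeric(nz); mu <- numeric(nz)
  depth <- z_um - phantom$surface_um
  if (phantom$kind == "tissue") {
    ls <- phantom$profile$layer_spec
    bounds <- cumsum(ls$thickness_um)
    idx <- findInterval(pmax(depth, 0), c(0, bounds), rightmost.closed = FALSE)
    idx <- pmin(pmax(idx, 1L), nrow(ls))
    b <- ifelse(depth >= 0, ls$backscatter[idx], 0)
    mu <- ifelse(depth >= 0, ls$attenuation_mm1[idx], 0)
  } else if (phantom$kind == "edge") {
    b <- ifelse(depth >= 0, 0.02, 0)     # faint uniform background medium
    mu <- ifelse(depth >= 0, 0.5, 0)
  }                                       # mesh/point targets sit in water
  list(b = b, mu = mu)
}

#' Simulate an OCT intensity scan of a phantom
#'
#' Intensity-level forward model for swept-source OCT A-lines: per voxel
#' `I(z) = backscatter(z) * exp(-2 * cumulative attenuation) * speckle +
#' detector noise`, with multiplicative unit-mean gamma speckle and additive
#' Gaussian noise, scaled to the configured numerical pixel range. Gland and
#' pit lumens override the layer backscatter with their calibrated observed
#' lumen level; mesh wires and the carbon-fibre cap marker render as strong
#' reflectors. The epithelium is hypo-reflective and the lamina propria
#' hyper-reflective for the stratified classes.
#'
#' @param phantom a [build_phantom()] or [make_calibration_target()] output.
#' @param config a [scan_config()].
#' @return a [scan_volume()], `modality = "oct"`, values in
#'   `[0, config$upper_limit]`.
#' @export
simulate_oct_scan <- function(phantom, config) {
  stopifnot(inherits(phantom, "phantom_volume"), inherits(config, "scan_config"))
  set.seed(config$seed + 101L)
  g <- scan_geometry(phantom, config, "oct")
  nz <- config$axial_samples_oct
  z_um <- (seq_len(nz) - 1) * config$oct_pixel_um
  lp <- layer_profiles(phantom, z_um)

  # backscatter field: per-depth layer value x lateral texture
  B <- array(rep(lp$b, times = g$na * g$nf), dim = c(nz, g$na, g$nf))
  tex_cv <- if (phantom$kind == "tissue") phantom$profile$texture_cv else 0
  if (tex_cv > 0) {
    tex <- texture_field(g$na, g$nf, tex_cv,
                         corr_px = max(3, round(400 / (g$pitch_mm * 1000))))
    B <- B * rep(tex, each = nz)
  }

  # attenuation along depth (two-way)
  att <- exp(-2 * cumsum(lp$mu * config$oct_pixel_um / 1000))
  S <- B * att

  # gland / pit lumens: calibrated observed level, not attenuated further
  paint_lumen_sphere <- function(S, f_mm, x_mm, z0_um, r_um, level) {
    zi <- which(abs(z_um - z0_um) <= r_um)
    xi <- which(abs(g$x_mm * 1000 - x_mm * 1000) <= r_um)
    fi <- which(abs(g$f_mm * 1000 - f_mm * 1000) <= r_um)
    if (!length(zi) || !length(xi) || !length(fi)) return(S)
    m <- outer(outer((z_um[zi] - z0_um)^2, (g$x_mm[xi] * 1000 - x_mm * 1000)^2,
                     "+"), (g$f_mm[fi] * 1000 - f_mm * 1000)^2, "+") <= r_um^2
    sub <- S[zi, xi, fi, drop = FALSE]
    sub[m] <- level
    S[zi, xi, fi] <- sub
    S
  }
  if (nrow(phantom$glands))
    for (i in seq_len(nrow(phantom$glands)))
      S <- paint_lumen_sphere(S, phantom$glands$f_mm[i], phantom$glands$x_mm[i],
                              phantom$surface_um + phantom$glands$z_um[i],
                              phantom$glands$radius_um[i],
                              phantom$glands$lumen_level[i])
  if (nrow(phantom$pits)) {
    for (i in seq_len(nrow(phantom$pits))) {
      p <- phantom$pits[i, ]
      zi <- which(z_um >= phantom$surface_um &
                  z_um <= phantom$surface_um + p$depth_um)
      xi <- which(abs(g$x_mm - p$x_mm) * 1000 <= p$radius_um)
      fi <- which(abs(g$f_mm - p$f_mm) * 1000 <= p$radius_um)
      if (length(zi) && length(xi) && length(fi)) S[zi, xi, fi] <- p$lumen_level
    }
  }
  if (!is.null(phantom$wires) && nrow(phantom$wires)) {
    for (i in seq_len(nrow(phantom$wires))) {
      w <- phantom$wires[i, ]
      zi <- which(abs(z_um - w$z_um) <= max(w$diam_um / 2, config$oct_pixel_um))
      if (is.finite(w$x_mm)) {
        xi <- which(abs(g$x_mm - w$x_mm) * 1000 <= w$diam_um / 2 + 30)
        if (length(zi) && length(xi)) S[zi, xi, ] <- 0.9
      } else {
        fi <- which(abs(g$f_mm - w$f_mm) * 1000 <= w$diam_um / 2 + 30)
        if (length(zi) && length(fi)) S[zi, , fi] <- 0.9
      }
    }
  }
  if (phantom$kind == "edge" && is.finite(phantom$edge_x_mm)) {
    bright <- g$x_mm < phantom$edge_x_mm
    zi <- which(z_um >= phantom$surface_um)
    S[zi, bright, ] <- 0.8
    S[zi, !bright, ] <- 0.02
  }
  if (is.finite(phantom$marker_angle_rad %||% NA_real_)) {
    xm <- phantom$marker_angle_rad * config$radius_mm
    ai <- which.min(abs(g$x_mm - xm))
    if (abs(g$x_mm[ai] - xm) < 2 * g$pitch_mm) S[1:3, ai, ] <- 0.95
  }

  n_vox <- length(S)
  k <- config$speckle_shape
  speckle <- array(stats::rgamma(n_vox, shape = k, rate = k), dim = dim(S))
  noise <- array(stats::rnorm(n_vox, 0, config$oct_noise_sd), dim = dim(S))
  I <- pmin(S * speckle + noise, 1) * config$upper_limit

  scan_volume(I, modality = "oct", pixel_um = config$oct_pixel_um,
              angle_pitch_rad = config$angle_pitch_rad,
              frame_pitch_um = config$frame_pitch_um,
              radius_mm = config$radius_mm,
              meta = list(seed = config$seed, upper_limit = config$upper_limit,
                          noise_sd = config$oct_noise_sd * config$upper_limit,
                          surface_um = phantom$surface_um,
                          class_label = if (phantom$kind == "tissue")
                            phantom$profile$class_label else phantom$kind))
}

#' Electro-mechanical impulse response specification
#'
#' Gaussian impulse-response model of the ultra-broadband detector, described
#' by its centre frequency; a point absorber then produces an N-shaped
#' (derivative-of-Gaussian) received pulse whose spectrum peaks near
#' `centre_mhz` and rolls off over the stated -6 dB bandwidth.
#'
#' @param centre_mhz spectral peak for a point absorber, MHz.
#' @param bw_mhz nominal -6 dB bandwidth, MHz (metadata).
#' @return list with `centre_mhz`, `bw_mhz`, `sigma_s` (time-domain Gaussian
#'   width in seconds).
#' @export
eir_spec <- function(centre_mhz = 68.5, bw_mhz = 100) {
  stopifnot_scalar_pos(centre_mhz, "centre_mhz")
  stopifnot_scalar_pos(bw_mhz, "bw_mhz")
  list(centre_mhz = centre_mhz, bw_mhz = bw_mhz,
       sigma_s = 1 / (2 * pi * centre_mhz * 1e6))
}

#' Simulate a raw OPAM scan of a phantom
#'
#' Each A-line is the sum, over absorbers intersecting the acoustic beam, of a
#' bipolar N-shaped pressure pulse centred at the one-way time of flight
#' (`depth = c * t`). The pulse is a derivative-of-Gaussian whose temporal
#' width combines the vessel-diameter transit time with the Gaussian
#' electro-mechanical impulse response, so large vessels emit predominantly
#' low-frequency ultrasound and capillaries broadband high-frequency
#' ultrasound. Amplitudes scale with vessel diameter and decay with the
#' optical fluence; white Gaussian noise sets the noise floor. Absorbers
#' whose time of flight falls outside the acquisition window are clipped and
#' counted in `meta$n_clipped`.
#'
#' @param phantom a `phantom_volume`.
#' @param config a [scan_config()].
#' @param eir an [eir_spec()].
#' @return a [scan_volume()], `modality = "opam_raw"`, sampled at
#'   `config$daq_hz`, with the instrumental axial offset
#'   `config$opam_axial_offset_um` baked into the time origin.
#' @export
simulate_opam_scan <- function(phantom, config, eir = eir_spec()) {
  stopifnot(inherits(phantom, "phantom_volume"), inherits(config, "scan_config"))
  set.seed(config$seed + 202L)
  g <- scan_geometry(phantom, config, "opam")
  nt <- config$time_samples_opam
  dps_um <- config$speed_of_sound * 1e6 / config$daq_hz   # um depth per sample
  sigma_eir_smp <- eir$sigma_s * config$daq_hz

  data <- array(stats::rnorm(nt * g$na * g$nf, 0, config$opam_noise_sd),
                dim = c(nt, g$na, g$nf))

  # Gaussian EIR kernel (unit area) for the N-wave convolution
  kr <- ceiling(4 * sigma_eir_smp)
  eir_kernel <- exp(-((-kr):kr)^2 / (2 * sigma_eir_smp^2))
  eir_kernel <- eir_kernel / sum(eir_kernel)

  n_clip <- 0L
  vs <- phantom$vessels
  amp0 <- config$opam_amp0
  if (!is.null(vs) && nrow(vs)) {
    # each A-line integrates over its angular sampling bin: absorbers map to
    # the nearest angular column so that connected structures stay connected
    ai_all <- pmin(g$na, pmax(1L, round(vs$x_mm / g$pitch_mm + 0.5)))
    for (i in seq_len(nrow(vs))) {
      diam_um <- vs$diam_um[i]; z_um <- vs$z_um[i]
      t0 <- (z_um + config$opam_axial_offset_um) / dps_um + 1
      # N-wave half-duration: sphere radius transit time
      tau <- max(((diam_um / 2) * 1e-6 / config$speed_of_sound) * config$daq_hz,
                 0.5)
      sig <- tau + 4 * sigma_eir_smp
      if (t0 > nt - 2 * sig || t0 < 1) {
        n_clip <- n_clip + 1L
        next
      }
      # sharp-fronted bipolar N-wave convolved with the Gaussian EIR: the
      # discontinuous fronts carry the broadband high-frequency content of
      # large absorbers, the ramp the low-frequency bulk
      lo <- max(1, floor(t0 - sig - kr)); hi <- min(nt, ceiling(t0 + sig + kr))
      u <- ((lo - kr):(hi + kr) - t0) / tau
      nwave <- ifelse(abs(u) <= 1, -u, 0)
      pulse <- stats::convolve(nwave, rev(eir_kernel), type = "filter")
      idx <- lo:hi
      amp <- amp0 * (diam_um / 15) * exp(-config$fluence_mm1 * z_um / 1000)
      sig_f <- max(diam_um * 0.7, 25)   # lateral footprint across frames, um
      fi <- which(abs(g$f_mm - vs$f_mm[i]) * 1000 <= 2 * sig_f)
      for (f in fi) {
        w <- exp(-((g$f_mm[f] - vs$f_mm[i]) * 1000)^2 / (2 * sig_f^2))
        data[idx, ai_all[i], f] <- data[idx, ai_all[i], f] + amp * w * pulse
      }
    }
  }
  if (is.finite(phantom$marker_angle_rad %||% NA_real_)) {
    xm <- phantom$marker_angle_rad * config$radius_mm
    ai <- which.min(abs(g$x_mm - xm))
    t0 <- config$opam_axial_offset_um / dps_um + 1
    idx <- max(1, floor(t0 - 6)):min(nt, ceiling(t0 + 6))
    tt <- (idx - t0) / sigma_eir_smp
    for (f in seq_len(g$nf))
      data[idx, ai, f] <- data[idx, ai, f] +
        10 * amp0 * (-tt * exp(-tt^2 / 2))
  }

  scan_volume(data, modality = "opam_raw",
              pixel_um = dps_um,
              sampling_rate_hz = config$daq_hz,
              angle_pitch_rad = config$angle_pitch_rad * 2,
              frame_pitch_um = config$frame_pitch_um,
              radius_mm = config$radius_mm,
              axial_offset_um = config$opam_axial_offset_um,
              meta = list(seed = config$seed, n_clipped = n_clip,
                          eir = eir,
                          noise_sd = config$opam_noise_sd,
                          surface_um = phantom$surface_um,
                          class_label = if (phantom$kind == "tissue")
                            phantom$profile$class_label else phantom$kind))
}
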