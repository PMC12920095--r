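# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic-signal envelope of one or more A-lines
#'
#' Computes `|x + i H(x)|` columnwise via the FFT construction of the analytic
#' signal. Input may be a vector or a matrix with time/depth along rows.
#'
#' @param x numeric vector or matrix (samples in rows).
#' @return object of the same shape containing the non-negative envelope.
#' @keywords internal
#' @noRd
analytic_envelope <- function(x) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  X <- stats::mvfft(xm)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::mvfft(X * h, inverse = TRUE) / n)
  if (v) drop(env) else env
}

# Squared magnitude response of an order-`ord` Butterworth band-pass,
# i.e. the frequency response of the same filter run forward and backward
# (zero phase). `f` in Hz, edges in Hz.
butter_bp_mag2 <- function(f, f_lo, f_hi, ord = 4) {
  lp <- 1 / (1 + (f / f_hi)^(2 * ord))
  hp <- 1 / (1 + ifelse(f == 0, Inf, (f_lo / f)^(2 * ord)))
  lp * hp
}

# Zero-phase band-pass along rows of a matrix (samples in rows): multiply the
# spectrum by the squared Butterworth magnitude.
bandpass_zero_phase <- function(x, fs, f_lo, f_hi, ord = 4) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)                 # two-sided frequency axis
  H2 <- butter_bp_mag2(f, f_lo, f_hi, ord)
  out <- Re(stats::mvfft(stats::mvfft(xm) * H2, inverse = TRUE) / n)
  if (v) drop(out) else out
}

# Band-pass + analytic envelope in a single spectral pass.
bandpass_envelope <- function(x, fs, f_lo, f_hi, ord = 4) {
  v <- is.null(dim(x))
  xm <- if (v) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  f <- (seq_len(n) - 1) / n * fs
  f2 <- pmin(f, fs - f)
  H2 <- butter_bp_mag2(f2, f_lo, f_hi, ord)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  env <- Mod(stats::mvfft(stats::mvfft(xm) * (H2 * h), inverse = TRUE) / n)
  if (v) drop(env) else env
}

# Local extrema (maxima and minima) of a vector with a prominence filter.
# Returns a data.frame with index, value, type ("max"/"min") and prominence.
local_extrema <- function(p, min_prominence = 0) {
  n <- length(p)
  if (n < 3) return(data.frame(index = integer(), value = numeric(),
                               type = character(), prominence = numeric()))
  d <- diff(p)
  s <- sign(d)
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  turn <- which(diff(s) != 0) + 1
  if (!length(turn)) return(data.frame(index = integer(), value = numeric(),
                                       type = character(), prominence = numeric()))
  type <- ifelse(s[turn - 1] > 0, "max", "min")
  prom <- vapply(seq_along(turn), function(i) {
    idx <- turn[i]
    left <- p[seq_len(idx)]
    right <- p[idx:n]
    if (type[i] == "max") {
      min(p[idx] - min(left), p[idx] - min(right))
    } else {
      min(max(left) - p[idx], max(right) - p[idx])
    }
  }, numeric(1))
  keep <- prom >= min_prominence
  data.frame(index = turn[keep], value = p[turn[keep]],
             type = type[keep], prominence = prom[keep])
}

# last-observation-carried-forward for the sign vector above
zoo_na_locf <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(1, length(x)))
  idx <- cumsum(ok)
  idx[idx == 0] <- 1
  x[ok][idx]
}

# Vectorised even-odd (ray casting) point-in-polygon test.
# px, py: points; vx, vy: polygon vertices (closed implicitly).
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Shoelace polygon area (absolute).
polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1))
  abs(sum(vx[j] * vy - vx * vy[j])) / 2
}

# Smooth, unit-mean, positive lateral texture field on an (na x nf) grid.
# Lognormal with coefficient of variation ~ cv and correlation length
# corr_px grid cells (coarse white noise, bilinear upsampling).
texture_field <- function(na, nf, cv, corr_px = 6) {
  if (cv <= 0) return(matrix(1, na, nf))
  s2 <- log(1 + cv^2)
  nc_a <- max(2, ceiling(na / corr_px) + 1)
  nc_f <- max(2, ceiling(nf / corr_px) + 1)
  g <- matrix(stats::rnorm(nc_a * nc_f), nc_a, nc_f)
  xa <- seq(1, nc_a, length.out = na)
  xf <- seq(1, nc_f, length.out = nf)
  ia <- pmin(floor(xa), nc_a - 1); ta <- xa - ia
  iff <- pmin(floor(xf), nc_f - 1); tf <- xf - iff
  up <- (1 - ta) %o% (1 - tf) * g[cbind(rep(ia, nf), rep(iff, each = na))] +
        ta %o% (1 - tf)       * g[cbind(rep(ia + 1, nf), rep(iff, each = na))] +
        (1 - ta) %o% tf       * g[cbind(rep(ia, nf), rep(iff + 1, each = na))] +
        ta %o% tf             * g[cbind(rep(ia + 1, nf), rep(iff + 1, each = na))]
  up <- matrix(up, na, nf)
  # bilinear mixing shrinks the variance; restore unit variance empirically
  up <- up / stats::sd(up)
  exp(sqrt(s2) * up - s2 / 2)
}

# running mean with window w (centred, edge-truncated)
running_mean <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- floor(w / 2)
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
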