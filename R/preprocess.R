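# Derivation of the 9 per-window time-series: tremor-band and
# voluntary-band versions of the accelerometer magnitude and the three
# gyroscope axes, plus the wavelet tremor-band energy of the tremor-band
# accelerometer magnitude.

DERIVED_SERIES_NAMES <- c(
  "trem_acc_mag", "trem_gyr_x", "trem_gyr_y", "trem_gyr_z",
  "vol_acc_mag", "vol_gyr_x", "vol_gyr_y", "vol_gyr_z",
  "wavelet_trem_energy"
)

#' Wavelet tremor-band energy series
#'
#' Continuous wavelet transform (analytic Morlet, centre frequency
#' `omega0 = 6`) of a signal on a fixed 0.1 Hz frequency grid spanning the
#' tremor band, integrated over frequency at each time point:
#' the per-time trapezoidal integral of the wavelet coefficient magnitudes
#' over 3.5-7.5 Hz. Integrating magnitudes rather than the complex
#' coefficients avoids phase cancellation across scales.
#'
#' @param x Numeric vector (typically the tremor-band accelerometer
#'   magnitude of one window).
#' @param fs Sampling rate in Hz; must be at least 15 Hz.
#' @param band Integration band in Hz.
#' @param df Frequency grid step in Hz.
#' @return Numeric vector of per-sample band energy, same length as `x`.
#' @export
wavelet_tremor_energy <- function(x, fs, band = c(3.5, 7.5), df = 0.1) {
  if (fs < 2 * band[2]) stop("fs must be at least twice the upper band edge")
  n <- length(x)
  if (!n) return(numeric(0))
  freqs <- seq(band[1], band[2], by = df)
  pad <- min(n - 1, round(2 * fs))
  xp <- c(x[(pad + 1):2], x, x[(n - 1):(n - pad)]) # even reflection
  np <- length(xp)
  nfft <- stats::nextn(np, 2)
  xz <- c(xp, numeric(nfft - np))
  X <- stats::fft(xz)
  omega0 <- 6
  dt <- 1 / fs
  w <- 2 * pi * (0:(nfft - 1)) / (nfft * dt) # angular frequency grid
  w[w > pi / dt] <- w[w > pi / dt] - 2 * pi / dt
  mags <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i]) # scale in seconds
    psi_hat <- numeric(nfft)
    pos <- w > 0
    psi_hat[pos] <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) * exp(-(s * w[pos] - omega0)^2 / 2)
    Wc <- stats::fft(X * psi_hat, inverse = TRUE) / nfft
    mags[i, ] <- Mod(Wc[(pad + 1):(pad + n)])
  }
  # trapezoidal integral over the frequency grid
  df * (colSums(mags) - (mags[1, ] + mags[nrow(mags), ]) / 2)
}

#' Derive the 9 analysis time-series of one window
#'
#' Applies [tremor_filter()] and [voluntary_filter()] to each sensor
#' channel, collapses the filtered accelerometer axes to their Euclidean
#' magnitude (directionality is irrelevant for tremor), keeps the gyroscope
#' axes separate (rotational tremor is axis-specific), and appends the
#' wavelet tremor-band energy series. The wavelet series is computed on the
#' signed tremor-band accelerometer axes (coefficient magnitudes summed
#' over the three axes), not on their Euclidean magnitude: taking the norm
#' of a coherent oscillation rectifies it, moving its spectral content to
#' DC and twice the tremor frequency, outside the 3.5-7.5 Hz band.
#'
#' @param w A `labelled_window` (or any list with fields `data` and `fs`).
#' @return Named list of 9 numeric vectors in the fixed order
#'   `trem_acc_mag, trem_gyr_x, trem_gyr_y, trem_gyr_z, vol_acc_mag,
#'   vol_gyr_x, vol_gyr_y, vol_gyr_z, wavelet_trem_energy`.
#' @export
derive_series <- function(w) {
  fs <- w$fs
  acc <- w$data[, 1:3, drop = FALSE]
  gyr <- w$data[, 4:6, drop = FALSE]
  trem_acc <- apply(acc, 2, tremor_filter, fs = fs)
  vol_acc <- apply(acc, 2, voluntary_filter, fs = fs)
  trem_mag <- accel_magnitude(trem_acc)
  wav <- wavelet_tremor_energy(trem_acc[, 1], fs) +
    wavelet_tremor_energy(trem_acc[, 2], fs) +
    wavelet_tremor_energy(trem_acc[, 3], fs)
  out <- list(
    trem_acc_mag = trem_mag,
    trem_gyr_x = tremor_filter(gyr[, 1], fs),
    trem_gyr_y = tremor_filter(gyr[, 2], fs),
    trem_gyr_z = tremor_filter(gyr[, 3], fs),
    vol_acc_mag = accel_magnitude(vol_acc),
    vol_gyr_x = voluntary_filter(gyr[, 1], fs),
    vol_gyr_y = voluntary_filter(gyr[, 2], fs),
    vol_gyr_z = voluntary_filter(gyr[, 3], fs),
    wavelet_trem_energy = wav
  )
  stopifnot(identical(names(out), DERIVED_SERIES_NAMES))
  out
}
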