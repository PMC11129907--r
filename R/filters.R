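# Butterworth IIR design in zero-pole-gain form, realised as cascaded
# second-order sections (SOS). A direct-form realisation at order 10 is
# numerically unstable in double precision; SOS cascades are the standard
# remedy and are what this module uses throughout.

#' Design a digital Butterworth filter as second-order sections
#'
#' Designs a lowpass, highpass or bandpass Butterworth filter by the
#' classical analog-prototype + bilinear-transform route and returns the
#' cascade of second-order sections.
#'
#' @param order Filter order of the analog prototype. For `type = "band"`
#'   the resulting digital filter has `2 * order` poles (the convention of
#'   mainstream design routines).
#' @param cutoff_hz Cutoff frequency in Hz (length 1 for low/high, length 2
#'   for band).
#' @param fs Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"band"`.
#' @return A matrix with one row per section and columns
#'   `b0, b1, b2, a0, a1, a2` (with `a0 = 1`), of class `"sos"`.
#' @examples
#' sos <- butter_sos(10, 3.5, fs = 50, type = "high")
#' Mod(sos_freq_response(sos, c(1, 5), fs = 50))
#' @export
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "high", "band")) {
  type <- match.arg(type)
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  # analog Butterworth prototype: poles on the unit circle, no zeros, gain 1
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p <- complex(real = -sin(theta), imaginary = cos(theta))
  z <- complex(0)
  gain <- 1
  fs2 <- 2 * fs
  warped <- fs2 * tan(pi * cutoff_hz / fs) # prewarped edge(s), rad/s

  if (type == "low") {
    p <- warped * p
    gain <- gain * warped^order
  } else if (type == "high") {
    gain <- gain * Re(1 / prod(-p))
    p <- warped / p
    z <- rep(0 + 0i, order)
  } else {
    if (length(cutoff_hz) != 2 || diff(cutoff_hz) <= 0) {
      stop("bandpass design needs cutoff_hz = c(low, high) with low < high")
    }
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    p_l <- p * bw / 2
    p <- c(p_l + sqrt(p_l^2 - wo^2), p_l - sqrt(p_l^2 - wo^2))
    z <- rep(0 + 0i, order)
    gain <- gain * bw^order
  }

  # bilinear transform
  degree <- length(p) - length(z)
  z_d <- (fs2 + z) / (fs2 - z)
  p_d <- (fs2 + p) / (fs2 - p)
  gain <- gain * Re(prod(fs2 - z) / prod(fs2 - p))
  z_d <- c(z_d, rep(-1 + 0i, degree))

  zpk2sos(z_d, p_d, gain)
}

# Pair conjugate poles/zeros into biquad sections. The designs produced by
# butter_sos() have digital zeros exactly at +/-1 and poles in conjugate
# pairs (orders here are even), which keeps the pairing logic simple.
zpk2sos <- function(z, p, k, tol = 1e-8) {
  if (length(z) != length(p)) stop("zpk2sos expects equal numbers of poles and zeros")
  pair_up <- function(r) {
    out <- list()
    r <- r[order(Re(r), abs(Im(r)))]
    used <- rep(FALSE, length(r))
    for (i in seq_along(r)) {
      if (used[i]) next
      if (abs(Im(r[i])) > tol) {
        j <- which(!used & abs(r - Conj(r[i])) < tol * (1 + abs(r[i])))
        j <- setdiff(j, i)
        if (!length(j)) stop("unpaired complex root in zpk2sos")
        used[c(i, j[1])] <- TRUE
        out[[length(out) + 1]] <- c(r[i], r[j[1]])
      }
    }
    reals <- r[!used & abs(Im(r)) <= tol]
    if (length(reals) %% 2 != 0) stop("odd number of real roots not supported")
    if (length(reals)) {
      reals <- reals[order(-abs(reals))]
      for (i in seq(1, length(reals), by = 2)) {
        out[[length(out) + 1]] <- c(reals[i], reals[i + 1])
      }
    }
    out
  }
  pp <- pair_up(p)
  zp <- pair_up(z)
  if (length(pp) != length(zp)) stop("pole/zero section counts differ")
  # order sections: poles nearest the unit circle last (applied with most
  # accumulated attenuation already in place)
  pp <- pp[order(vapply(pp, function(q) max(Mod(q)), 0))]
  # greedy zero assignment: each pole pair takes the zero pair whose mean
  # position is closest (breaks the +1/-1 mix of bandpass designs sensibly)
  zsec <- vector("list", length(pp))
  left <- zp
  for (i in seq_along(pp)) {
    pc <- mean(pp[[i]])
    d <- vapply(left, function(q) Mod(mean(q) - pc), 0)
    j <- which.min(d)
    zsec[[i]] <- left[[j]]
    left <- left[-j]
  }
  ns <- length(pp)
  g <- k^(1 / ns) # distribute overall gain evenly across sections
  sos <- matrix(0, ns, 6, dimnames = list(NULL, c("b0", "b1", "b2", "a0", "a1", "a2")))
  for (i in seq_len(ns)) {
    zz <- zsec[[i]]
    ppx <- pp[[i]]
    sos[i, 1:3] <- g * c(1, -Re(zz[1] + zz[2]), Re(zz[1] * zz[2]))
    sos[i, 4:6] <- c(1, -Re(ppx[1] + ppx[2]), Re(ppx[1] * ppx[2]))
  }
  structure(sos, class = c("sos", "matrix"))
}

#' Apply a second-order-section filter (single pass)
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param x Numeric vector.
#' @param zi Optional initial state, one `(z1, z2)` row per section
#'   (transposed direct form II); defaults to zero state.
#' @return Filtered vector, same length as `x`.
#' @export
sos_filter <- function(sos, x, zi = NULL) {
  x <- as.numeric(x)
  if (!length(x)) return(x)
  if (is.null(zi)) zi <- matrix(0, nrow(sos), 2)
  sosfilt_cpp(unclass(sos), x, zi)
}

# initial state reproducing the steady-state response to a unit step, per
# section, with the step amplitude propagated through the DC gain of the
# preceding sections (the standard filtfilt transient suppression)
sos_filter_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    b <- sos[s, 1:3]
    a1 <- sos[s, 5]
    a2 <- sos[s, 6]
    yss <- sum(b) / (1 + a1 + a2)
    zi[s, 1] <- scale * (yss - b[1])
    zi[s, 2] <- scale * (b[3] - a2 * yss)
    scale <- scale * yss
  }
  zi
}

#' Apply a second-order-section filter forward and backward (zero phase)
#'
#' Odd-reflection padding of three filter lengths plus step-matched initial
#' conditions on both passes keep boundary transients small on finite
#' windows, mirroring the behaviour of mainstream `filtfilt` routines.
#'
#' @param sos SOS matrix from [butter_sos()].
#' @param x Numeric vector.
#' @return Zero-phase filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x) {
  x <- as.numeric(x)
  n <- length(x)
  if (!n) return(x)
  lp <- min(3 * (2 * nrow(sos) + 1), n - 1)
  xp <- if (lp > 0) {
    c(2 * x[1] - x[(lp + 1):2], x, 2 * x[n] - x[(n - 1):(n - lp)])
  } else x
  zi <- sos_filter_zi(sos)
  y <- sos_filter(sos, xp, zi * xp[1])
  y <- rev(sos_filter(sos, rev(y), zi * y[length(y)]))
  y[(lp + 1):(lp + n)]
}

#' Frequency response of an SOS cascade
#'
#' @param sos SOS matrix.
#' @param f Frequencies (Hz) at which to evaluate.
#' @param fs Sampling rate (Hz).
#' @return Complex response at each frequency.
#' @export
sos_freq_response <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  h <- rep(1 + 0i, length(w))
  e1 <- exp(-1i * w)
  e2 <- exp(-2i * w)
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * e1 + sos[s, 3] * e2) /
      (1 + sos[s, 5] * e1 + sos[s, 6] * e2)
  }
  h
}

# settle length of the band filters (samples); windows shorter than three
# settle lengths are refused because boundary transients would dominate
filter_settle_len <- function(fs, settle_s = 2) round(settle_s * fs)

check_filter_len <- function(x, fs) {
  need <- 3 * filter_settle_len(fs)
  if (length(x) < need) {
    stop("window too short for stable filtering (need >= ", need, " samples)")
  }
  invisible(x)
}

#' Isolate the tremor band (3.5-7.5 Hz) of a signal
#'
#' High-pass at 3.5 Hz (order-10 Butterworth) followed by an order-10
#' Butterworth low-pass at 7.5 Hz, the cascade used to separate rest tremor
#' from voluntary movement and high-frequency artefacts. Both stages are
#' applied zero-phase via [sos_filtfilt()] after mean removal, so band
#' outputs stay phase-aligned with their source components.
#'
#' @param x Numeric vector (one sensor channel or magnitude series).
#' @param fs Sampling rate in Hz (must exceed 15 Hz).
#' @return Band-limited series, same length as `x`.
#' @export
tremor_filter <- function(x, fs) {
  if (fs <= 15) stop("fs must exceed 15 Hz for the tremor band")
  check_filter_len(x, fs)
  hp <- butter_sos(10, 3.5, fs, "high")
  lp <- butter_sos(10, 7.5, fs, "low")
  sos_filtfilt(lp, sos_filtfilt(hp, x - mean(x)))
}

#' Isolate the voluntary-movement band (0.5-3 Hz) of a signal
#'
#' Order-10 Butterworth bandpass, applied zero-phase with the same mean
#' removal and length contract as [tremor_filter()].
#'
#' @inheritParams tremor_filter
#' @return Band-limited series, same length as `x`.
#' @export
voluntary_filter <- function(x, fs) {
  if (fs <= 15) stop("fs must exceed 15 Hz")
  check_filter_len(x, fs)
  bp <- butter_sos(10, c(0.5, 3), fs, "band")
  sos_filtfilt(bp, x - mean(x))
}

#' Euclidean magnitude of a 3-channel accelerometer block
#'
#' @param acc Numeric matrix with 3 columns (x, y, z), one row per sample.
#' @return Numeric vector of per-sample Euclidean norms.
#' @export
accel_magnitude <- function(acc) {
  acc <- as.matrix(acc)
  if (ncol(acc) != 3) stop("`acc` must have exactly 3 columns")
  sqrt(rowSums(acc^2))
}
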