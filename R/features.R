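# The 90-feature catalog: for each of the 9 derived series, 5 time-domain
# statistics, 3 frequency-domain features from the Welch PSD, and 2
# nonlinear/regularity features. Feature names are `<series>__<feature>`
# in a fixed order so selections are reproducible.

FEATURE_SUFFIXES <- c("mean", "sd", "iqr", "cv", "rms",
                      "dom_freq", "band_ratio", "spec_entropy",
                      "apen", "acf_zero_lag")

#' Names of the full feature catalog
#'
#' @return Character vector of the 90 feature names in canonical order.
#' @export
feature_names <- function() {
  as.vector(t(outer(DERIVED_SERIES_NAMES, FEATURE_SUFFIXES, paste, sep = "__")))
}

#' Time-domain summary statistics of one series
#'
#' @param s Numeric vector.
#' @return Named vector: `mean`, `sd` (n-1 denominator), `iqr`
#'   (linear-interpolation quantiles), `cv` (`sd/|mean|`, 0 when the mean is
#'   numerically zero), `rms`.
#' @export
time_domain_features <- function(s) {
  if (!length(s)) stop("empty series")
  m <- mean(s)
  sdev <- stats::sd(s)
  if (is.na(sdev)) sdev <- 0
  c(mean = m,
    sd = sdev,
    iqr = stats::IQR(s, type = 7),
    cv = if (abs(m) < 1e-12) 0 else sdev / abs(m),
    rms = sqrt(mean(s^2)))
}

#' Welch power spectral density (8 segments, 50% overlap, Hann taper)
#'
#' Segment length is `floor(2n/9)` so that 8 half-overlapping segments tile
#' the window; segment means are removed before tapering; the one-sided PSD
#' is scaled so that `sum(psd) * df` approximates the signal variance.
#'
#' @param s Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param n_segments Number of segments (default 8).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(s, fs, n_segments = 8) {
  n <- length(s)
  L <- floor(2 * n / (n_segments + 1))
  if (L < 8) stop("series too short for ", n_segments, " half-overlapping segments")
  starts <- round(seq(0, n - L, length.out = n_segments))
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / L)) # periodic Hann
  u <- sum(w^2)
  nb <- floor(L / 2) + 1
  acc <- numeric(nb)
  for (st in starts) {
    seg <- s[(st + 1):(st + L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (fs * u)
    half <- P[1:nb]
    # one-sided: double everything but DC (and Nyquist when L is even)
    dbl <- rep(2, nb)
    dbl[1] <- 1
    if (L %% 2 == 0) dbl[nb] <- 1
    acc <- acc + half * dbl
  }
  list(freq = (0:(nb - 1)) * fs / L, psd = acc / n_segments)
}

#' Frequency-domain features of one series
#'
#' @param s Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Tremor band for the power ratio, Hz.
#' @return Named vector: `dom_freq` (PSD argmax, Hz), `band_ratio` (band
#'   power / total power), `spec_entropy` (Shannon entropy of the
#'   normalised PSD divided by `log(n_bins)`, so 0 for a single-bin spectrum
#'   and 1 for a flat one). A zero-power series maps to all zeros.
#' @export
frequency_features <- function(s, fs, band = c(3.5, 7.5)) {
  p <- welch_psd(s, fs)
  tot <- sum(p$psd)
  if (tot <= 0 || !is.finite(tot)) {
    return(c(dom_freq = 0, band_ratio = 0, spec_entropy = 0))
  }
  pr <- p$psd / tot
  nz <- pr > 0
  h <- -sum(pr[nz] * log(pr[nz])) / log(length(pr))
  inb <- p$freq >= band[1] & p$freq <= band[2]
  c(dom_freq = p$freq[which.max(p$psd)],
    band_ratio = sum(p$psd[inb]) / tot,
    spec_entropy = h)
}

#' Approximate entropy (Pincus)
#'
#' `ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r)` with Chebyshev distance and
#' self-matches included. A constant series returns 0 by convention.
#'
#' @param s Numeric vector of length at least 50 (shorter input errors).
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(s)`.
#' @return Scalar ApEn value.
#' @export
approximate_entropy <- function(s, m = 2, r = NULL) {
  if (length(s) < 50) stop("series too short for approximate entropy (need >= 50)")
  sdev <- stats::sd(s)
  if (sdev < 1e-14) return(0)
  if (is.null(r)) r <- 0.2 * sdev
  if (r <= 0) stop("`r` must be positive")
  apen_cpp(as.numeric(s), as.integer(m), r)
}

#' Lag of the first autocorrelation zero crossing
#'
#' First lag (converted to seconds) at which the biased sample
#' autocorrelation becomes non-positive; 0 by convention for a constant
#' series, and the maximum computed lag if no crossing occurs.
#'
#' @param s Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param max_lag_s Largest lag searched, in seconds.
#' @return Named scalar `acf_zero_lag` (seconds).
#' @export
autocorr_features <- function(s, fs, max_lag_s = 2) {
  if (stats::sd(s) < 1e-14) return(c(acf_zero_lag = 0))
  max_lag <- min(length(s) - 1, round(max_lag_s * fs))
  rho <- stats::acf(s, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[-1]
  k <- which(rho <= 0)
  c(acf_zero_lag = if (length(k)) k[1] / fs else max_lag / fs)
}

# 10 features of one derived series
series_features <- function(s, fs) {
  c(time_domain_features(s),
    frequency_features(s, fs),
    apen = approximate_entropy(s),
    autocorr_features(s, fs))
}

#' Compute the 90-feature vector of one window
#'
#' @param w A `labelled_window`.
#' @return Named numeric vector of length 90 (order of [feature_names()]).
#' @export
window_features <- function(w) {
  der <- derive_series(w)
  out <- unlist(lapply(der, series_features, fs = w$fs), use.names = FALSE)
  names(out) <- feature_names()
  out
}

#' Extract the feature matrix of a window set
#'
#' @param windows List of `labelled_window` objects.
#' @return A `feature_matrix`: list with `features` (n x 90 numeric matrix,
#'   canonical column order), `labels` (integer vector) and `meta`
#'   (data.frame with `subject_id`, `limb`, `window_end_s`).
#' @export
extract_features <- function(windows) {
  if (!length(windows)) stop("no windows supplied")
  X <- t(vapply(windows, window_features, numeric(90)))
  meta <- data.frame(
    subject_id = vapply(windows, `[[`, "", "subject_id"),
    limb = vapply(windows, `[[`, "", "limb"),
    window_end_s = vapply(windows, `[[`, 0, "window_end_s"),
    stringsAsFactors = FALSE
  )
  structure(list(features = X,
                 labels = vapply(windows, `[[`, 0L, "label"),
                 meta = meta),
            class = "feature_matrix")
}

#' Write a feature matrix to CSV (features + `label` column)
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$features)
  df$label <- fm$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# --- mutual information -----------------------------------------------------

# Continuous-feature / discrete-label mutual information by the
# nearest-neighbour estimator of Ross (2014):
#   I = psi(N) - <psi(N_c)> + psi(k) - <psi(m_i)>
# where the k-th nearest same-class neighbour of point i defines a radius
# and m_i counts all points strictly inside it. Implemented with sorted
# vectors (features are scalar).
mi_cont_disc <- function(x, y, k = 3) {
  n <- length(x)
  ord_all <- sort(x)
  classes <- unique(y)
  rad <- rep(NA_real_, n)
  keep <- rep(FALSE, n)
  kk <- rep(k, n)
  for (cl in classes) {
    idx <- which(y == cl)
    nc <- length(idx)
    if (nc <= 1) next
    kc <- min(k, nc - 1)
    xs <- sort(x[idx])
    pos <- findInterval(x[idx], xs) # position of each value in the sorted class
    for (ii in seq_along(idx)) {
      p <- pos[ii]
      # k-th smallest |x - neighbours| among the class, excluding self:
      lo <- max(1, p - kc)
      hi <- min(nc, p + kc)
      d <- abs(xs[lo:hi] - x[idx[ii]])
      d <- sort(d)[kc + 1] # [1] is the self distance 0
      rad[idx[ii]] <- d
      keep[idx[ii]] <- TRUE
      kk[idx[ii]] <- kc
    }
  }
  if (!any(keep)) return(0)
  i <- which(keep)
  # m_i: points of the full sample strictly within rad (count includes self)
  m <- findInterval(x[i] + rad[i], ord_all, left.open = TRUE) + 1 -
    findInterval(x[i] - rad[i], ord_all)
  m <- pmax(m - 1, 1) # exclude the boundary-point convention mismatch; >= 1
  ncl <- as.vector(table(y)[as.character(y[i])])
  mi <- digamma(length(i)) + mean(digamma(kk[i])) -
    mean(digamma(ncl)) - mean(digamma(m))
  max(mi, 0)
}

#' Rank features by mutual information with the class label
#'
#' MI between each (continuous) feature and the (discrete) severity label is
#' estimated with a k-nearest-neighbour continuous/discrete estimator
#' (`k = 3`), with a tiny random jitter (`1e-10` of the feature scale) to
#' break ties, averaged over `n_reps` jitter seeds. Ranking is by descending
#' MI with deterministic name-order tie-breaking. MI is computed on the
#' full, pre-resampling matrix.
#'
#' @param fm A `feature_matrix` (or a list with `features` and `labels`).
#' @param k Neighbour count of the estimator.
#' @param n_reps Number of jitter repetitions averaged.
#' @param seed Seed for the jitter.
#' @return Data.frame `feature`, `mi` (nats), `rank`, `selected` (top 30),
#'   of class `"mi_ranking"`, ordered by rank.
#' @export
mutual_information_ranking <- function(fm, k = 3, n_reps = 5, seed = 1L) {
  X <- fm$features
  y <- fm$labels
  if (length(unique(y)) < 2) stop("need at least 2 classes for MI ranking")
  set.seed(seed)
  nf <- ncol(X)
  mi <- numeric(nf)
  for (rep in seq_len(n_reps)) {
    for (j in seq_len(nf)) {
      x <- X[, j]
      if (stats::sd(x) < 1e-14) next # constant feature: MI exactly 0
      scale <- max(1, mean(abs(x)))
      x <- x + stats::rnorm(length(x), sd = 1e-10 * scale)
      mi[j] <- mi[j] + mi_cont_disc(x, y, k)
    }
  }
  mi <- mi / n_reps
  nm <- colnames(X)
  ord <- order(-mi, nm)
  out <- data.frame(feature = nm[ord], mi = mi[ord], rank = seq_len(nf),
                    selected = seq_len(nf) <= 30, stringsAsFactors = FALSE)
  class(out) <- c("mi_ranking", "data.frame")
  out
}

#' Select the top-k features of an MI ranking
#'
#' @param ranking An `mi_ranking`.
#' @param k Number of features to keep (default 30).
#' @return Character vector of the `k` selected feature names, in rank order.
#' @export
select_top_k <- function(ranking, k = 30) {
  if (k > nrow(ranking)) stop("k exceeds the number of ranked features")
  ranking$feature[seq_len(k)]
}
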