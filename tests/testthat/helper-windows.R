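# Build one labelled 30 s window directly from signal components (no full
# session needed): voluntary movement on every channel, a tremor oscillation
# projected on random fixed directions, sensor noise, gravity on acc z.
make_synthetic_window <- function(severity, seed, fs = 50, window_s = 30,
                                  amp = c(0, 0.5, 2), noise_sd = 0.1,
                                  gyr_scale = 30) {
  set.seed(seed)
  dir_a <- stats::rnorm(3); dir_a <- dir_a / sqrt(sum(dir_a^2))
  dir_g <- stats::rnorm(3); dir_g <- dir_g / sqrt(sum(dir_g^2))
  n <- round(window_s * fs)
  noise_a <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  noise_g <- matrix(stats::rnorm(3 * n, sd = noise_sd * gyr_scale), n, 3)
  trem_a <- tremor_component(severity, window_s, fs, amp = amp, seed = seed * 7L + 1L)
  trem_g <- tremor_component(severity, window_s, fs, amp = amp * gyr_scale,
                             seed = seed * 7L + 2L)
  acc <- vapply(1:3, function(ch)
    voluntary_component(window_s, fs, seed = seed * 31L + ch), numeric(n))
  gyr <- gyr_scale * vapply(1:3, function(ch)
    voluntary_component(window_s, fs, seed = seed * 37L + ch), numeric(n))
  acc <- acc + outer(trem_a, dir_a) + noise_a
  gyr <- gyr + outer(trem_g, dir_g) + noise_g
  acc[, 3] <- acc[, 3] + 9.81
  dat <- cbind(acc, gyr)
  colnames(dat) <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  structure(list(subject_id = "T01", limb = "right_wrist",
                 label = as.integer(severity), data = dat,
                 window_end_s = window_s, fs = fs),
            class = "labelled_window")
}

make_window_set <- function(seed, n0 = 20, n1 = 12, n2 = 8, ...) {
  sev <- c(rep(0L, n0), rep(1L, n1), rep(2L, n2))
  lapply(seq_along(sev), function(i)
    make_synthetic_window(sev[i], seed = seed * 1000L + i, ...))
}

# expensive end-to-end runs are computed once and shared across test files
.tk_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .tk_cache)) assign(name, force(expr), envir = .tk_cache)
  get(name, envir = .tk_cache)
}

separated_config <- function(noise_sd = 0.05) {
  session_config(tremor_amp = c(0, 1, 4), noise_sd = noise_sd, nodata_prob = 0.02)
}
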