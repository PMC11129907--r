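# Independent brute-force oracle for approximate entropy: plain double-loop
# transcription of the Phi_m definition, kept free of any package internals.
apen_brute <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  phi <- function(m) {
    n <- length(x)
    nt <- n - m + 1
    C <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) cnt <- cnt + 1
      }
      C[i] <- cnt / nt
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

# Independent occupancy-modal label over (t0, t1]: scans the full schedule
# with plain vector arithmetic.
modal_label_oracle <- function(schedule, t0, t1) {
  ov <- pmin(schedule$end_s, t1) - pmax(schedule$start_s, t0)
  ov[ov < 0] <- 0
  occ <- c(sum(ov[schedule$severity == 0]),
           sum(ov[schedule$severity == 1]),
           sum(ov[schedule$severity == 2]))
  which.max(occ) - 1L
}

make_sine <- function(f, fs = 50, n = 1500, amp = 1) {
  amp * sin(2 * pi * f * (0:(n - 1)) / fs)
}
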