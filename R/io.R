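# Reading/writing recordings and score logs, and cutting the 30-second
# pre-score windows that form the analysis samples.

RECORDING_HEADER <- c("time", "acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")

#' Write an IMU recording to CSV
#'
#' Columns `time,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z` in SI units
#' (s, m/s^2, deg/s).
#'
#' @param rec An `imu_recording`.
#' @param path Output file path.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time = rec$t, rec$acc, rec$gyr)
  names(df) <- RECORDING_HEADER
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an IMU recording from CSV
#'
#' Rejects malformed headers, wrong channel counts, non-monotone or
#' non-uniform timestamps, and gaps larger than two sample periods.
#'
#' @param path CSV file written by [write_recording()] (or conforming to its
#'   dialect).
#' @param subject_id,limb Metadata to attach (the CSV carries none).
#' @return An `imu_recording`.
#' @export
load_recording <- function(path, subject_id = "unknown", limb = "right_wrist") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!identical(names(df), RECORDING_HEADER)) {
    stop("format error: expected header ", paste(RECORDING_HEADER, collapse = ","),
         " but found ", paste(names(df), collapse = ","))
  }
  if (any(!vapply(df, is.numeric, TRUE))) stop("format error: non-numeric column")
  if (anyNA(df)) stop("format error: missing values at row ", which(rowSums(is.na(df)) > 0)[1])
  t <- df$time
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop("format error: non-monotone time at row ", which(dt <= 0)[1] + 1)
  }
  dt0 <- stats::median(dt)
  if (any(dt > 2 * dt0 + 1e-12)) {
    stop("format error: timestamp gap > 2/fs after row ", which(dt > 2 * dt0 + 1e-12)[1])
  }
  if (any(abs(dt - dt0) > 1e-9)) {
    stop("format error: non-uniform timestamps at row ",
         which(abs(dt - dt0) > 1e-9)[1] + 1)
  }
  structure(list(subject_id = subject_id, limb = match.arg(limb, LIMBS),
                 t = t, acc = as.matrix(df[, 2:4]), gyr = as.matrix(df[, 5:7]),
                 fs = 1 / dt0),
            class = "imu_recording")
}

#' Write / read a clinician score log
#'
#' CSV `time,limb,label` with label in `{0, 1, 2, NA}` (`NA` = `NO_DATA`).
#'
#' @param events Data.frame with columns `time_s`, `label`, `limb`.
#' @param path File path.
#' @export
write_score_log <- function(events, path) {
  utils::write.csv(data.frame(time = events$time_s, limb = events$limb,
                              label = events$label),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_score_log
#' @return `load_score_log()` returns the events data.frame.
#' @export
load_score_log <- function(path) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("time", "limb", "label"))) {
    stop("format error: expected header time,limb,label")
  }
  bad <- !(is.na(df$label) | df$label %in% 0:2)
  if (any(bad)) stop("format error: invalid label at row ", which(bad)[1])
  data.frame(time_s = df$time, label = as.integer(df$label), limb = df$limb,
             stringsAsFactors = FALSE)
}

#' Export labelled windows as long-format CSV
#'
#' One row per sample: `window_id, subject_id, limb, label, window_end_s,
#' sample, acc_x..gyr_z`.
#'
#' @param windows List of `labelled_window` objects.
#' @param path Output file path.
#' @export
write_windows <- function(windows, path) {
  parts <- lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    data.frame(window_id = i, subject_id = w$subject_id, limb = w$limb,
               label = w$label, window_end_s = w$window_end_s,
               sample = seq_len(nrow(w$data)), w$data,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' Cut labelled 30-second windows preceding each score entry
#'
#' Each scored window is the half-open interval `(t_score - 30, t_score]` of
#' the limb's sensor stream. `NO_DATA` scores, scores with fewer than 30 s of
#' preceding data, and scores beyond the recorded span are skipped (counts
#' are attached as attributes, not errors). Events must belong to the
#' recording's limb so that sensor stream and label stay limb-matched.
#'
#' @param rec An `imu_recording`.
#' @param events Score events data.frame (`time_s`, `label`, `limb`).
#' @param window_s Window length in seconds (default 30).
#' @return List of `labelled_window` objects (fields `subject_id`, `limb`,
#'   `label`, `data` — a `round(window_s * fs)` x 6 matrix with columns
#'   `acc_x..gyr_z` — and `window_end_s`), with attributes
#'   `n_skipped_nodata` and `n_skipped_short`.
#' @export
extract_windows <- function(rec, events, window_s = 30) {
  if (!inherits(rec, "imu_recording")) stop("`rec` must be an imu_recording")
  if (any(events$limb != rec$limb)) {
    stop("events belong to limb(s) ", paste(unique(events$limb), collapse = ", "),
         " but recording is from ", rec$limb)
  }
  fs <- rec$fs
  wlen <- round(window_s * fs)
  n <- length(rec$t)
  t0 <- rec$t[1]
  windows <- list()
  skipped_nodata <- 0L
  skipped_short <- 0L
  for (e in seq_len(nrow(events))) {
    lab <- events$label[e]
    if (is.na(lab)) {
      skipped_nodata <- skipped_nodata + 1L
      next
    }
    ie <- round((events$time_s[e] - t0) * fs) + 1 # sample at the score time
    is <- ie - wlen + 1
    if (is < 1 || ie > n) {
      skipped_short <- skipped_short + 1L
      next
    }
    dat <- cbind(rec$acc[is:ie, , drop = FALSE], rec$gyr[is:ie, , drop = FALSE])
    colnames(dat) <- RECORDING_HEADER[-1]
    windows[[length(windows) + 1]] <- structure(
      list(subject_id = rec$subject_id, limb = rec$limb, label = as.integer(lab),
           data = dat, window_end_s = events$time_s[e], fs = fs),
      class = "labelled_window"
    )
  }
  attr(windows, "n_skipped_nodata") <- skipped_nodata
  attr(windows, "n_skipped_short") <- skipped_short
  windows
}
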