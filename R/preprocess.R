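#' Band-pass filter a recording
#'
#' Applies a Butterworth band-pass (default 5th order, 2-30 Hz) to every
#' channel. The filter is applied forward and backward (zero-phase), which
#' doubles the effective order; only band power is consumed downstream, so
#' the magnitude-squared response is what matters.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz; must satisfy 0 < low < high < fs/2.
#' @param order Butterworth design order (per pass).
#' @return the filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, low = 2, high = 30, order = 5) {
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= rec$fs / 2) stop("high edge must be below the Nyquist rate")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec
  out$samples <- t(filtfilt_mat(bf$b, bf$a, t(rec$samples)))
  rownames(out$samples) <- rownames(rec$samples)
  out
}

# Zero-phase IIR filtering of every column of a time x channel matrix, with
# the same end-padding convention as signal::filtfilt (2*max(na,nb) zeros),
# but batched over channels through stats::filter.
filtfilt_mat <- function(b, a, x) {
  npad <- 2L * max(length(a), length(b))
  xp <- rbind(x, matrix(0, npad, ncol(x)))
  y <- iir_mat(b, a, xp)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y <- iir_mat(b, a, y)
  y <- y[rev(seq_len(nrow(y))), , drop = FALSE]
  y[seq_len(nrow(x)), , drop = FALSE]
}

iir_mat <- function(b, a, x) {
  if (abs(a[1] - 1) > 1e-12) {
    b <- b / a[1]
    a <- a / a[1]
  }
  nb <- length(b)
  xp <- rbind(matrix(0, nb - 1L, ncol(x)), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1L)
  v <- v[nb:nrow(xp), , drop = FALSE]
  if (length(a) > 1L) {
    v <- stats::filter(v, -a[-1], method = "recursive")
  }
  matrix(as.numeric(v), nrow(x), ncol(x))
}

#' Detect and remove blink transients
#'
#' Blink correction by template regression: candidate blinks are detected on
#' the AFz channel (low-passed below 8 Hz, amplitude criterion), and within
#' +/-300 ms of each detection the low-passed AFz waveform is used as a blink
#' template and regressed out of every channel. Samples outside blink windows
#' are untouched, so the background spectrum is preserved. In `"reject"` mode
#' nothing is subtracted; the detected windows are returned so the epochs
#' overlapping them can be marked as artifacts instead.
#'
#' @param rec an [eeg_recording()]; the montage must include AFz (or the
#'   first frontal channel is used).
#' @param mode `"correct"` (regress the template out) or `"reject"` (detect
#'   only).
#' @param threshold detection amplitude on the low-passed AFz, in uV.
#' @param window half-width of the correction window, seconds.
#' @return list with `recording`, `blink_count`, and `windows` (two-column
#'   matrix of sample indices).
#' @export
correct_blinks <- function(rec, mode = c("correct", "reject"),
                           threshold = 40, window = 0.3) {
  mode <- match.arg(mode)
  if (!length(rec$montage$frontal)) stop("montage has no frontal channels")
  fs <- rec$fs
  det_ch <- if ("AFz" %in% rec$montage$labels) "AFz" else
    rec$montage$frontal[1]
  lp <- signal::butter(4, 8 / (fs / 2), type = "low")
  smoothed <- signal::filtfilt(lp, rec$samples[det_ch, ])
  above <- which(abs(smoothed) > threshold)
  if (!length(above)) {
    return(list(recording = rec, blink_count = 0L,
                windows = matrix(integer(0), 0, 2)))
  }
  # cluster suprathreshold samples separated by < 150 ms into single events
  # (a blink's own two lobes merge; distinct blinks >= 300 ms apart resolve)
  gap <- which(diff(above) > round(0.15 * fs))
  starts <- above[c(1L, gap + 1L)]
  ends <- above[c(gap, length(above))]
  peaks <- mapply(function(s, e) {
    s + which.max(abs(smoothed[s:e])) - 1L
  }, starts, ends)
  half <- round(window * fs)
  n <- ncol(rec$samples)
  windows <- cbind(pmax(1L, peaks - half), pmin(n, peaks + half))
  out <- rec
  if (mode == "correct") {
    for (k in seq_len(nrow(windows))) {
      idx <- windows[k, 1]:windows[k, 2]
      b <- smoothed[idx]
      denom <- sum(b^2)
      if (denom == 0) next
      for (ch in seq_len(nrow(out$samples))) {
        beta <- sum(out$samples[ch, idx] * b) / denom
        out$samples[ch, idx] <- out$samples[ch, idx] - beta * b
      }
    }
  }
  list(recording = out, blink_count = length(peaks), windows = windows)
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive non-overlapping epochs (default 1 s); a trailing partial epoch
#' is discarded. The artifact mask starts all-clean.
#'
#' @param rec an [eeg_recording()].
#' @param epoch_length epoch duration in seconds.
#' @return an object of class `eeg_epochs`: array `epochs`
#'   (epoch x channel x sample), `fs`, `epoch_length`, logical
#'   `artifact_mask` (TRUE = rejected), `montage`, `meta`.
#' @export
segment_epochs <- function(rec, epoch_length = 1.0) {
  n_per <- round(rec$fs * epoch_length)
  n_ep <- floor(ncol(rec$samples) / n_per)
  if (n_ep < 1L) stop("recording shorter than one epoch")
  arr <- array(NA_real_, c(n_ep, nrow(rec$samples), n_per))
  for (e in seq_len(n_ep)) {
    arr[e, , ] <- rec$samples[, ((e - 1L) * n_per + 1L):(e * n_per)]
  }
  structure(list(epochs = arr, fs = rec$fs, epoch_length = epoch_length,
                 artifact_mask = rep(FALSE, n_ep), montage = rec$montage,
                 meta = rec$meta),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("EEG epochs: %d x %g s (%d channels), %d marked artifact\n",
              dim(x$epochs)[1], x$epoch_length, dim(x$epochs)[2],
              sum(x$artifact_mask)))
  invisible(x)
}

#' Mark amplitude-threshold artifacts
#'
#' An epoch is rejected when any sample on any channel exceeds the threshold
#' in absolute value (the whole epoch is rejected on an any-channel
#' violation). The mask is monotone in the threshold: raising it never
#' rejects more epochs. Marks are combined with any existing mask by OR.
#'
#' @param epochs an `eeg_epochs` object.
#' @param threshold amplitude threshold in uV (positive).
#' @return `epochs` with an updated `artifact_mask`.
#' @export
mark_amplitude_artifacts <- function(epochs, threshold = 80) {
  if (threshold <= 0) stop("threshold must be positive")
  peak <- apply(abs(epochs$epochs), 1L, max)
  epochs$artifact_mask <- epochs$artifact_mask | (peak > threshold)
  epochs
}

# Mark epochs overlapping detected blink windows (used in "reject" mode).
mark_blink_artifacts <- function(epochs, windows, offset = 0L) {
  if (!nrow(windows)) return(epochs)
  n_per <- round(epochs$fs * epochs$epoch_length)
  n_ep <- dim(epochs$epochs)[1]
  ep_start <- (seq_len(n_ep) - 1L) * n_per + 1L + offset
  ep_end <- ep_start + n_per - 1L
  hit <- vapply(seq_len(n_ep), function(e) {
    any(windows[, 1] <= ep_end[e] & windows[, 2] >= ep_start[e])
  }, logical(1))
  epochs$artifact_mask <- epochs$artifact_mask | hit
  epochs
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed order: band-pass filter, blink handling, edge trimming (1 s at each
#' end, removing filter transients), epoching, amplitude-threshold rejection.
#'
#' @inheritParams bandpass_filter
#' @inheritParams segment_epochs
#' @inheritParams mark_amplitude_artifacts
#' @param blink_mode `"correct"`, `"reject"`, or `"off"`.
#' @param trim seconds trimmed from each end after filtering.
#' @return an `eeg_epochs` object ready for band-power computation.
#' @export
preprocess_recording <- function(rec, low = 2, high = 30, order = 5,
                                 blink_mode = c("correct", "reject", "off"),
                                 epoch_length = 1.0, threshold = 80,
                                 trim = 1.0) {
  blink_mode <- match.arg(blink_mode)
  rec <- bandpass_filter(rec, low, high, order)
  windows <- matrix(integer(0), 0, 2)
  if (blink_mode != "off") {
    bl <- correct_blinks(rec, mode = if (blink_mode == "reject") "reject"
                                     else "correct")
    rec <- bl$recording
    windows <- bl$windows
  }
  n_trim <- round(trim * rec$fs)
  if (ncol(rec$samples) > 2 * n_trim + round(rec$fs * epoch_length)) {
    rec$samples <- rec$samples[, (n_trim + 1L):(ncol(rec$samples) - n_trim),
                               drop = FALSE]
  } else {
    n_trim <- 0L
  }
  ep <- segment_epochs(rec, epoch_length)
  ep <- mark_amplitude_artifacts(ep, threshold)
  if (blink_mode == "reject") {
    ep <- mark_blink_artifacts(ep, windows, offset = n_trim)
  }
  ep
}
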