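# Welch power spectral density estimation (Hanning window, one-sided,
# window-power compensated so that sum(psd) * df equals the mean square of
# the analysed signal for broadband input and amp^2/2 for a pure tone whose
# spectral spread lies inside the summed band).

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

#' Welch PSD of a single channel
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param window_sec segment length in seconds (default 2 s, 0.5 Hz
#'   resolution); `overlap` fraction between consecutive segments.
#' @return list with `freq` (Hz, one-sided) and `psd` (uV^2/Hz).
#' @export
welch_psd <- function(x, fs, window_sec = 2, overlap = 0.5) {
  nw <- round(window_sec * fs)
  if (length(x) < nw) stop("signal shorter than one Welch window")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- hann_window(nw)
  acc <- numeric(nw)
  for (s in starts) {
    X <- stats::fft(w * x[s:(s + nw - 1L)])
    acc <- acc + Mod(X)^2
  }
  pxx <- acc / (length(starts) * fs * sum(w^2))
  half <- floor(nw / 2) + 1L
  one <- pxx[seq_len(half)]
  if (nw %% 2 == 0) {
    one[2:(half - 1L)] <- 2 * one[2:(half - 1L)]
  } else {
    one[2:half] <- 2 * one[2:half]
  }
  list(freq = fs * (seq_len(half) - 1L) / nw, psd = one)
}

# Periodograms for every (epoch, channel) pair of an epoch array in one
# batched FFT; returns freq vector and a [epoch, channel, freq] array.
epoch_periodograms <- function(epochs) {
  d <- dim(epochs$epochs)
  n_ep <- d[1]; n_ch <- d[2]; n <- d[3]
  w <- hann_window(n)
  flat <- matrix(aperm(epochs$epochs, c(3, 1, 2)), nrow = n,
                 ncol = n_ep * n_ch)
  X <- stats::mvfft(flat * w)
  pxx <- Mod(X)^2 / (epochs$fs * sum(w^2))
  half <- floor(n / 2) + 1L
  pxx <- pxx[seq_len(half), , drop = FALSE]
  if (n %% 2 == 0) {
    pxx[2:(half - 1L), ] <- 2 * pxx[2:(half - 1L), ]
  } else {
    pxx[2:half, ] <- 2 * pxx[2:half, ]
  }
  arr <- array(t(pxx), c(n_ep, n_ch, half))
  list(freq = epochs$fs * (seq_len(half) - 1L) / n, pxx = arr)
}

band_integral <- function(freq, psd, band) {
  df <- freq[2] - freq[1]
  sel <- freq >= band[1] & freq <= band[2]
  sum(psd[sel]) * df
}
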