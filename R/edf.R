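# Minimal 16-bit European Data Format (EDF) I/O.
#
# Supports what the pipeline needs: continuous multi-channel recordings with
# a common sampling rate, physical dimension uV (or mV), one data record
# holding the whole segment. Values are quantized to the 16-bit digital
# range, so round-trips agree to within (physical range)/65534 per channel.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  pad_field(s, width)
}

#' Write a recording to EDF
#'
#' @param rec an [eeg_recording()]; `fs` is written into the single data
#'   record's duration, so any duration is representable.
#' @param path output file.
#' @param physical_dim physical dimension label, default `"uV"`.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path, physical_dim = "uV") {
  mat <- rec$samples
  ns <- nrow(mat)
  n <- ncol(mat)
  pmax_ <- pmax(apply(abs(mat), 1L, max), 1)
  pmax_ <- pmax_ * 1.0001
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(paste0("subject ", rec$meta$subject_id), 80),
    pad_field(paste0("eegmetrics ", rec$meta$kind, " ",
                     rec$meta$condition), 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256 + 256 * ns, 8),
    pad_field("", 44),
    pad_field(1, 8),
    num_field(n / rec$fs, 8),
    pad_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig <- paste0(
    paste(vapply(rec$montage$labels, pad_field, "", width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(physical_dim, 8), ns), collapse = ""),
    paste(vapply(-pmax_, num_field, "", width = 8), collapse = ""),
    paste(vapply(pmax_, num_field, "", width = 8), collapse = ""),
    paste(rep(pad_field(-32767, 8), ns), collapse = ""),
    paste(rep(pad_field(32767, 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(n, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = "")
  )
  writeChar(sig, con, eos = NULL)
  # re-read the physical extremes exactly as an EDF consumer will parse them,
  # so quantization is anchored to the stored (truncated) header strings
  pmin_s <- as.numeric(vapply(-pmax_, num_field, "", width = 8))
  pmax_s <- as.numeric(vapply(pmax_, num_field, "", width = 8))
  for (ch in seq_len(ns)) {
    dig <- round((mat[ch, ] - pmin_s[ch]) / (pmax_s[ch] - pmin_s[ch]) *
                   65534 - 32767)
    dig <- pmin(pmax(dig, -32767), 32767)
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                       # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  nsamp <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  out <- vector("list", ns)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nsamp[ch], size = 2L,
                     endian = "little")
      phys <- (dig - dmin_[ch]) / (dmax_[ch] - dmin_[ch]) *
        (pmax_[ch] - pmin_[ch]) + pmin_[ch]
      out[[ch]] <- c(out[[ch]], phys)
    }
  }
  samples <- do.call(rbind, out)
  rownames(samples) <- labels
  list(samples = samples, labels = labels, units = units,
       fs = nsamp[1] / (rec_dur / 1), n_records = n_rec)
}
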