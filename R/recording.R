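#' Multi-channel EEG recording
#'
#' Container for one continuous EEG segment: a channels-by-samples matrix in
#' microvolts, its sampling rate, the montage, and study metadata (subject,
#' group, condition, and whether the segment is a task or an eyes-closed rest
#' recording).
#'
#' @param samples numeric matrix, channels x samples, microvolts. Row order
#'   must follow `montage$labels`.
#' @param fs sampling rate in Hz.
#' @param montage an [channel_montage()] object.
#' @param subject_id,group,condition,kind metadata strings; `kind` is
#'   `"task"` or `"rest"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, montage = channel_montage(),
                          subject_id = NA_character_, group = NA_character_,
                          condition = NA_character_, kind = "task") {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(montage$labels)) {
    stop("samples must have one row per montage channel")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be > 0")
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  rownames(samples) <- montage$labels
  structure(
    list(samples = samples, fs = fs, montage = montage,
         meta = list(subject_id = subject_id, group = group,
                     condition = condition, kind = kind)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / x$fs, x$fs))
  m <- x$meta
  cat(sprintf("  subject=%s group=%s condition=%s kind=%s\n",
              m$subject_id, m$group, m$condition, m$kind))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' Write a recording as a long CSV
#'
#' Columns: `time_s`, `channel`, `value_uV`. The channel column follows the
#' montage order, samples within channel are in time order.
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  n <- ncol(rec$samples)
  t <- (seq_len(n) - 1L) / rec$fs
  df <- data.frame(
    time_s = rep(t, times = nrow(rec$samples)),
    channel = rep(rec$montage$labels, each = n),
    value_uV = as.vector(t(rec$samples))
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from EDF or long CSV
#'
#' CSV input must have columns `time_s`, `channel`, `value_uV` (any channel
#' order; rows are re-ordered to the montage). EDF input is the 16-bit
#' European Data Format as written by [write_recording_edf()]; physical
#' dimension must resolve to microvolts (uV or mV).
#'
#' @param path input file.
#' @param format `"edf"` or `"csv"`; default guesses from the extension.
#' @param montage target [channel_montage()]; the file must contain at least
#'   these channels, and the result rows follow montage order.
#' @param fs sampling rate, required for CSV when the file has fewer than two
#'   time points per channel; otherwise inferred from `time_s`.
#' @inheritParams eeg_recording
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           montage = channel_montage(), fs = NULL,
                           subject_id = NA_character_,
                           group = NA_character_,
                           condition = NA_character_, kind = "task") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("time_s", "channel", "value_uV")
    if (!all(need %in% names(df))) {
      stop("CSV recording must have columns: ", paste(need, collapse = ", "))
    }
    missing <- setdiff(montage$labels, unique(df$channel))
    if (length(missing)) {
      stop("recording lacks montage channel(s): ",
           paste(missing, collapse = ", "))
    }
    mat <- NULL
    for (lab in montage$labels) {
      sub <- df[df$channel == lab, , drop = FALSE]
      sub <- sub[order(sub$time_s), , drop = FALSE]
      if (is.null(mat)) {
        mat <- matrix(NA_real_, length(montage$labels), nrow(sub))
      }
      if (nrow(sub) != ncol(mat)) stop("unequal sample counts across channels")
      mat[match(lab, montage$labels), ] <- sub$value_uV
    }
    if (is.null(fs)) {
      tt <- sort(unique(df$time_s))
      if (length(tt) < 2L) stop("cannot infer fs from a single time point")
      fs <- 1 / stats::median(diff(tt))
    }
    eeg_recording(mat, fs, montage, subject_id, group, condition, kind)
  } else {
    edf <- read_edf(path)
    missing <- setdiff(montage$labels, edf$labels)
    if (length(missing)) {
      stop("recording lacks montage channel(s): ",
           paste(missing, collapse = ", "))
    }
    scale <- vapply(edf$units, function(u) {
      switch(tolower(trimws(u)), "uv" = 1, "µv" = 1, "mv" = 1000,
             stop("cannot resolve physical dimension '", u,
                  "' to microvolts"))
    }, numeric(1))
    mat <- edf$samples * scale
    mat <- mat[match(montage$labels, edf$labels), , drop = FALSE]
    eeg_recording(mat, edf$fs, montage, subject_id, group, condition, kind)
  }
}
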