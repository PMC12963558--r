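#' Estimate the individual alpha frequency from a rest segment
#'
#' Welch periodogram (2-s Hanning windows, 50% overlap) averaged over the
#' parietal channels; the IAF is the frequency of the largest local maximum
#' of the (lightly smoothed) spectrum inside the search range. A candidate
#' peak must also exceed 1.25x the median in-range spectral density — a
#' prominence criterion that keeps sampling fluctuations of a peakless
#' (e.g. white-noise) spectrum from being reported as an alpha peak. When no
#' peak qualifies, the conventional 10 Hz is returned with a warning.
#'
#' @param rest an [eeg_recording()] of at least 30 s.
#' @param search_range frequency window for the peak search, Hz.
#' @param subset montage role to average over (default `"parietal"`).
#' @param window_sec Welch window length (2 s gives 0.5 Hz resolution).
#' @return the IAF estimate in Hz.
#' @export
estimate_iaf <- function(rest, search_range = c(7, 13), subset = "parietal",
                         window_sec = 2) {
  idx <- montage_idx(rest$montage, subset)
  if (!length(idx)) stop("channel subset '", subset, "' is empty")
  if (rec_duration(rest) < 30) stop("rest segment must be at least 30 s")
  psd <- NULL
  for (ch in idx) {
    p <- welch_psd(rest$samples[ch, ], rest$fs, window_sec)
    psd <- if (is.null(psd)) p$psd else psd + p$psd
  }
  psd <- psd / length(idx)
  freq <- p$freq
  sm <- stats::filter(psd, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- psd[is.na(sm)]
  in_range <- which(freq >= search_range[1] & freq <= search_range[2])
  med <- stats::median(sm[in_range])
  is_peak <- vapply(in_range, function(i) {
    i > 1 && i < length(sm) && sm[i] > sm[i - 1] && sm[i] >= sm[i + 1] &&
      sm[i] >= 1.25 * med
  }, logical(1))
  if (!any(is_peak)) {
    warning("no alpha peak found in the rest spectrum; using fallback 10 Hz")
    return(10)
  }
  cand <- in_range[is_peak]
  freq[cand[which.max(sm[cand])]]
}

#' IAF-anchored band scheme
#'
#' Theta spans `[iaf - 6, iaf - 2]` Hz and alpha `[iaf - 2, iaf + 2]` Hz, so
#' the two bands tile `[iaf - 6, iaf + 2]` with a shared edge; for any IAF in
#' 7-13 Hz both bands lie inside the 2-30 Hz filtered range.
#'
#' @param iaf individual alpha frequency, Hz (must lie in 7-13).
#' @return object of class `band_scheme` with `iaf`, `theta`, `alpha`.
#' @export
band_edges <- function(iaf) {
  if (!is.finite(iaf) || iaf < 7 || iaf > 13) {
    stop("iaf must lie in [7, 13] Hz")
  }
  structure(list(iaf = iaf, theta = c(iaf - 6, iaf - 2),
                 alpha = c(iaf - 2, iaf + 2)),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("IAF %.2f Hz: theta [%.2f, %.2f] Hz, alpha [%.2f, %.2f] Hz\n",
              x$iaf, x$theta[1], x$theta[2], x$alpha[1], x$alpha[2]))
  invisible(x)
}

#' Per-epoch GFP band power over a channel subset
#'
#' For every clean epoch, the per-channel band power is the integral of the
#' single-Hanning-periodogram spectral density over the band; the global
#' field power (GFP) summary for the epoch is, by default, the mean of the
#' per-channel band powers over the subset. The classical spatial-variance
#' GFP (per-sample across-channel variance of the band-passed signal,
#' averaged over the epoch) is available via `mode = "spatial-variance"` for
#' sensitivity analysis; it degenerates to zero on spatially uniform signals,
#' which is why the subset mean is the default for 2-3 channel pools.
#'
#' @param epochs an `eeg_epochs` object.
#' @param band numeric `c(low, high)` in Hz.
#' @param subset montage role name (`"frontal"`, `"parietal"`,
#'   `"frontal_right"`, `"frontal_left"`) or a character vector of labels.
#' @param mode `"subset-mean"` or `"spatial-variance"`.
#' @param pg optional precomputed periodogram set (internal cache used by
#'   [aggregate_study()] so WL and AW share one spectral decomposition).
#' @return numeric vector of per-epoch power (uV^2) for clean epochs
#'   (rejected epochs are dropped), with attribute `epoch_index`.
#' @export
band_gfp <- function(epochs, band, subset,
                     mode = c("subset-mean", "spatial-variance"),
                     pg = NULL) {
  mode <- match.arg(mode)
  idx <- if (length(subset) == 1L && subset %in%
               c("frontal", "parietal", "frontal_right", "frontal_left")) {
    montage_idx(epochs$montage, subset)
  } else {
    match(subset, epochs$montage$labels)
  }
  if (!length(idx) || anyNA(idx)) stop("empty or unknown channel subset")
  clean <- which(!epochs$artifact_mask)
  if (!length(clean)) stop("no clean epochs")
  if (mode == "subset-mean") {
    if (is.null(pg)) pg <- epoch_periodograms(epochs)
    df <- pg$freq[2] - pg$freq[1]
    sel <- pg$freq >= band[1] & pg$freq <= band[2]
    sub <- pg$pxx[clean, idx, sel, drop = FALSE]
    per_ch <- matrix(rowSums(matrix(sub, nrow = length(clean) * length(idx))),
                     length(clean), length(idx)) * df
    out <- rowMeans(per_ch)
  } else {
    bf <- signal::butter(4, band / (epochs$fs / 2), type = "pass")
    out <- vapply(clean, function(e) {
      seg <- epochs$epochs[e, idx, , drop = TRUE]
      if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
      filt <- t(apply(seg, 1L, function(x) signal::filtfilt(bf, x)))
      mean(apply(filt, 2L, function(col) mean((col - mean(col))^2)))
    }, numeric(1))
  }
  attr(out, "epoch_index") <- clean
  out
}

#' Workload index
#'
#' `WL = mean clean-epoch theta GFP power over the frontal pool /
#' mean clean-epoch alpha GFP power over the parietal pool` — the classic
#' frontal-theta over parietal-alpha ratio; dimensionless, higher under
#' higher cognitive load, and invariant to a global channel gain.
#' The ratio of epoch-mean powers (rather than the mean of per-epoch ratios)
#' is used by default for stability with 1-s epochs; set
#' `per_epoch_ratio = TRUE` for the alternative.
#'
#' @param epochs an `eeg_epochs` object (task recording, preprocessed).
#' @param scheme a [band_edges()] scheme.
#' @param montage optional override of the epochs' montage roles.
#' @param gfp_mode passed to [band_gfp()].
#' @param per_epoch_ratio average per-epoch theta/alpha ratios instead.
#' @return list with `wl` and `n_clean_epochs`.
#' @export
workload_index <- function(epochs, scheme, montage = epochs$montage,
                           gfp_mode = "subset-mean",
                           per_epoch_ratio = FALSE, pg = NULL) {
  epochs$montage <- montage
  th <- band_gfp(epochs, scheme$theta, "frontal", mode = gfp_mode, pg = pg)
  al <- band_gfp(epochs, scheme$alpha, "parietal", mode = gfp_mode, pg = pg)
  if (per_epoch_ratio) {
    if (any(al == 0)) stop("zero parietal alpha power in an epoch")
    wl <- mean(th / al)
  } else {
    if (mean(al) == 0) stop("zero parietal alpha power; WL undefined")
    wl <- mean(th) / mean(al)
  }
  list(wl = wl, n_clean_epochs = length(th))
}

#' Approach-withdrawal (acceptance) index
#'
#' `AW = mean clean-epoch alpha GFP power over the right frontal pool -
#' the same over the left frontal pool`, in uV^2. Positive values (more
#' right-hemisphere alpha, hence relatively less right-hemisphere activity)
#' are read as approach/acceptance. Exactly antisymmetric under swapping the
#' left and right pools. A log-power variant
#' (`scale = "log"`: difference of log mean powers) common in the asymmetry
#' literature is available but not the default.
#'
#' @inheritParams workload_index
#' @param scale `"power"` (raw uV^2 difference) or `"log"`.
#' @return list with `aw` and `n_clean_epochs`.
#' @export
approach_withdrawal_index <- function(epochs, scheme,
                                      montage = epochs$montage,
                                      gfp_mode = "subset-mean",
                                      scale = c("power", "log"),
                                      pg = NULL) {
  scale <- match.arg(scale)
  epochs$montage <- montage
  if (!length(montage$frontal_right) || !length(montage$frontal_left)) {
    stop("montage must define non-empty frontal_right and frontal_left")
  }
  r <- band_gfp(epochs, scheme$alpha, "frontal_right", mode = gfp_mode,
                pg = pg)
  l <- band_gfp(epochs, scheme$alpha, "frontal_left", mode = gfp_mode,
                pg = pg)
  aw <- if (scale == "power") mean(r) - mean(l) else
    log(mean(r)) - log(mean(l))
  list(aw = aw, n_clean_epochs = length(r))
}

#' Compute neurometrics for a whole study
#'
#' Runs the preprocessing chain and both neurometrics for every subject and
#' condition: the IAF is estimated from the subject's filtered rest segment,
#' the IAF-anchored bands are formed, and WL and AW are computed from the
#' clean task epochs. Records with zero clean epochs are excluded with a
#' warning.
#'
#' @param study an `eeg_study` from [generate_study()], or a compatible list
#'   with `profiles`, `recordings` (named `subject.condition`) and `rest`.
#' @param low,high,order,blink_mode,threshold preprocessing parameters, see
#'   [preprocess_recording()].
#' @param gfp_mode,aw_scale metric options, see [band_gfp()] and
#'   [approach_withdrawal_index()].
#' @return data.frame (one row per subject x condition): `subject_id`,
#'   `group`, `condition`, `wl`, `aw`, `n_clean_epochs`, `iaf_hz`.
#' @export
aggregate_study <- function(study, low = 2, high = 30, order = 5,
                            blink_mode = "correct", threshold = 80,
                            gfp_mode = "subset-mean", aw_scale = "power") {
  rows <- list()
  for (i in seq_len(nrow(study$profiles))) {
    p <- study$profiles[i, ]
    rest <- bandpass_filter(study$rest[[p$subject_id]], low, high, order)
    iaf <- estimate_iaf(rest)
    scheme <- band_edges(iaf)
    for (cond in study_conditions) {
      rec <- study$recordings[[paste(p$subject_id, cond, sep = ".")]]
      if (is.null(rec)) stop("missing recording for ", p$subject_id,
                             " condition ", cond)
      ep <- preprocess_recording(rec, low, high, order, blink_mode,
                                 threshold = threshold)
      if (all(ep$artifact_mask)) {
        warning("no clean epochs for ", p$subject_id, "/", cond,
                "; record excluded")
        next
      }
      pg <- if (gfp_mode == "subset-mean") epoch_periodograms(ep)
      wl <- workload_index(ep, scheme, gfp_mode = gfp_mode, pg = pg)
      aw <- approach_withdrawal_index(ep, scheme, gfp_mode = gfp_mode,
                                      scale = aw_scale, pg = pg)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = p$subject_id, group = p$group, condition = cond,
        wl = wl$wl, aw = aw$aw, n_clean_epochs = wl$n_clean_epochs,
        iaf_hz = iaf, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
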