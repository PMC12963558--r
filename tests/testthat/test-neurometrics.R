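test_that("IAF estimation finds tones, recovers synthetic peaks, falls back", {
  # pure 9 Hz parietal sinusoid -> exactly the 9.0 Hz bin
  rec <- tone_recording(c(NA, NA, NA, NA, NA, 9, 9, 9), duration = 40)
  expect_equal(estimate_iaf(rec), 9.0)
  # white noise: no qualifying peak -> fallback 10 Hz with a warning
  set.seed(1)
  wn <- eeg_recording(matrix(rnorm(8 * 40 * 128, sd = 5), 8), 128)
  expect_warning(est <- estimate_iaf(wn), "fallback")
  expect_equal(est, 10)
  # synthetic rest with known IAF
  p <- make_profiles(2, 0, seed = 31)
  p$true_iaf[1] <- 10.6
  rest <- synthesize_rest(p[1, ], 60, 128, seed = 3)
  est <- estimate_iaf(bandpass_filter(rest))
  expect_true(est >= 10.1 && est <= 11.1)
  m0 <- channel_montage(parietal = character(0))
  expect_error(estimate_iaf(eeg_recording(matrix(0, 8, 40 * 128), 128, m0)),
               "empty")
})

test_that("band scheme anchors theta and alpha to the IAF", {
  s <- band_edges(10)
  expect_equal(s$theta, c(4, 8))
  expect_equal(s$alpha, c(8, 12))
  s8 <- band_edges(8)
  expect_equal(s8$theta, c(2, 6))
  expect_equal(s8$alpha, c(6, 10))
  for (iaf in seq(7, 13, by = 0.5)) {
    sc <- band_edges(iaf)
    expect_equal(sc$theta[2], sc$alpha[1])   # adjacency, no gap or overlap
    expect_gte(sc$theta[1], 1)
    expect_lte(sc$alpha[2], 15)
  }
  expect_error(band_edges(6.5), "7")
  expect_error(band_edges(NaN), "7")
})

test_that("band power matches theory on tones and scales quadratically", {
  # unit-amplitude tone at band centre: mean-square 0.5 uV^2
  rec <- tone_recording(c(NA, NA, NA, NA, NA, 10, NA, NA), duration = 10)
  ep <- segment_epochs(rec)
  pw <- band_gfp(ep, c(8, 12), "Pz")
  expect_equal(mean(pw), 0.5, tolerance = 0.01)
  # scaling by c multiplies epoch powers by c^2
  rec2 <- rec; rec2$samples <- 3 * rec2$samples
  pw2 <- band_gfp(segment_epochs(rec2), c(8, 12), "Pz")
  expect_equal(as.numeric(pw2), as.numeric(9 * pw), tolerance = 1e-10)
  expect_error(band_gfp(ep, c(8, 12), character(0)), "subset")
})

test_that("band power agrees with the independent periodogram oracle", {
  set.seed(42)
  p <- quiet_profile()
  rec <- synthesize_recording(p, "BB", effect_spec(), duration = 60,
                              fs = 128, seed = 17)
  ep <- segment_epochs(bandpass_filter(rec))
  scheme <- band_edges(p$true_iaf)
  for (band in list(scheme$theta, scheme$alpha)) {
    got <- band_gfp(ep, band, "frontal")
    picks <- sample(length(got), 50)
    idx <- attr(got, "epoch_index")
    chans <- montage_idx(ep$montage, "frontal")
    for (e in picks) {
      want <- mean(vapply(chans, function(ch)
        oracle_band_power(ep$epochs[idx[e], ch, ], 128, band), 0))
      expect_equal(got[e], want, tolerance = 0.01)
    }
  }
})

test_that("workload index behaves as a calibrated ratio", {
  fs <- 128
  t <- (0:(fs * 20 - 1)) / fs
  m <- matrix(0, 8, length(t))
  for (ch in 1:5) m[ch, ] <- 2 * sin(2 * pi * 6 * t)   # frontal theta
  for (ch in 6:8) m[ch, ] <- 2 * sin(2 * pi * 10 * t)  # parietal alpha
  ep <- segment_epochs(eeg_recording(m, fs))
  scheme <- band_edges(10)
  expect_equal(workload_index(ep, scheme)$wl, 1, tolerance = 1e-4)
  # doubling the frontal theta amplitude multiplies WL by 4 (power ~ amp^2)
  m2 <- m; m2[1:5, ] <- 2 * m2[1:5, ]
  ep2 <- segment_epochs(eeg_recording(m2, fs))
  expect_equal(workload_index(ep2, scheme)$wl, 4, tolerance = 0.05 * 4)
  # global gain leaves WL unchanged
  m3 <- 17 * m
  ep3 <- segment_epochs(eeg_recording(m3, fs))
  expect_equal(workload_index(ep3, scheme)$wl, workload_index(ep, scheme)$wl,
               tolerance = 1e-10)
  expect_error(workload_index(segment_epochs(eeg_recording(matrix(0, 8, 1280),
                                                           fs)), scheme),
               "undefined")
})

test_that("WL scale invariance holds on random recordings (property)", {
  set.seed(99)
  scheme <- band_edges(10)
  for (k in 1:10) {
    m <- matrix(rnorm(8 * 1280, sd = 10), 8)
    ep <- segment_epochs(eeg_recording(m, 128))
    c_gain <- runif(1, 0.1, 10)
    epc <- segment_epochs(eeg_recording(c_gain * m, 128))
    expect_equal(workload_index(epc, scheme)$wl,
                 workload_index(ep, scheme)$wl, tolerance = 1e-10)
  }
})

test_that("AW is symmetric for mirrored signals and antisymmetric under swap", {
  fs <- 128
  t <- (0:(fs * 20 - 1)) / fs
  m <- matrix(0, 8, length(t))
  m[2, ] <- m[3, ] <- 3 * sin(2 * pi * 10 * t)  # AF3 == AF4
  m[4, ] <- m[5, ] <- 2 * sin(2 * pi * 10 * t)  # AF7 == AF8
  ep <- segment_epochs(eeg_recording(m, fs))
  scheme <- band_edges(10)
  expect_equal(approach_withdrawal_index(ep, scheme)$aw, 0, tolerance = 1e-9)
  # antisymmetry on arbitrary signals
  set.seed(12)
  m2 <- matrix(rnorm(8 * 1280, sd = 8), 8)
  ep2 <- segment_epochs(eeg_recording(m2, fs))
  swapped <- channel_montage(frontal_right = c("AF3", "AF7"),
                             frontal_left = c("AF4", "AF8"))
  aw <- approach_withdrawal_index(ep2, scheme)$aw
  aw_sw <- approach_withdrawal_index(ep2, scheme, montage = swapped)$aw
  expect_equal(aw_sw, -aw, tolerance = 1e-12)
  bad <- channel_montage(frontal_right = character(0))
  expect_error(approach_withdrawal_index(ep2, scheme, montage = bad),
               "non-empty")
})

test_that("programmed right-alpha shift yields positive AW across subjects", {
  p <- make_profiles(0, 50, seed = 51)
  eff <- effect_spec()   # students get +0.5 uV right frontal alpha under HM
  aw <- vapply(seq_len(nrow(p)), function(i) {
    rec <- synthesize_recording(p[i, ], "HM", eff, duration = 300, fs = 128,
                                seed = 600 + i)
    ep <- preprocess_recording(rec)
    approach_withdrawal_index(ep, band_edges(p$true_iaf[i]))$aw
  }, 0)
  expect_gte(mean(aw > 0), 0.9)
})

test_that("aggregate_study produces one record per subject and condition", {
  st <- small_study(seed = 23)
  recs <- suppressWarnings(aggregate_study(st))
  expect_equal(nrow(recs), 2 * nrow(st$profiles))
  expect_true(all(recs$wl > 0))
  expect_true(all(recs$n_clean_epochs >= 1))
  expect_true(all(abs(recs$iaf_hz - st$profiles$true_iaf[
    match(recs$subject_id, st$profiles$subject_id)]) < 1.5))
  # epoch-order permutation cannot change the records
  ep <- preprocess_recording(st$recordings[["S01.BB"]])
  perm <- sample(dim(ep$epochs)[1])
  ep_p <- ep
  ep_p$epochs <- ep$epochs[perm, , , drop = FALSE]
  ep_p$artifact_mask <- ep$artifact_mask[perm]
  scheme <- band_edges(10)
  expect_equal(workload_index(ep_p, scheme)$wl,
               workload_index(ep, scheme)$wl, tolerance = 1e-12)
})
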