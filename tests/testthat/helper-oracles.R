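# Independent oracles and shared fixtures for the test suite.

# Brute-force Type III oracle for the 2x2 mixed design, via lm projections
# on difference and mean scores with sum-to-zero contrasts (car::Anova for
# the within stratum). Deliberately a different route than the package's
# closed-form unweighted-means computation.
oracle_mixed_anova <- function(d) {
  w <- stats::reshape(d[, c("subject_id", "group", "condition", "value")],
                      idvar = c("subject_id", "group"),
                      timevar = "condition", direction = "wide")
  cl <- sort(unique(d$condition))
  dif <- w[[paste0("value.", cl[1])]] - w[[paste0("value.", cl[2])]]
  s <- (w[[paste0("value.", cl[1])]] + w[[paste0("value.", cl[2])]]) / 2
  g <- factor(w$group)
  stats::contrasts(g) <- stats::contr.sum(2)
  aw <- car::Anova(stats::lm(dif ~ g), type = 3)
  ab <- stats::anova(stats::lm(s ~ g))
  ss <- c(aw["(Intercept)", "Sum Sq"] / 2, aw["g", "Sum Sq"] / 2,
          aw["Residuals", "Sum Sq"] / 2,
          2 * ab["g", "Sum Sq"], 2 * ab["Residuals", "Sum Sq"])
  df <- c(1, 1, nrow(w) - 2, 1, nrow(w) - 2)
  ms <- ss / df
  f <- c(ms[1] / ms[3], ms[2] / ms[3], NA, ms[4] / ms[5], NA)
  p <- ifelse(is.na(f), NA, stats::pf(f, 1, nrow(w) - 2, lower.tail = FALSE))
  list(ss = ss, df = df, F = f, p = p)
}

# Random balanced-or-unbalanced long dataset for the mixed design.
random_mixed_data <- function(n1, n2, sd = 1, cond_eff = 0, group_eff = 0) {
  n <- n1 + n2
  d <- expand.grid(subject_id = sprintf("s%02d", seq_len(n)),
                   condition = c("A", "B"), stringsAsFactors = FALSE)
  d$group <- rep(rep(c("g1", "g2"), c(n1, n2)), 2)
  subj_int <- stats::rnorm(n)
  d$value <- subj_int[match(d$subject_id, unique(d$subject_id))] +
    stats::rnorm(nrow(d), sd = sd) +
    cond_eff * (d$condition == "B") + group_eff * (d$group == "g2")
  d
}

# Independent band-power oracle: plain Hanning periodogram of one channel
# of one epoch, rectangle-rule band integral. Written directly against the
# DFT definition, no shared code with the package internals.
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  X <- stats::fft(w * x)
  pxx <- Mod(X)^2 / (fs * sum(w^2))
  half <- floor(n / 2) + 1L
  pxx <- pxx[seq_len(half)]
  pxx[2:(half - 1L)] <- 2 * pxx[2:(half - 1L)]
  freq <- fs * (seq_len(half) - 1L) / n
  sum(pxx[freq >= band[1] & freq <= band[2]]) * fs / n
}

# A quiet subject profile: low background and oscillation amplitudes so
# artifact-injection tests have crisp signal-to-background contrast.
quiet_profile <- function() {
  p <- make_profiles(1, 0, seed = 2)
  p$noise_rms <- 4
  p$base_theta_amp <- 3
  p$base_alpha_amp <- 5
  p
}

# Small in-memory study for pipeline tests.
small_study <- function(seed = 7, n_expert = 4, n_student = 3,
                        task_duration = 16, rest_duration = 30, fs = 128) {
  generate_study(study_config(n_expert = n_expert, n_student = n_student,
                              fs = fs, task_duration = task_duration,
                              rest_duration = rest_duration, seed = seed))
}

# Sinusoid recording builder (channels x samples).
tone_recording <- function(freqs_by_channel, amp = 1, fs = 128,
                           duration = 10, montage = channel_montage()) {
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  m <- matrix(0, length(montage$labels), n)
  for (ch in seq_along(freqs_by_channel)) {
    f <- freqs_by_channel[ch]
    if (!is.na(f) && f > 0) m[ch, ] <- amp * sin(2 * pi * f * t)
  }
  eeg_recording(m, fs, montage)
}
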