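#' Synthetic study generator
#'
#' Generates a complete synthetic two-condition study — task EEG, eyes-closed
#' rest EEG, and Likert questionnaires — with the statistical structure the
#' analysis pipeline assumes: a 1/f (pink) background, a subject-specific
#' alpha peak recoverable from rest, condition-dependent frontal-theta and
#' parietal-alpha power (workload), a programmable right-minus-left frontal
#' alpha imbalance (acceptance), frontal blink transients, rare high-amplitude
#' spikes, and Likert items loading on shared latent constructs.
#'
#' @name synthetic_study
NULL

study_conditions <- c("BB", "HM")

#' Draw subject profiles
#'
#' Each profile carries the subject-level ground-truth parameters of the
#' generator: the true individual alpha frequency (IAF, truncated normal with
#' mean 10 Hz, sd 1, bounds 8-12 Hz), oscillation amplitudes, a signed
#' right-minus-left frontal alpha amplitude offset, blink rate and background
#' noise level.
#'
#' @param n_expert,n_student group sizes (default 11 experts, 10 students).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param iaf_mean,iaf_sd,iaf_bounds truncated-normal parameters of the IAF.
#' @return data.frame with one row per subject, class `subject_profiles`.
#' @export
make_profiles <- function(n_expert = 11, n_student = 10, seed = 1,
                          iaf_mean = 10, iaf_sd = 1, iaf_bounds = c(8, 12)) {
  if (n_expert < 0 || n_student < 0) stop("group sizes must be non-negative")
  n <- n_expert + n_student
  with_seed(seed, {
    df <- data.frame(
      subject_id = sprintf("S%02d", seq_len(max(n, 1L))[seq_len(n)]),
      group = rep(c("expert", "student"), c(n_expert, n_student)),
      true_iaf = rtrunc_norm(n, iaf_mean, iaf_sd, iaf_bounds),
      base_theta_amp = rtrunc_norm(n, 6, 1, c(3, 9)),
      base_alpha_amp = rtrunc_norm(n, 8, 1.5, c(4, 12)),
      asymmetry_offset = stats::rnorm(n, 0, 0.15),
      blink_rate = rtrunc_norm(n, 15, 4, c(5, 30)),
      noise_rms = rtrunc_norm(n, 8, 1.5, c(4, 12)),
      stringsAsFactors = FALSE
    )
    if (n == 0L) df <- df[0L, ]
    class(df) <- c("subject_profiles", "data.frame")
    df
  })
}

rtrunc_norm <- function(n, mean, sd, bounds) {
  if (n == 0L) return(numeric(0))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < bounds[1] | out > bounds[2])
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < bounds[1] | out > bounds[2])
  }
  out
}

#' Condition effect specification
#'
#' Encodes the programmed between-condition effects of the generator. The
#' defaults encode the direction the analysis is designed to detect: under
#' the unexplained condition (`BB`) frontal theta is stronger (gain 1.3) and
#' parietal alpha weaker (gain 0.8), i.e. higher workload; under the
#' explained condition (`HM`) students receive a +0.5 uV right-frontal alpha
#' amplitude shift, i.e. higher acceptance; and the questionnaire latents
#' shift towards higher willingness under `HM` and higher perceived work
#' performance for students.
#'
#' @param theta_gain,alpha_gain named numeric vectors over conditions,
#'   multiplicative factors on the frontal-theta / parietal-alpha amplitudes;
#'   must be positive.
#' @param asym_shift per-group named list of per-condition additive
#'   right-minus-left frontal alpha amplitude shifts (uV).
#' @param likert_shift data.frame (construct, group, condition, shift) of
#'   latent-scale shifts; missing cells shift by 0.
#' @param item_loading named per-item loading in (0, 1]; items not named get
#'   `default_loading`.
#' @param default_loading,item_noise_sd,subject_sd,latent_base Likert latent
#'   model parameters (latent-scale units; responses live on 1-5).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(theta_gain = c(BB = 1.3, HM = 1.0),
                        alpha_gain = c(BB = 0.8, HM = 1.0),
                        asym_shift = list(expert = c(BB = 0, HM = 0),
                                          student = c(BB = 0, HM = 0.5)),
                        likert_shift = default_likert_shift(),
                        item_loading = NULL,
                        default_loading = 0.9,
                        item_noise_sd = 0.35,
                        subject_sd = 0.5,
                        latent_base = 3) {
  if (any(theta_gain <= 0) || any(alpha_gain <= 0)) {
    stop("condition gains must be positive")
  }
  if (!is.null(item_loading) &&
      (any(item_loading <= 0) || any(item_loading > 1))) {
    stop("item loadings must lie in (0, 1]")
  }
  if (default_loading <= 0 || default_loading > 1) {
    stop("item loadings must lie in (0, 1]")
  }
  structure(list(theta_gain = theta_gain, alpha_gain = alpha_gain,
                 asym_shift = asym_shift, likert_shift = likert_shift,
                 item_loading = item_loading,
                 default_loading = default_loading,
                 item_noise_sd = item_noise_sd, subject_sd = subject_sd,
                 latent_base = latent_base),
            class = "effect_spec")
}

#' Null effects: no condition or group differences anywhere
#' @return an [effect_spec()] with all gains 1 and all shifts 0.
#' @export
null_effects <- function() {
  effect_spec(theta_gain = c(BB = 1, HM = 1), alpha_gain = c(BB = 1, HM = 1),
              asym_shift = list(expert = c(BB = 0, HM = 0),
                                student = c(BB = 0, HM = 0)),
              likert_shift = data.frame(construct = character(),
                                        group = character(),
                                        condition = character(),
                                        shift = numeric()))
}

default_likert_shift <- function() {
  rbind(
    expand.grid(construct = "willingness_to_use",
                group = c("expert", "student"),
                condition = "HM", shift = 0.5,
                stringsAsFactors = FALSE),
    data.frame(construct = "willingness_to_use", group = "student",
               condition = c("BB", "HM"), shift = 0.4),
    data.frame(construct = "work_performance", group = "student",
               condition = c("BB", "HM"), shift = 0.6)
  )
}

lookup_shift <- function(spec, construct, group, condition) {
  ls <- spec$likert_shift
  if (is.null(ls) || !nrow(ls)) return(0)
  hit <- ls$construct == construct & ls$group == group &
    ls$condition == condition
  sum(ls$shift[hit])
}

asym_for <- function(spec, group, condition) {
  a <- spec$asym_shift
  if (is.null(a)) return(0)
  g <- a[[group]]
  if (is.null(g)) return(0)
  v <- g[[condition]]
  if (is.null(v) || is.na(v)) 0 else v
}

# ---- signal building blocks -------------------------------------------------

# Band-limited 1/f ("pink") background: white Gaussian spectrum shaped by an
# f^(-1/2) amplitude profile between f_lo and f_hi, scaled to the target RMS.
pink_noise <- function(n, fs, rms, f_lo = 1, f_hi = 45) {
  if (rms <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- fs * (seq_len(n) - 1) / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  shape <- ifelse(f >= f_lo & f <= f_hi, 1 / sqrt(pmax(f, f_lo)), 0)
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) return(numeric(n))
  y * (rms / s)
}

# Amplitude-modulated oscillation: back-to-back Hanning-windowed bursts of
# random duration (1-2 s) and phase, avoiding a degenerate line spectrum.
osc_track <- function(n, fs, freq, amp) {
  if (amp <= 0 || freq <= 0) return(numeric(n))
  out <- numeric(n)
  pos <- 1L
  while (pos <= n) {
    dur <- round(stats::runif(1, 1, 2) * fs)
    idx <- pos:min(pos + dur - 1L, n)
    k <- seq_along(idx)
    env <- if (length(idx) > 1L) {
      0.5 * (1 - cos(2 * pi * (k - 1) / (length(idx) - 1)))
    } else 0
    phase <- stats::runif(1, 0, 2 * pi)
    out[idx] <- amp * env * sin(2 * pi * freq * (idx - 1) / fs + phase)
    pos <- pos + dur
  }
  out
}

# Biphasic blink transient: 250 ms positive half-sine followed by a 150 ms
# negative lobe at 40% amplitude; frontally dominant, absent at parietal sites.
blink_template <- function(fs, amp = 120) {
  n1 <- round(0.25 * fs)
  n2 <- round(0.15 * fs)
  c(amp * sin(pi * seq_len(n1) / n1),
    -0.4 * amp * sin(pi * seq_len(n2) / n2))
}

blink_channel_weights <- function(montage) {
  w <- stats::setNames(rep(0, length(montage$labels)), montage$labels)
  w[intersect("AFz", montage$labels)] <- 1
  w[intersect(c("AF3", "AF4"), montage$labels)] <- 0.8
  w[intersect(c("AF7", "AF8"), montage$labels)] <- 0.6
  w
}

#' Synthesize one task recording
#'
#' @param profile one-row slice of [make_profiles()].
#' @param condition `"BB"` or `"HM"`.
#' @param effects an [effect_spec()].
#' @param duration seconds (>= 10); `fs` Hz (>= 128).
#' @param seed integer seed; output is deterministic given the seed.
#' @param blink_rate override of the profile blink rate (events/minute).
#' @param spike_rate rate of rectangular >100 uV artifact spikes
#'   (events/minute) on random channels.
#' @param montage target [channel_montage()].
#' @return an [eeg_recording()] with attribute `injected`, a list logging the
#'   ground-truth blink onset times and spike sample windows.
#' @export
synthesize_recording <- function(profile, condition, effects = effect_spec(),
                                 duration = 300, fs = 256, seed = 1,
                                 blink_rate = NULL, spike_rate = 0.5,
                                 montage = channel_montage()) {
  if (!condition %in% study_conditions) {
    stop("unknown condition: ", condition)
  }
  if (duration < 10) stop("duration must be at least 10 s")
  if (fs < 128) stop("fs must be at least 128 Hz")
  th_amp <- profile$base_theta_amp * effects$theta_gain[[condition]]
  al_amp <- profile$base_alpha_amp * effects$alpha_gain[[condition]]
  fr_alpha_left <- 0.6 * profile$base_alpha_amp
  fr_alpha_right <- max(0, fr_alpha_left + profile$asymmetry_offset +
                          asym_for(effects, profile$group, condition))
  build_recording(profile, montage, duration, fs, seed,
                  theta_amp = th_amp, parietal_alpha_amp = al_amp,
                  frontal_alpha = c(left = fr_alpha_left,
                                    right = fr_alpha_right),
                  blink_rate = if (is.null(blink_rate)) profile$blink_rate
                               else blink_rate,
                  spike_rate = spike_rate,
                  condition = condition, kind = "task")
}

#' Synthesize an eyes-closed rest segment
#'
#' Like [synthesize_recording()] but with no task modulation and the parietal
#' alpha amplitude boosted (x2 by default), giving the rest spectrum a clear
#' peak at the subject's true IAF for IAF estimation.
#'
#' @inheritParams synthesize_recording
#' @param duration seconds (>= 30).
#' @param alpha_boost multiplier on the parietal alpha amplitude.
#' @export
synthesize_rest <- function(profile, duration = 60, fs = 256, seed = 1,
                            alpha_boost = 2, blink_rate = NULL,
                            spike_rate = 0.2, montage = channel_montage()) {
  if (duration < 30) stop("rest duration must be at least 30 s")
  if (fs < 128) stop("fs must be at least 128 Hz")
  fr_alpha_left <- 0.6 * profile$base_alpha_amp
  fr_alpha_right <- max(0, fr_alpha_left + profile$asymmetry_offset)
  build_recording(profile, montage, duration, fs, seed,
                  theta_amp = profile$base_theta_amp,
                  parietal_alpha_amp = profile$base_alpha_amp * alpha_boost,
                  frontal_alpha = c(left = fr_alpha_left,
                                    right = fr_alpha_right),
                  blink_rate = if (is.null(blink_rate))
                    0.2 * profile$blink_rate else blink_rate,
                  spike_rate = spike_rate,
                  condition = NA_character_, kind = "rest")
}

build_recording <- function(profile, montage, duration, fs, seed,
                            theta_amp, parietal_alpha_amp, frontal_alpha,
                            blink_rate, spike_rate, condition, kind) {
  n <- round(duration * fs)
  labels <- montage$labels
  theta_f <- profile$true_iaf - 4
  with_seed(seed, {
    mat <- matrix(0, length(labels), n, dimnames = list(labels, NULL))
    for (ch in seq_along(labels)) {
      mat[ch, ] <- pink_noise(n, fs, profile$noise_rms)
    }
    for (lab in montage$frontal) {
      mat[lab, ] <- mat[lab, ] + osc_track(n, fs, theta_f, theta_amp)
    }
    for (lab in montage$parietal) {
      mat[lab, ] <- mat[lab, ] +
        osc_track(n, fs, profile$true_iaf, parietal_alpha_amp)
    }
    for (lab in montage$frontal_left) {
      mat[lab, ] <- mat[lab, ] +
        osc_track(n, fs, profile$true_iaf, frontal_alpha[["left"]])
    }
    for (lab in montage$frontal_right) {
      mat[lab, ] <- mat[lab, ] +
        osc_track(n, fs, profile$true_iaf, frontal_alpha[["right"]])
    }
    mid <- setdiff(montage$frontal,
                   c(montage$frontal_left, montage$frontal_right))
    for (lab in mid) {
      mat[lab, ] <- mat[lab, ] +
        osc_track(n, fs, profile$true_iaf, mean(frontal_alpha))
    }
    # blink transients, Poisson arrivals
    tmpl <- blink_template(fs)
    w <- blink_channel_weights(montage)
    n_blinks <- stats::rpois(1, blink_rate * duration / 60)
    blink_starts <- sort(round(stats::runif(n_blinks, 1,
                                            n - length(tmpl) - 1)))
    for (s in blink_starts) {
      idx <- s:(s + length(tmpl) - 1L)
      mat[, idx] <- mat[, idx] + outer(w, tmpl)
    }
    # rare rectangular high-amplitude spikes
    n_spikes <- stats::rpois(1, spike_rate * duration / 60)
    spike_log <- list()
    if (n_spikes > 0) {
      len <- round(0.05 * fs)
      for (k in seq_len(n_spikes)) {
        s <- round(stats::runif(1, 1, n - len - 1))
        ch <- sample(length(labels), 1)
        amp <- sample(c(-1, 1), 1) * stats::runif(1, 110, 150)
        mat[ch, s:(s + len - 1L)] <- mat[ch, s:(s + len - 1L)] + amp
        spike_log[[k]] <- c(channel = ch, start = s, end = s + len - 1L,
                            amp = amp)
      }
    }
    rec <- eeg_recording(mat, fs, montage,
                         subject_id = profile$subject_id,
                         group = profile$group,
                         condition = condition, kind = kind)
    attr(rec, "injected") <- list(blink_times = blink_starts / fs,
                                  n_blinks = n_blinks, spikes = spike_log)
    rec
  })
}

#' Synthesize a Likert questionnaire
#'
#' For each subject x condition, one latent value per construct is drawn as
#' `latent_base + shift(construct, group, condition) + subject intercept`;
#' each item response is `round(loading * latent + noise)` clipped to 1..5,
#' so items of one construct correlate positively in expectation.
#'
#' @param profiles a [make_profiles()] frame.
#' @param effects an [effect_spec()].
#' @param composites list of [composite_spec()] objects defining the item
#'   battery; every item must belong to exactly one construct.
#' @param seed integer seed.
#' @return a [likert_table()] with attribute `latent` holding the per-row
#'   ground-truth latent values.
#' @export
synthesize_questionnaire <- function(profiles, effects = effect_spec(),
                                     composites = default_composites(),
                                     seed = 1) {
  items <- unlist(lapply(composites, `[[`, "items"))
  if (anyDuplicated(items)) {
    stop("item(s) assigned to more than one construct: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  }
  loading <- function(it) {
    v <- effects$item_loading[[it]]
    if (is.null(v)) effects$default_loading else v
  }
  with_seed(seed, {
    rows <- list()
    lat_rows <- list()
    for (i in seq_len(nrow(profiles))) {
      p <- profiles[i, ]
      intercept <- stats::setNames(
        stats::rnorm(length(composites), 0, effects$subject_sd),
        vapply(composites, `[[`, "", "name"))
      for (cond in study_conditions) {
        for (cs in composites) {
          latent <- effects$latent_base +
            lookup_shift(effects, cs$name, p$group, cond) +
            intercept[[cs$name]]
          lat_rows[[length(lat_rows) + 1L]] <- data.frame(
            subject_id = p$subject_id, group = p$group, condition = cond,
            construct = cs$name, latent = latent)
          for (it in cs$items) {
            resp <- round(loading(it) * latent +
                            stats::rnorm(1, 0, effects$item_noise_sd))
            rows[[length(rows) + 1L]] <- data.frame(
              subject_id = p$subject_id, group = p$group, condition = cond,
              item = it, response = min(5, max(1, resp)))
          }
        }
      }
    }
    tab <- likert_table(do.call(rbind, rows))
    attr(tab, "latent") <- do.call(rbind, lat_rows)
    tab
  })
}

#' Study configuration
#'
#' Bundles the generator parameters for [generate_study()]. Defaults are the
#' reference study conditions: 11 experts and 10 students, two conditions per
#' subject, programmed workload and acceptance effects as in [effect_spec()].
#'
#' @param n_expert,n_student group sizes.
#' @param fs sampling rate (Hz); `task_duration`, `rest_duration` seconds.
#' @param effects an [effect_spec()].
#' @param spike_rate,blink_rate artifact rates (per minute); `blink_rate`
#'   `NULL` uses each profile's own rate.
#' @param rest_alpha_boost parietal alpha multiplier at rest.
#' @param composites item battery, list of [composite_spec()].
#' @param seed single integer; every random draw in the study derives from it.
#' @export
study_config <- function(n_expert = 11, n_student = 10, fs = 256,
                         task_duration = 300, rest_duration = 60,
                         effects = effect_spec(), spike_rate = 0.5,
                         blink_rate = NULL, rest_alpha_boost = 2,
                         composites = default_composites(), seed = 1) {
  as.list(environment())
}

#' Generate a complete synthetic study
#'
#' @param config a [study_config()] list.
#' @return object of class `eeg_study`: `profiles`, `recordings` (named
#'   `subject.condition`), `rest` (named by subject), `questionnaire`,
#'   `ground_truth` and the `config`. Fully reproducible from `config$seed`.
#' @export
generate_study <- function(config = study_config()) {
  if (is.null(config$seed)) stop("config must carry a seed")
  profiles <- make_profiles(config$n_expert, config$n_student,
                            seed = derive_seed(config$seed, "profiles"))
  recordings <- list()
  rest <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    for (cond in study_conditions) {
      recordings[[paste(p$subject_id, cond, sep = ".")]] <-
        synthesize_recording(
          p, cond, config$effects, config$task_duration, config$fs,
          seed = derive_seed(config$seed, paste0("rec/", p$subject_id,
                                                 "/", cond)),
          blink_rate = config$blink_rate, spike_rate = config$spike_rate)
    }
    rest[[p$subject_id]] <- synthesize_rest(
      p, config$rest_duration, config$fs,
      seed = derive_seed(config$seed, paste0("rest/", p$subject_id)),
      alpha_boost = config$rest_alpha_boost,
      blink_rate = if (is.null(config$blink_rate)) NULL
                   else config$blink_rate)
  }
  questionnaire <- synthesize_questionnaire(
    profiles, config$effects, config$composites,
    seed = derive_seed(config$seed, "likert"))
  eff <- config$effects
  gt <- data.frame(
    subject_id = profiles$subject_id,
    group = profiles$group,
    wl_bb_gt_hm = eff$theta_gain[["BB"]] > eff$theta_gain[["HM"]] &&
      eff$alpha_gain[["BB"]] < eff$alpha_gain[["HM"]],
    aw_sign_BB = sign(profiles$asymmetry_offset +
                        vapply(profiles$group, asym_for, 0,
                               spec = eff, condition = "BB")),
    aw_sign_HM = sign(profiles$asymmetry_offset +
                        vapply(profiles$group, asym_for, 0,
                               spec = eff, condition = "HM"))
  )
  structure(list(profiles = profiles, recordings = recordings, rest = rest,
                 questionnaire = questionnaire, ground_truth = gt,
                 config = config),
            class = "eeg_study")
}

#' @export
print.eeg_study <- function(x, ...) {
  cat(sprintf(paste0("Synthetic study: %d subjects (%d expert, %d student), ",
                     "%d task recordings, %d rest segments\n"),
              nrow(x$profiles), sum(x$profiles$group == "expert"),
              sum(x$profiles$group == "student"),
              length(x$recordings), length(x$rest)))
  cat(sprintf("  fs %g Hz, task %g s, rest %g s, seed %d\n",
              x$config$fs, x$config$task_duration, x$config$rest_duration,
              x$config$seed))
  invisible(x)
}

#' Write a study to disk
#'
#' Recordings and rest segments are written one file per segment (long CSV
#' or EDF), plus `questionnaire.csv`, `profiles.csv` and `ground_truth.csv`.
#'
#' @param study an `eeg_study`.
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"` for the EEG segments.
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writer <- if (format == "csv") write_recording_csv else write_recording_edf
  for (nm in names(study$recordings)) {
    writer(study$recordings[[nm]],
           file.path(dir, paste0("task_", nm, ".", format)))
  }
  for (nm in names(study$rest)) {
    writer(study$rest[[nm]], file.path(dir, paste0("rest_", nm, ".", format)))
  }
  utils::write.csv(study$questionnaire,
                   file.path(dir, "questionnaire.csv"), row.names = FALSE)
  utils::write.csv(study$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(study$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
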