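# Monte-Carlo runners for calibration and power checks of the pipeline.
# These drive many reduced-size synthetic studies through the analysis chain;
# recording durations are arguments so callers can trade precision against
# runtime, while the programmed effect sizes always come from the effect
# spec itself.

#' Within-factor p-value of one null synthetic study
#'
#' Generates a study with [null_effects()] (all gains 1, all shifts 0),
#' computes the workload index per subject x condition through the
#' preprocessing chain, and returns the within-factor (condition) p-value of
#' the 2x2 mixed ANOVA. Band schemes use the profiles' true IAF and ocular
#' artifacts are disabled: both are condition-independent, so they cannot
#' affect the type-I rate being calibrated, and skipping them keeps large
#' replication counts tractable.
#'
#' @param seed integer seed for the study.
#' @param n_expert,n_student group sizes.
#' @param duration task-recording duration (s); `fs` sampling rate.
#' @return the condition-effect p-value.
#' @export
null_study_pvalue <- function(seed, n_expert = 11, n_student = 10,
                              duration = 16, fs = 128) {
  profiles <- make_profiles(n_expert, n_student,
                            seed = derive_seed(seed, "null/profiles"))
  eff <- null_effects()
  rows <- vector("list", 2L * nrow(profiles))
  k <- 0L
  for (i in seq_len(nrow(profiles))) {
    scheme <- band_edges(profiles$true_iaf[i])
    for (cond in study_conditions) {
      rec <- synthesize_recording(
        profiles[i, ], cond, eff, duration, fs,
        seed = derive_seed(seed, paste0("null/", i, "/", cond)),
        blink_rate = 0, spike_rate = 0)
      ep <- preprocess_recording(rec, blink_mode = "off")
      k <- k + 1L
      rows[[k]] <- data.frame(subject_id = profiles$subject_id[i],
                              group = profiles$group[i], condition = cond,
                              value = workload_index(ep, scheme)$wl)
    }
  }
  mixed_anova(do.call(rbind, rows))$table$p[1]
}

#' Summary of one default-effects synthetic study
#'
#' Generates a full study with the default programmed effects, runs the
#' complete chain (rest-based IAF estimation, filtering, blink correction,
#' artifact rejection, neurometrics) and fits the 2x2 mixed ANOVA on the
#' workload and acceptance indices.
#'
#' @param seed study seed.
#' @param task_duration,rest_duration,fs study sizes (seconds, Hz).
#' @param n_expert,n_student group sizes.
#' @return list: `wl_mean` (named by condition), `p_explainability_wl`,
#'   `aw_cell_means` (group x condition matrix), `metrics`.
#' @export
effect_study_summary <- function(seed, task_duration = 64,
                                 rest_duration = 30, fs = 128,
                                 n_expert = 11, n_student = 10) {
  cfg <- study_config(n_expert = n_expert, n_student = n_student, fs = fs,
                      task_duration = task_duration,
                      rest_duration = rest_duration, seed = seed)
  study <- generate_study(cfg)
  metrics <- suppressWarnings(aggregate_study(study))
  wl <- metrics[, c("subject_id", "group", "condition", "wl")]
  names(wl)[4] <- "value"
  fit <- mixed_anova(wl)
  aw_cells <- tapply(metrics$aw, list(metrics$group, metrics$condition),
                     mean)
  list(wl_mean = tapply(metrics$wl, metrics$condition, mean),
       p_explainability_wl = fit$table$p[1],
       aw_cell_means = aw_cells,
       metrics = metrics)
}

#' IAF recovery errors over synthetic rest segments
#'
#' Draws `n` subject profiles, synthesizes one rest segment each, runs the
#' filter and [estimate_iaf()], and returns the absolute estimation errors
#' against the profiles' true IAF.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param duration,fs rest-segment size.
#' @return numeric vector of `|estimated - true|` in Hz.
#' @export
iaf_recovery_errors <- function(n = 100, seed = 1, duration = 60, fs = 128) {
  profiles <- make_profiles(ceiling(n / 2), floor(n / 2),
                            seed = derive_seed(seed, "iaf/profiles"))
  vapply(seq_len(n), function(i) {
    rest <- synthesize_rest(profiles[i, ], duration, fs,
                            seed = derive_seed(seed, paste0("iaf/", i)))
    est <- estimate_iaf(bandpass_filter(rest))
    abs(est - profiles$true_iaf[i])
  }, numeric(1))
}
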