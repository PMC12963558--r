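test_that("profiles have the requested group structure and are seeded", {
  p <- make_profiles(11, 10, seed = 7)
  expect_equal(nrow(p), 21)
  expect_equal(sum(p$group == "expert"), 11)
  expect_equal(sum(p$group == "student"), 10)
  expect_true(all(p$true_iaf >= 8 & p$true_iaf <= 12))
  expect_true(all(p$base_theta_amp >= 0 & p$base_alpha_amp >= 0 &
                    p$blink_rate >= 0 & p$noise_rms >= 0))

  expect_equal(nrow(make_profiles(0, 0, seed = 1)), 0)
  expect_identical(make_profiles(5, 5, seed = 1), make_profiles(5, 5, seed = 1))
  expect_error(make_profiles(-1, 5, seed = 1), "non-negative")
})

test_that("recordings are seed-deterministic and validate arguments", {
  p <- quiet_profile()
  a <- synthesize_recording(p, "BB", effect_spec(), 12, 128, seed = 3)
  b <- synthesize_recording(p, "BB", effect_spec(), 12, 128, seed = 3)
  expect_identical(a$samples, b$samples)
  expect_error(synthesize_recording(p, "XX", effect_spec(), 12, 128, 1),
               "unknown condition")
  expect_error(synthesize_recording(p, "BB", effect_spec(), 5, 128, 1),
               "duration")
  expect_error(effect_spec(theta_gain = c(BB = 0, HM = 1)), "positive")
  expect_error(effect_spec(default_loading = 1.4), "loadings")
})

test_that("theta gain raises frontal theta band power (periodogram oracle)", {
  p <- quiet_profile()
  eff_hi <- effect_spec(theta_gain = c(BB = 1.3, HM = 1.0))
  same_subject_power <- function(cond, seed) {
    rec <- synthesize_recording(p, cond, eff_hi, 30, 128, seed = seed,
                                blink_rate = 0, spike_rate = 0)
    band <- c(p$true_iaf - 6, p$true_iaf - 2)
    mean(vapply(1:28, function(e) {
      idx <- ((e - 1) * 128 + 1):(e * 128)
      mean(vapply(1:5, function(ch)
        oracle_band_power(rec$samples[ch, idx], 128, band), 0))
    }, 0))
  }
  pw <- vapply(1:5, function(s) {
    same_subject_power("BB", s) - same_subject_power("HM", s)
  }, 0)
  expect_true(all(pw > 0))
})

test_that("rest segments expose the alpha peak and are sized correctly", {
  p <- make_profiles(3, 0, seed = 9)
  r <- synthesize_rest(p[1, ], duration = 60, fs = 256, seed = 2)
  expect_equal(ncol(r$samples), 15360)
  expect_identical(r$samples,
                   synthesize_rest(p[1, ], 60, 256, seed = 2)$samples)
  expect_error(synthesize_rest(p[1, ], duration = 10, fs = 128, seed = 1),
               "at least 30")
  # downstream IAF estimate lands within one 0.5 Hz bin + peak-width slack
  est <- estimate_iaf(bandpass_filter(synthesize_rest(p[2, ], 60, 128,
                                                      seed = 5)))
  expect_lt(abs(est - p$true_iaf[2]), 0.6)
})

test_that("artifact-free low-amplitude recordings survive thresholding", {
  p <- quiet_profile()
  rec <- synthesize_recording(p, "HM", effect_spec(), 20, 128, seed = 8,
                              blink_rate = 0, spike_rate = 0)
  ep <- mark_amplitude_artifacts(segment_epochs(rec), threshold = 80)
  expect_equal(sum(ep$artifact_mask), 0)
})

test_that("questionnaire responses are clipped, keyed and construct-coherent", {
  p <- make_profiles(11, 10, seed = 3)
  q <- synthesize_questionnaire(p, effect_spec(), seed = 11)
  expect_true(all(q$response %in% 1:5))
  expect_equal(nrow(q), 21 * 2 * 6)
  # noise-free, loading-1 items of one construct are identical
  eff0 <- effect_spec(item_noise_sd = 0, default_loading = 1)
  q0 <- synthesize_questionnaire(p, eff0,
                                 list(composite_spec("c", c("x", "y"))),
                                 seed = 2)
  wide <- reshape(as.data.frame(q0)[, c("subject_id", "condition", "item",
                                        "response")],
                  idvar = c("subject_id", "condition"), timevar = "item",
                  direction = "wide")
  expect_identical(wide$response.x, wide$response.y)
  # duplicate item assignment rejected
  expect_error(
    synthesize_questionnaire(p, effect_spec(),
                             list(composite_spec("a", c("i1", "i2")),
                                  composite_spec("b", c("i2"))), seed = 1),
    "more than one construct")
})

test_that("two-item construct recovers a strong positive correlation", {
  # loading 0.9 with noise sd 0.45 targets a population correlation near 0.7
  # on the discretized 1-5 scale; sample r (n = 42) should land in a wide
  # band around it for >= 90% of seeds
  eff <- effect_spec(item_noise_sd = 0.45, subject_sd = 1,
                     likert_shift = data.frame(construct = character(),
                                               group = character(),
                                               condition = character(),
                                               shift = numeric()))
  rs <- vapply(1:200, function(s) {
    p <- make_profiles(11, 10, seed = s)
    q <- synthesize_questionnaire(p, eff,
                                  list(composite_spec("c1", c("i1", "i2"))),
                                  seed = 1000 + s)
    correlation_matrix(q)$r["i1", "i2"]
  }, 0)
  expect_gte(mean(rs >= 0.5 & rs <= 0.85), 0.9)
})

test_that("generate_study assembles a complete reproducible dataset", {
  st <- small_study(seed = 13)
  n <- nrow(st$profiles)
  expect_equal(length(st$recordings), 2 * n)
  expect_equal(length(st$rest), n)
  expect_equal(sort(unique(st$questionnaire$subject_id)),
               sort(st$profiles$subject_id))
  # programmed workload direction is recorded in the ground truth
  expect_true(all(st$ground_truth$wl_bb_gt_hm))
  # byte-identical regeneration from the same seed
  st2 <- small_study(seed = 13)
  expect_identical(st$recordings[["S01.BB"]]$samples,
                   st2$recordings[["S01.BB"]]$samples)
  expect_identical(st$questionnaire$response, st2$questionnaire$response)
  expect_error(generate_study(study_config(seed = NULL)), "seed")
})
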