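---
title: "EEG workload and acceptance neurometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG workload and acceptance neurometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegmetrics)
```

This vignette is the package's account of the science it implements: the
neurophysiological model behind the two indices, the preprocessing chain and
its parameters, what the synthetic-study generator emulates (and what it
does not), the statistical machinery, and the numerical and design choices
made where the design was genuinely open.

## The neurophysiological model

Two robust spectral signatures of cognitive state motivate the indices.
Under rising mental workload, theta-band power over the prefrontal cortex
increases while alpha-band power over the posterior parietal cortex
decreases; their ratio therefore moves monotonically with load from both
ends. Separately, frontal alpha asymmetry indexes approach versus withdrawal
motivation: because alpha power is inversely related to cortical activation,
relatively more alpha over the *right* prefrontal cortex means relatively
less right-hemisphere (withdrawal-system) activity, read as approach —
here, acceptance of the stimulus.

Band edges are subject-specific. Alpha peak frequency varies by a couple of
Hz across adults, so fixed 4–8/8–12 Hz bands mix bands across subjects. The
package anchors both bands to the individual alpha frequency (IAF) estimated
from an eyes-closed rest segment, where the alpha peak is most prominent:

* theta = [IAF − 6, IAF − 2] Hz, alpha = [IAF − 2, IAF + 2] Hz.

The two bands tile [IAF − 6, IAF + 2] with a shared edge; for any IAF the
estimator can return (7–13 Hz) both lie inside the 2–30 Hz filtered range.

The indices, per subject and condition, over clean 1-s epochs:

* `WL = mean theta GFP (frontal pool) / mean alpha GFP (parietal pool)` —
  dimensionless and invariant to a global channel gain;
* `AW = mean alpha GFP (right frontal pool) − mean alpha GFP (left frontal
  pool)` in µV², exactly antisymmetric under swapping the pools.

### GFP operationalization

"Global field power over a channel subset" admits more than one formula. The
classical definition (per-sample across-channel variance) degenerates to
zero on spatially uniform signals and is unstable for 2–3 channel pools, so
the default here is the *mean over subset channels of per-channel band
power* (integral of the per-epoch Hanning periodogram over the band). The
spatial-variance form is available via `gfp_mode = "spatial-variance"` for
sensitivity analysis. Likewise the channel pools are configurable; defaults
are frontal = {AFz, AF3, AF4, AF7, AF8}, parietal = {Pz, P3, P4},
asymmetry right = {AF4, AF8}, left = {AF3, AF7} (midline AFz excluded from
the hemispheric pools).

Two further aggregation choices: WL uses the ratio of epoch-mean powers
rather than the mean of per-epoch ratios (per-epoch ratios are noisy at 1-s
resolution; the alternative is available via `per_epoch_ratio = TRUE`), and
AW is a raw power difference in µV² as the definition states, with a
log-power variant (`aw_scale = "log"`) behind a flag because much of the
asymmetry literature works on log power.

## Preprocessing chain

Fixed order: band-pass filter → blink handling → edge trimming → 1-s
epoching → amplitude thresholding.

| parameter | default | meaning |
|---|---|---|
| `low`, `high` | 2, 30 Hz | Butterworth band-pass edges |
| `order` | 5 | design order; applied forward–backward (zero phase), so the magnitude response is effectively squared |
| `blink_mode` | `"correct"` | `"reject"` marks blink epochs instead; `"off"` disables |
| `epoch_length` | 1 s | epoching unit; non-overlapping |
| `threshold_uv` | 80 µV | any-channel, any-sample rejection threshold per epoch |
| `trim` | 1 s | cut from each end after filtering (filter transients) |

Zero-phase filtering was chosen because only band *power* is consumed
downstream; the doubled effective order is documented and harmless here.
The rejection rule is deliberately conservative: one violating sample on one
channel rejects the whole epoch, and the mask is monotone in the threshold.

### Blink correction

The blink corrector is a template-regression algorithm of this package
(published blink-specific cleaners exist whose internals are not public;
the contract here — suppress the frontally dominant transient without
distorting the background spectrum — is what the tests assert). Detection
runs on AFz low-passed below 8 Hz with a 40 µV amplitude criterion;
suprathreshold runs closer than 150 ms merge into one event (a blink's own
two lobes merge; distinct blinks ≥ 300 ms apart resolve). Within ±300 ms of
each detection the low-passed AFz waveform is the template, regressed out of
every channel by least squares. Samples outside blink windows are untouched
by construction. Overlapping blinks can superpose destructively and evade
the amplitude criterion; at realistic blink rates this affects a small
minority of events, and the rejected-epoch route (`blink_mode = "reject"`)
is available when correction fidelity matters more than data retention.

### IAF estimation

Welch spectrum of the rest segment (2-s Hanning windows, 50% overlap,
0.5 Hz resolution) averaged over the parietal pool; the IAF is the largest
local maximum of the lightly smoothed (3-bin moving average) spectrum in
7–13 Hz. A candidate peak must exceed 1.25× the median in-range density —
without this prominence criterion, sampling fluctuations of a peakless
spectrum (white noise input) would always produce some local maximum. When
no peak qualifies the conventional 10 Hz is returned with a warning, which
the pipeline surfaces in its report.

## The synthetic-study generator

The generator exists so that every downstream stage is testable offline
with known ground truth. Per channel it superposes:

* a band-limited 1/f ("pink") background, 1–45 Hz, scaled to the subject's
  RMS (default drawn around 8 µV) — a plausible EEG floor;
* oscillations as back-to-back Hanning-windowed bursts of 1–2 s with random
  phase (a continuous tone would put a degenerate line in the spectrum):
  frontal theta at IAF − 4 Hz, parietal alpha at IAF, and frontal alpha at
  0.6× the parietal amplitude whose right-pool amplitude exceeds the left
  by the subject's resting offset (sd 0.15 µV) plus the programmed
  condition shift;
* biphasic blink transients (250 ms positive lobe, 150 ms negative at 40%,
  120 µV at AFz, scaled 0.8 at AF3/AF4 and 0.6 at AF7/AF8, absent
  parietally) with Poisson arrivals at the subject's blink rate;
* rare rectangular spikes above 100 µV on random channels, for the
  threshold-rejection stage to catch.

Subjects (default 11 experts + 10 students) draw a true IAF from a
truncated normal (mean 10, sd 1, bounds 8–12 Hz). The default programmed
effects give the unexplained condition `BB` a frontal theta gain of 1.3 and
a parietal alpha gain of 0.8 (higher workload), give students a +0.5 µV
right-frontal alpha shift under the explained condition `HM` (higher
acceptance), and shift questionnaire latents toward higher willingness
under `HM` and higher perceived work-performance impact for students. The
frontal-alpha fraction (0.6) and resting-asymmetry spread (0.15 µV) were
fixed at design time so that the programmed 0.5 µV shift dominates
subject-level variability — i.e. so the generator actually instantiates the
effect structure it claims to program.

Likert items load on construct latents: response =
`round(loading × latent + noise)` clipped to 1–5, with latent = base (3) +
cell shift + subject intercept. Items of one construct therefore correlate
positively in expectation, which is what the correlation-screening stage
assumes.

What the generator does *not* emulate: volume conduction and realistic
scalp topographies (channels are independent apart from the programmed
structure), non-stationary artifacts other than blinks and spikes, EOG/ECG
channels, drowsiness drift, or any coupling between the questionnaire and
the EEG of the same subject. Passing tests therefore demonstrate that the
pipeline recovers programmed spectral structure from realistic noise floors
— not that it handles every pathology of real recordings.

## Statistics

The 2×2 mixed repeated-measures ANOVA is computed from closed-form stratum
decompositions: the between-subject stratum (subject means) splits into the
group effect and subjects-within-groups; the within-subject stratum
(condition difference scores) into the condition effect, the
condition × group interaction, and their residual. Effects use unweighted
cell means, so the sums of squares coincide with the Type III convention
under group imbalance (11 vs 10). With two within levels, no sphericity
question arises. An independent general-linear-model oracle (lm projections
with sum-to-zero contrasts via `car::Anova`) reproduces every SS, F and p
to 1e-10 in the test suite.

One subtlety worth recording: with unequal group sizes the five Type III
sums of squares are *not* additive — they do not sum to the total SS about
the grand mean (they do exactly when groups are balanced, which the test
suite asserts). This is a standard property of unweighted-means analyses,
not an implementation artifact.

Both η² conventions are always computed: classical (SS over the total of
all five SS rows) and partial (SS over SS + its stratum's residual SS);
classical ≤ partial for every source. Published tables are sometimes
inconsistent about which convention their η² column actually follows, which
is why `verify_printed_table()` reports both and matches each packaged table
against its arithmetically consistent convention.

### Verifying printed tables

`verify_printed_table()` reconstructs MS, F, p and both η² from printed
SS/df. Because printed SS are rounded (typically to 3 decimals), a derived
value can differ from its printed counterpart by more than its own printed
precision even when both are correct — e.g. an F of 0.27 computed from an
SS printed as 0.006 carries an ~8% input-rounding uncertainty. The
comparison therefore propagates the half-ulp interval of every printed SS
through each derived quantity (all derived quantities are monotone in each
input, so interval endpoints are exact) and flags a value *consistent* when
its derived interval overlaps the printed value's own rounding band. A
genuinely wrong printed value fails; a value differing only through input
rounding passes. Exact three-decimal agreement is additionally asserted for
the entries where the arithmetic reproduces the print digit-for-digit.

### Duncan's multiple range test

Critical values use the studentized range quantile at Duncan's protection
level `(1 − α)^(p−1)` for a span of `p` ordered means (obtained from the
studentized-range distribution in base R and validated against published
Duncan tables), scaled by `sqrt(MS_error / n_h)` with `n_h` the harmonic
mean of the spanned cell sizes. Testing is stepwise with the non-crossing
rule: pairs inside a non-significant wider span are never declared
significant. With two means the procedure reduces exactly to the two-sided
t-test on the same error term, which the suite verifies algebraically over
random inputs. For post-hoc comparison of the four group × condition cells,
the default error term pools the two strata's residuals
(`(SS_br + SS_wr) / (df_br + df_wr)`) — appropriate for comparisons that
cross both factors — with either single stratum selectable.

### Questionnaire screening

Item pairs are screened with Pearson r over all subject × condition
observations; p-values come from the t-transform with n − 2 df. A merge
into a composite is approved only when every pairwise r is positive at
p < 0.001 (configurable); approval is monotone in α, rejection is a valid
outcome, and the pipeline can force a build with a logged override. The
composite is the unweighted item mean (sum and z-mean variants available),
keeping composites on the 1–5 scale. Cronbach's α is emitted as an
informational diagnostic only.

## Configuration, determinism and problem sizes

The pipeline is driven by one YAML configuration with sections per stage
(`simulate`, `preprocess`, `neurometrics`, `questionnaire`, `stats`);
unknown keys are rejected and a seed is mandatory. Every random draw in a
study derives from the single top-level seed via a tagged hash
(`derive_seed`), so identical config + seed gives byte-identical outputs
and manifests record per-file checksums.

Monte-Carlo validation sizes are the package's chosen compromise between
estimator precision and runtime: type-I calibration uses 500 null studies
of 21 subjects with 16-s task recordings at 128 Hz (the F-test operates on
subject-level indices, so short recordings only widen per-subject
measurement noise, which the calibration should and does tolerate); effect
recovery uses 50 studies with 64-s recordings and full rest-based IAF
estimation; subject-level asymmetry checks use 300-s recordings because the
AW sampling error shrinks as `1/sqrt(epochs)` and should sit well below the
programmed 0.5 µV shift. Disk-default durations (300-s task, 60-s rest,
256 Hz) mirror a realistic scenario length.

## Known limitations

* The blink corrector's equivalence to any specific published cleaner
  cannot be asserted — only its contract (suppression without spectral
  distortion outside blink windows), which is what the tests pin down.
* AW in raw µV² inherits the scale of absolute alpha power, so
  between-subject comparisons of AW are noisier than within-subject ones;
  the log variant mitigates but changes interpretation.
* The EDF writer/reader covers the subset of EDF this package emits
  (continuous 16-bit records, common sampling rate); it is not a general
  EDF implementation.
* No normalization (e.g. per-subject z-scoring) is applied to neurometrics
  before the ANOVA; if a study requires it, transform the metrics table
  before fitting.
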