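---
title: "Methods: analysing intended and observed actions across formats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing intended and observed actions across formats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

When a person intends a hand action and when they watch the same action
being performed, do the same neural populations carry the same code? This
package implements a complete analysis pipeline for that question as posed
with intracortical array recordings from motor cortex (MC/MCM/MCL) and the
superior parietal lobule (SPL): single-unit statistics, a cross-format
linear-model taxonomy, representational similarity, linear decoding within
and across formats and time, high-gamma field-potential analysis, and
population geometry. Because such patient recordings are not publicly
deposited, the package pairs every analysis with a synthetic-session
generator that plants known coding structure, so each stage can be
validated end to end against ground truth.

The task model is a fully crossed 2 (hand) x 3 (action: lift, slide,
rotate) x 2 (direction) design, run in an *intention* format (the
participant prepares/executes the cued action) and an *observation* format
(the participant watches a video of it): 12 conditions per format, 12
repetitions per condition per block. The trial timeline places the hand
cue at 0 s, the action/direction cue at 0.5 s, the go cue at 1.5 s and the
video end at 2.5 s; trials are recorded over [-0.5, 3) s. Some figure
renderings of this paradigm place the go cue at 1.25 s; we treat 1.5 s as
the operative timeline and expose it as `task_design(go_time_s = ...)`
rather than asserting either value. Two *dissociation* variants decouple
the instructed action from a concurrently shown video using four conflict
types (congruent, action-incongruent, hand-incongruent, both-incongruent)
over a 2 (action) x 2 (hand) design with direction fixed; a probe variant
additionally forces recall of the video, making both streams behaviourally
relevant.

## Pipeline stages and their parameters

All stages consume `binned_rates`: net firing rates in 100 ms bins over
[0, 3) s, with the per-trial mean rate over the -500 to 0 ms baseline
subtracted (`bin_rates()`).

**Responsiveness and latency** (`test_responsiveness()`): overlapping
200 ms windows, 100 ms step, from stimulus onset (29 windows); per window
a t-test of the net rate against zero across a condition's trials — since
rates are baseline-subtracted per trial this *is* the paired comparison of
window activity versus baseline. Significance at alpha / 29 (Bonferroni
over windows); a unit is responsive given three consecutive significant
windows, and its latency is the centre of the first window of the earliest
such run. The source text does not state the sidedness of the t-test; the
default is two-sided (conservative), with `alternative = "greater"`
available since responsive units are described as above baseline.

**Tuning** (`anova_timecourse()`): per 500 ms non-overlapping bin, a
fixed-effects factorial ANOVA (3 factors for the main task, 2 for
dissociation) with all interactions, type-II sums of squares (identical to
the classical ANOVA on balanced tables, robust to mild imbalance after
artifact rejection). The stated significance divisor is the number of
units or channels; we implement that default with a per-bin option. A
unit counts as selectively tuned to a main effect only when no interaction
involving that factor is significant; interaction-tuned units are counted
under the interaction.

**Model taxonomy** (`fit_models_cv()`, `classify_population()`): per unit,
responses are averaged over the 1-2 s window, and ten linear models are
compared — null; invariant (action + hand + direction, shared weights);
shared action, hand, direction; a six-level action-by-direction variant;
mixed (all main effects and interactions, shared); idiosyncratic (full
factorial, separate coefficients per format); and intention-only /
observation-only models. Every non-null model carries a format intercept
so format-wise offsets never masquerade as tuning. Scoring is five-fold
cross-validation stratified over the 24 condition-by-format cells (fold
remainders spread over a random rotation so fold sizes stay balanced),
pooled held-out R^2 = 1 - SS_res/SS_tot with SS_tot about the training
mean; ties break toward fewer parameters. A unit keeps its winning label
iff cross-validated R^2 > 0.01, the label-shuffle permutation p (winning
model only, 1000 shuffles, design fixed) survives Benjamini-Hochberg FDR
at q = 0.05 across units, and the winner is not the null model.

A caveat established during validation and worth knowing when interpreting
taxonomy output: selection by highest cross-validated R^2 among *nested*
models is intrinsically noisy — a unit truly tuned only to action is
recovered as `action3` in roughly 75-85% of simulations at an effect of
three trial-SDs, with the remainder absorbed by the invariant / action6 /
mixed supersets. Repeated-CV averaging and alternative R^2 conventions do
not change this; it is a property of the selection rule, not of the
implementation.

**RSA** (`split_half_rsa()`): trials halved within condition (500 random
splits; the odd trial goes to side A); condition-averaged feature vectors
concatenate the 1-2 s bins with units; Pearson correlations between all
condition pairs form the matrix; within-format matrices correlate the two
half-averages of the same format, cross-format matrices correlate halves
of different formats so noise levels match, and within-format matrices
are symmetrised (the half assignment is arbitrary). Structure strength is
mean(diagonal) - mean(off-diagonal). The permutation null shuffles
condition labels independently within each format before splitting; by
default whole conditions are relabelled rather than individual trials,
because the trial-level shuffle destroys within-format geometry that the
cross-format null hypothesis should preserve and is measurably
anticonservative for populations with real but format-independent
structure; `null = "trial"` restores the literal trial-level scheme.
Robustness controls recompute the matrix in four alternative windows and
on all units, comparing lower triangles by Pearson correlation.

**Decoding** (`decode_timecourse()`, `cross_time_decode()`,
`cross_format_decode()`): LDA on PCA-reduced population activity.
Within-format: non-overlapping 200 ms windows (500 ms for high-gamma),
ten-fold stratified CV; per fold the PCA is fitted on training data
stacked across all windows (components to 95% variance, at most 50).
The LDA uses a pooled within-class covariance with equal priors and a
pseudo-inverse, so rank-deficient inputs degrade gracefully; shrinkage is
unnecessary behind the PCA step. Cross-time maps train at each window and
test at all windows within the same folds, so the diagonal reproduces the
time-resolved decoder exactly. Cross-format decoding trains on all trials
of one format per 100 ms bin (PCA fitted on the training format, top 50
components) and tests on every bin of the other; significance comes from
shuffling test labels map-wide per iteration (1000 times). For the
significance mask we use the max-statistic permutation correction rather
than the stated Bonferroni: with ~900 cells and 1000 permutations the
add-one permutation p can never clear a Bonferroni threshold, while the
plain proportion estimator under Bonferroni has a measured family-wise
error near 75% on null populations; the max-statistic correction is exact
under the map-wide shuffle null and `correction = "bonferroni"` retains
the literal variant. Trained models never see test labels, so permutation
inference cannot alter predictions.

**High-gamma** (`preprocess_lfp()`, `morlet_power()`,
`hg_unified_envelope()`): all filtering is FFT-based with real symmetric
responses (hence exactly zero-phase); no dedicated signal-processing
package is available in the target stack, and the Gaussian band shapes
are themselves the design. Line noise is suppressed by spectrum
interpolation at 60 Hz and harmonics (a reproducible stand-in for the
combined spectral-spatial method cited in the source, whose details are
external); the high-pass is an order-4 Butterworth magnitude at 2 Hz;
trials whose broadband RMS (pooled over channels) exceeds two SDs above
the session mean are flagged excluded. Morlet power uses 7-cycle wavelets
on a 60-120 Hz grid in 2 Hz steps (step size unstated in the source),
trims 100 ms at each trial edge, normalizes per frequency by the 500 ms
pre-stimulus baseline, and stores the time axis at 100 Hz. The unified
high-gamma envelope applies common-average referencing per array, eight
frequency-domain Gaussian band-pass filters with centres
`73 * (144/73)^(i/7)` and full-width-half-maximum 0.2 times the centre
(the simplest faithful reading of a semi-logarithmic 20% bandwidth),
analytic amplitudes, an anti-alias low-pass and resampling to 100 Hz,
per-channel z-scoring, tanh compression (scale 4 SD), and a per-channel
SVD across bands whose first left singular vector — sign-fixed to
positive mean band loading — is the envelope. Channel selection is a
paired t-test of the 1-2 s window against 0-0.5 s at p < 0.05. Note that
common-average referencing makes strong modulation on one channel leak
(sign-inverted) into quiet channels of the same array; this is faithful
to the method, not an artifact.

**Geometry** (`pca_trajectories()`, `procrustes_distance()`,
`embed_trials()`): condition-by-format mean timecourses over [-0.5, 2.5] s
are stacked and decomposed jointly; the top three components (signs fixed
by the largest-magnitude loading) define a shared space; variance
explained is reported for the combined stack and per format within the
shared space. Procrustes alignment is the standardized (symmetric) form —
both trajectories centred and scaled to unit Frobenius norm, distance
`d = 1 - (sum of singular values)^2` in [0, 1] — so values are comparable
across conditions; reflections are allowed by default (classical
Procrustes) with a proper-rotation toggle. UMAP embeds 1-2 s
window-averaged single trials (cosine metric, 15 neighbours, minimum
distance 0.1, via uwot) with per-group covariance-eigen ellipses.

**Dissociation analyses** (`derive_video_labels()`, `run_dissociation()`):
video labels follow deterministically from the instructed labels and
conflict type (action flips under action/both-incongruent, hand under
hand/both-incongruent); the battery composes two-way tuning for instructed
and video factors, instructed/video/16-way/conflict decoding per block,
optional cross-time maps, and an incongruent-only rerun. Windows after
probe onset (2.5 s) are excluded from peak bookkeeping by default to
avoid saccade-report confounds.

## The synthetic world

`simulate_spikes()` draws inhomogeneous-Poisson trains with rate
`baseline + effect * boxcar(latency, duration) * format_gain * indicator`;
the boxcar (rather than a smooth peri-stimulus shape) is deliberate — it
is the simplest profile that exercises the latency, three-consecutive-bin
and window logic analytically. Defaults: baseline 10 spikes/s and peak
effect 20 spikes/s (typical cortical task modulations; the source states
no per-archetype magnitudes), latency 1.0 s and duration 1.0 s so the
response fills the 1-2 s analysis window. Archetypes mirror the taxonomy,
plus a `gated_observer` that codes the *video* action only on trials where
the video is behaviourally relevant (observation blocks; always, in the
probe variant; `gating = "on"/"off"` overrides). `observation_gain`
scales observation-format effects and defaults to 0.5 for shared
archetypes, reproducing the qualitatively reduced observation responses.
One consequence decided a priori from the model algebra: a gain below 1
*is* a format-by-factor interaction, whose correct taxonomy label is
idiosyncratic rather than the shared model — so taxonomy-recovery
validation uses gain 1, while paper-like emulation keeps 0.5.

`simulate_lfp()` builds each trace as 1/f^beta background noise, a 60 Hz
line component, and a band-limited [73, 144] Hz carrier whose envelope
rises from 1 to 1 + depth in the response window on preferred-condition
trials.

What the generator does *not* emulate: refractoriness, spike waveforms and
sorting errors, rate co-fluctuations and noise correlations between units,
non-stationarities across a session, eye movements, and smooth response
shapes. A green test therefore establishes that each analysis recovers the
statistical structure it assumes, at realistic magnitudes — not that it is
robust to every pathology of real recordings.

## Numerical choices and degenerate inputs

Bins are half-open [left, right); windows crossing the trial end are
dropped. Zero-variance t-tests resolve to p = 1 (zero mean) or p = 0
(nonzero mean). Permutation p-values use the add-one estimator
`(1 + exceedances) / (n + 1)` except where noted above. Negative pooled
R^2 is reported as-is. Constant trajectories make Procrustes scaling
undefined and error; constant band envelopes z-score to zero with a
warning. All randomness flows through explicit seeds; identical
configurations reproduce byte-identical outputs.

## Known limitations

Single-format sessions cannot run cross-format stages; the pipeline skips
them. The taxonomy's nested-model confusion (above) bounds per-archetype
recovery near 75-85% at moderate effects. The spectrum-interpolation
notch omits the spatial filtering step of the cited line-noise method.
The Morlet grid step and several bandwidth conventions are reasoned
defaults, configurable where the source is silent.
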