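---
title: "Methods: synthetic EEG cohorts and the vulnerability-biomarker pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic EEG cohorts and the vulnerability-biomarker pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`vulneeg` re-implements, as tested and reusable code, an analysis family
common in affective neurophysiology: compare resting-state and task-based
EEG between groups with high and low vulnerability to depression, extract
the standard depression biomarkers, correct channel-wise statistics for
multiple comparisons, search for informative biomarker subsets with
evolutionary wrappers, and benchmark classifiers. Because real recordings
from such studies are not redistributable, the package treats the pipeline
itself as the object under test: synthetic cohorts with known, planted
group effects feed every stage, and the question is always whether the
stage recovers what was planted and stays quiet when nothing was.

## The synthetic cohort model

**Background signal.** Each channel carries independent 1/f-shaped noise:
white Gaussian noise is spectrally reweighted by |f|^(−χ/2) (default
exponent χ = 1, per-channel SD 10 µV) and renormalized. This reproduces
the two features of resting EEG that matter for the downstream estimators —
a falling spectrum and broadband phase — without volume conduction or
head-geometry modeling, which are explicit non-goals. FFT work is done at
the next highly composite length and truncated, so any requested duration
is O(n log n).

**Design constants.** The defaults are the study conditions: two groups of
20 subjects; 5-minute resting recordings at 512 Hz; the 32-channel Biosemi
10–20 montage (plus two EOG channels); SART sessions of 8 blocks × 90
trials with fixation crosses sampled from {1480, 1640, 1800, 1960, 2020} ms,
320 ms words, 880 ms masks, 3020 ms ISI, a 1/9 No-go rate, and stickiness
ratings 1–9 on the five trials preceding each thought probe (1–4
"less sticky", 6–9 "more sticky", 5 excluded). Probe frequency is not a
published constant; the generator's default of one probe per 18 trials
(~5 per block) is a free parameter chosen to give a few dozen labelled
trials per session. Questionnaire scores are drawn from untruncated
per-group normals with the published group means and SDs (PTQ 45.85/4.70
vs 25.10/8.33 and so on); instrument score ranges are not published, so no
clipping is applied and occasional out-of-range draws are possible by
design. Writing-task ratings (intensity, frequency) are jointly missing
for 3 high-group and 1 low-group subject by default, capped in smaller
cohorts so two observations always remain.

**Planted effects.** Group differences enter in two forms.
*Amplitude effects* add (g − 1) times the band-passed channel signal back
to the channel for high-vulnerability subjects, which multiplies that
band's amplitude by exactly g while leaving other bands untouched.
*Coupling effects* add a shared band-limited noise carrier to both channels
of a pair, the second copy rotated by a constant phase lag via FFT phase
rotation. Carriers are filtered noise rather than sinusoids so coherence,
PLV and PLI estimates are non-degenerate. A 90° lag at mixing coefficient
0.6 is comfortably detected by PLI at n = 20 + 20; a zero-lag version
raises correlation but not PLI, which is the volume-conduction control the
phase-lag index exists for.

**EOG and blinks.** Two EOG channels carry noise plus raised-cosine blink
transients (~300 ms, 120 µV) at 0.1 blinks/s, leaking into the four
frontal channels at gain 0.4. These exercise the rejection and
role-exclusion code paths; they are milder than real movement artifacts,
so rejection rates in synthetic runs are near zero and the peak-to-peak
rejection contract is instead tested with explicitly planted spikes.

## Preprocessing

The default chain mirrors standard event-related practice: zero-phase
band-pass (4th-order Butterworth, 0.5–40 Hz, applied forward-backward so
the effective response is |H(f)|²), segmentation from −0.5 to +1.3 s
around word onset under a half-open `round(t·fs)` sample convention
(exactly 922 samples at 512 Hz), baseline subtraction over the
pre-stimulus interval, peak-to-peak rejection at 150 µV on scalp channels
(an automatic proxy for manual artifact marking, which is not
reproducible), neighbor-mean interpolation of listed bad channels (k = 4
nearest montage neighbors by projected Euclidean distance), average
re-referencing over non-EOG channels, and trimming to the −0.2..1.3 s
analysis window (768 samples). Since −0.2 s is not on the 512 Hz sample
grid of a −0.5 s epoch, the trimmed window starts at the nearest grid
point (−0.19922 s). All operations are pure; resting data uses
consecutive 2 s pseudo-epochs instead of event segmentation.

## Biomarkers

Band edges tile the filtered range: delta 0.5–4 (published), theta 4–8,
alpha 8–13, beta 13–30, gamma 30–40 Hz (conventional choices; only the
delta edges are fixed by the source analysis), and "raw" means the full
0.5–40 Hz band with no further filtering. Spectral quantities use Welch
averaging with 2 s Hann windows and 50% overlap — 0.5 Hz resolution, enough
to resolve delta — capped at the epoch length, so 1.5 s task epochs
degrade to one segment per epoch with trials still averaged. Band power
integrates the PSD over [low, high); relative power divides by total
0.5–40 Hz power; alpha asymmetry is ln P(F4) − ln P(F3) (the F3/F4 pair is
conventional; the homologous pair is configurable). Coherency pools
cross-spectra over windows and trials before normalizing; the imaginary
part is stored as |Im C| because the signed quantity is antisymmetric in
channel order and the connectivity container is symmetric by contract.
Phase measures band-filter, take the analytic signal (FFT half-spectrum
construction), drop 5% of samples at each edge against filter transients,
and pool phase differences over time and trials; whether the original
analyses averaged per epoch or concatenated is unstated, and per-epoch
pooling was chosen as the variance-safer default. HFD uses kmax = 8; DFA
uses 12 log-spaced scales from 4 to N/4 with per-window linear detrending —
none of these constants are published, and all are arguments. Feature
tables default to one row per subject (matching a 20-vs-20 t-test);
per-epoch granularity is available.

## Group statistics

Group comparisons are pooled-variance t-tests (the published df = 38 at
n = 20 + 20 implies pooled; Welch is an option), also computable from
printed summary statistics. The 2×2 chi-square uses no continuity
correction, which is what reproduces the published gender statistic 5.23
on the 16/4 vs 9/11 table. Multiple comparisons are handled by
Benjamini–Hochberg step-up at q = 0.05, applied per feature family (the 32
channels of one measure-band, or its 496 pairs), mirroring per-panel
thresholds; the masked t-vector sets non-significant channels to zero for
topography export. Recomputing the published questionnaire t values from
their rounded summaries reproduces PTQ 9.70 and CES-D 9.71 exactly and
gives 10.184 where 10.19 was printed for RRS — agreement to one unit in
the last printed digit, the expected artifact of summary rounding.

## Feature selection

The three wrappers share one fitness: stratified 5-fold cross-validated
accuracy of a Gini decision tree (depth 5 default; rpart caps depth at 30)
on the selected columns, minus λ times the selected fraction (λ = 0 by
default, matching plain-accuracy reporting; the analysis scripts use
λ = 0.05 to demonstrate parsimony pressure). Masks traverse an empty-set
fitness of −2 rather than erroring. Binary encoding follows standard
binary-GWO/PSO practice — sigmoid transfer with a 0.5 threshold on
continuous positions — since the source describes no encoding. Defaults
are population 10 and 20 iterations (convergence traces flatten well
before that); GA uses tournament-3 selection, one-point crossover at 0.8,
per-bit mutation at 1/d and elitism of one; PSO uses inertia 0.7,
cognitive/social weights 1.5, velocity clamp 4. Bits default to
biomarker-level (measure, band) blocks rather than single columns because
subsets are reported at the biomarker level ("HFD in delta"), with
column-level available. Exhaustive search over all 2^d − 1 masks at d ≤ 10
is the oracle the optimizers are held to in the tests.

## Classification

Sequence models consume 32-sample windows cut within (never across) trial
boundaries; DT and MLP flatten them. Splits are sample-level (stratified
over windows, 60/20/20 or k = 5) or subject-level (whole subjects per
partition). Sample-level is the default, matching common practice in this literature, and is leak-prone:
windows of one subject appear on both sides of the split, so
subject-identity cues inflate accuracy. `leakage_demo()` plants
subject-specific channel offsets with no group effect and shows
sample-level accuracy far above chance while subject-level stays at it —
the mechanism that plausibly inflates headline accuracies in this
literature; subject-level evaluation is the recommended honest protocol.
The neural families (MLP 16/8; CNN with two valid conv blocks of 32/64
filters, kernel 3, global average pooling; LSTM hidden 24; BLSTM 16 per
direction with a 16-unit head — the recurrent sizes are desk-scale
choices, as the published architectures beyond the running text are not
specified) train with Adam (lr 0.001, β₁ 0.9, β₂ 0.999, batch 32), early
stopping on validation loss with patience 5 and at most 50 epochs, all
seeded; forward/backward passes are verified against finite differences
in the test suite.

## Numerical choices and degenerate inputs

Butterworth band-passes are stable in double precision down to the delta
band at 512 Hz; forward-backward application doubles the effective order
and zeroes the phase, which the tests verify against the designed |H(f)|²
and a symmetric-pulse invariance. Constant signals are rejected by HFD and
DFA (no curve length / no fluctuation); zero-variance channels are
rejected by correlation; both-constant-equal samples make the t statistic
undefined and error. Welch estimators require at least two averaged
segments for coherence. Ties in k-NN montage distances are resolved by
stable ordering of the packaged coordinates.

## What the synthetic tests do and do not show

Passing the suite shows the estimators are correct on signals with known
ground truth, that BH-FDR is calibrated under the null, that planted
effects of the stated sizes are recoverable at the study's sample size,
and that the selection and classification layers behave rationally on
separable, null and leakage constructions. It does not show that real
resting EEG contains such effects, nor that the published real-data
accuracies (98.06% resting, 91.42% task) are attainable — those recordings
are not available, the synthetic generator models no volume conduction,
subject heterogeneity, or nonstationarity, and the sample-level protocol
behind such numbers is exactly the one the leakage demonstration argues
against.

## Problem sizes used in shipped runs

The analysis scripts run 8 + 8 subjects with 60 s rest and 2 × 30 task
trials; the acceptance script uses 20 + 20 subjects with 20 s recordings
for effect recovery (20 replicates), 200 null cohorts for FDR calibration,
and 1023-mask exhaustive oracles for selection. These sizes were chosen as
the smallest at which every planted effect is comfortably inside its
detection regime, and they are stated here so that larger re-runs are a
matter of changing the `cohort_spec()` arguments.
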