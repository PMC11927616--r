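---
title: "Methods: axis coding, attention, and spike-field interactions in fixation-aligned recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axis coding, attention, and spike-field interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

During free-gaze visual search, a primate fixates a sequence of array items;
each fixation can be treated as a trial, with neuronal responses referenced
to fixation onset. Two properties of a unit are of interest:

* **Axis coding** — whether the unit's firing rate is a (near-)linear
  function of the fixated stimulus's position in a high-dimensional visual
  feature space (e.g. deep-network embeddings). Units with this property
  encode *directions* (axes) of feature space rather than single exemplars.
* **Attention coding** — whether the unit fires differently when the fixated
  item is a search target versus a distractor.

`fixsearch` implements the full chain needed to relate the two: unit
screening (responsiveness, receptive-field class, category selectivity),
axis-coding detection with a permutation-calibrated PLS encoding model,
population representational geometry, fixation-windowed spike-LFP
coherence, and frequency-domain Granger causality, all exercised end to end
on a synthetic-session simulator with planted ground truth.

## Analysis windows

All windows are milliseconds relative to an anchor event and half-open
`[start, end)`, so adjacent windows never double-count a spike:

| name | interval | anchor | used for |
|---|---|---|---|
| feature (early) | [50, 150) | fixation onset | encoding models, early geometry |
| attention (late) | [150, 225) | fixation onset | attention index, late geometry |
| baseline | [-150, 0) | cue onset | baseline subtraction, responsiveness |
| cue_response | [50, 200) | cue / array onset | responsiveness, category selectivity |

Windowed rates are spike counts divided by window length. The spike density
function uses a causal EPSP-like kernel
$K(t) = (1 - e^{-t/\tau_g})\,e^{-t/\tau_d}$ with growth
$\tau_g = 1$ ms and decay $\tau_d = 20$ ms, normalised to unit area so the
trace is a rate estimate in spikes/s; the normalisation constant is a
package choice (it cancels in every normalised quantity).

## The synthetic-session simulator

No recordings ship with the package; every downstream stage is validated on
simulated sessions with known ground truth. The simulator emulates:

* **Task structure** — 400 ms initial fixation; cue (uniform 500–1300 ms);
  500 ms delay; a search array of 11 items, exactly 2 of which are targets
  of the cue's category, placed at 11 of 20 locations; a fixation sequence
  over the items. Fixation durations are log-normal matched to mean/SD
  208.24/153.77 ms and truncated below at 80 ms (sub-80 ms "fixations" are
  not analysable events); items are visited uniformly at random, since the
  task imposes no search-order constraint. The truncation raises the
  realised mean duration slightly above the nominal value; we accept this
  rather than re-fitting the parameters, because no analysis depends on the
  mean duration itself.
* **Stimulus features** — four categories (face, house, flower, hand) of 40
  stimuli each, embedded in `D = 512` dimensions. Category means are
  near-orthogonal random directions with norm $\sqrt{2}\,s$ (so two means
  sit $2s$ apart, `s` = `separation`, default 4) and stimuli scatter
  isotropically with unit variance. At the default separation a supervised
  linear readout of category from held-out stimuli is nearly perfect, and
  the leading principal component of the features separates categories, as
  with real deep-network embeddings.
* **Axis units** — rate for stimulus $s$ is
  $r(s) = \mathrm{softplus}(b + m\,z_s)$, where $z_s$ is the standardised
  projection of the stimulus features onto the unit's random unit-norm axis,
  $b$ is the unit's baseline rate and $m$ = `rate_mod_sd` $\times\, b$. The
  softplus link keeps rates non-negative while remaining effectively linear
  at the baseline rates used (8–20 spikes/s), so the planted code stays
  recoverable by a linear encoding model. Non-axis units receive
  per-stimulus rates drawn independently of the features (log-normal around
  baseline with matched spread) — an *exact* null for permutation
  calibration, not merely a weakly tuned unit.
* **Attentional gain** — multiplicative rate gain on target fixations,
  applied only in the late window; per-unit gains are drawn around
  class-specific means (axis 1.4, non-axis 1.15, SD 0.1). The class
  difference plants the axis > non-axis attentional asymmetry that the
  group-level analyses are designed to detect; the per-unit jitter makes
  attentional scaling non-proportional across the population, which is what
  allows representational *angles* (not just distances) to change.
* **Theta spike-field coupling** — each area has one theta oscillator whose
  instantaneous frequency drifts inside 4–12 Hz (mean-reverting walk); its
  phase is shared between the area's LFP channels
  (LFP = theta sinusoid + 1/f noise) and the spike modulation
  $r(t) \propto 1 + \lambda \cos\phi(t)$ during the first 200 ms of each
  fixation. Locking depth $\lambda$ is 0.6 on distractor fixations and
  drops on target fixations (axis units to 0.2, non-axis to 0.45), planting
  target-induced theta desynchronisation that is stronger for axis units.
* **Spiking** — inhomogeneous Poisson at 1 ms resolution; spontaneous rate
  between stimulus-drive periods is half the unit's baseline. Stimulus
  drive follows events with a 50 ms latency.

Defaults (200 trials, 10 fixations per trial, 12 units and 2 electrodes
per area in V4/TEO/TE/OFC) were chosen once so that a single session
contains roughly 1,500–2,000 analysable fixations — enough for the planted
effects to be recoverable at desk scale — and were not revisited
afterwards. What the simulator does **not** emulate: retinotopy and
peripheral receptive fields (every unit responds to the fixated item),
saccade dynamics and eye-position noise, spike-sorting artefacts,
cross-area conduction delays, and non-Poisson spiking statistics. Passing
tests therefore demonstrate the correctness and calibration of the
analysis chain under the planted generative model, not robustness to those
real-data complications.

## Axis-coding detection

The encoding model is PLS regression from the feature matrix to the unit's
mean rate per stimulus (distractor fixations, early window). PLS is
required because `D` (512) exceeds the number of stimuli; four latent
components are used by default. The implementation is SIMPLS on centred
data; for a univariate response the components admit a closed-form
deflation, and because all quantities live in the span of the training
rows, the permutation loop runs in the `n x n` Gram space — algebraically
identical to the feature-space computation (the package tests assert
agreement to 1e-10, and agreement of the fit with an independent PLS
implementation).

Significance uses a split-and-permute procedure with `n_perm` runs. Per
run: draw a random 50/50 train/test split of stimuli; fit on the training
half; correlate predicted with actual rates on the held-out half, once
with true labels and once with the rate vector shuffled against the
feature rows before splitting. The unit is flagged axis-coding when the
observed correlation exceeds the 95th percentile of the null correlations;
the observed correlation is also the *strength* of axis coding.

Two calibration decisions deserve note:

* **Single-split observed statistic (default).** Averaging the observed
  correlation over the whole split ensemble looks attractive (it removes
  split-choice variance) but mis-calibrates the percentile rule: the mean
  of hundreds of split-correlations has far smaller null variance than the
  single-split null draws it is compared against, driving the false-flag
  rate from the nominal 5% down to about 1%. With a single-split observed
  statistic, observed and null draws are exchangeable under the null and
  the selection is calibrated exactly; measured specificity on 500 null
  units is within the binomial band around 95%. The ensemble mode remains
  available (`observed = "ensemble"`) for users who prefer a conservative
  selection.
* **Number of permutation runs.** The reference procedure uses 1000 runs;
  package tests and the acceptance script use 200. The empirical
  percentile rule is unbiased in the number of runs — only the resolution
  of the null quantile (and hence the variance of the decision) changes —
  so the flag rate is unchanged in expectation. 200 runs keep the
  500-unit calibration suite within a few minutes on one CPU.

Component count is fixed at 4 rather than re-selected per dataset by
variance explained; it is exposed as configuration.

## Category selectivity and attention

The selectivity index is $SI = (R_f - R_h)/(R_f + R_h)$ on
baseline-subtracted face/house responses, clamped to $+1$ when
$R_f > 0 > R_h$ and $-1$ when $R_f < 0 < R_h$ (the ratio is meaningless
with mixed signs), and clipped into $[-1, 1]$ otherwise. Face-selective
units additionally need rank-sum $p < 0.05$ and $SI > 0.13$ (i.e.
$R_f \ge 1.3\,R_h$); house-selective symmetrically.

Attention selectivity pairs responses *per stimulus* — the unit's mean
late-window rate when a stimulus was fixated as a target versus as a
distractor — and applies a two-tailed Wilcoxon signed-rank test. The
stimulus is the natural pairing entity because it is the repeated unit
across roles; at least 6 stimuli fixated in both roles are required. The
attention index is the normalised contrast of the condition means,
$(FR_T - FR_D)/(FR_T + FR_D)$.

## Representational geometry

Dissimilarity matrices use $1 - r$ (Pearson) between population response
patterns; correspondence between matrices uses Spearman correlation of the
lower triangles with a label-shuffling permutation null (Bonferroni across
comparisons is left to the caller).

For geometry, each stimulus is a point in unit space: $v_s$ is the
population mean-rate vector for stimulus $s$ in a condition. For every
stimulus pair, the Euclidean distance $\lVert v_i - v_j\rVert$ and the
angle $\arccos(v_i \cdot v_j / \lVert v_i\rVert\lVert v_j\rVert)$ are
computed per condition, contrasted as $(T - D)/(T + D)$, and compared with
a paired t test across pairs (64 stimuli give 2016 pairs, df 2015 — the
degrees of freedom uniquely identify the per-stimulus-pair reading of
"distance between units", which is the interpretation adopted). Distances
scale linearly under proportional rate scaling while angles are invariant,
so angle changes isolate genuine reshaping of the population code from
global gain. Pairs involving a zero population vector get `NA` angles and
are counted, never dropped silently. Geometry is computed in both early
and late windows.

## Spike-LFP coherence

Coherence is $C_{xy}(f) = |S_{xy}(f)| / \sqrt{S_x(f) S_y(f)}$ with auto-
and cross-spectra averaged across fixations before the division. Per
fixation, a fixed 200 ms window from fixation onset is used regardless of
fixation duration (short fixations therefore overlap the next fixation;
the window is part of the procedure). Spikes are binned as counts at the
LFP sampling rate and mean-subtracted per segment; the LFP is
mean-subtracted per segment; both get a single Hanning taper. On a 200 ms
window at 1 kHz the frequency resolution is 5 Hz, so the 4–12 Hz theta
summary averages the 5 and 10 Hz bins. Spikes and LFP must come from
different electrodes.

Because coherence magnitude is biased upward by finite sampling (about
$1/\sqrt{n_{\text{segments}}}$ for independent signals — asserted in the
tests), conditions are compared only after equalising both the number of
fixations and the number of spikes: the larger condition is subsampled
without replacement and excess spikes are deleted at random, repeated 20
times with the spectra averaged over repeats (repetition reduces
subsampling variance; the equal-count rule holds within every repeat).
The desynchronisation index is the normalised contrast
$(C_D - C_T)/(C_D + C_T)$ of theta-band means, positive when target
fixations desynchronise. An optional flag subtracts the coherence
estimated from the initial fixations preceding the cue.

## Granger causality

LFP segments are detrended (per-segment least-squares line) and the
across-segment ensemble mean is removed; spike segments are binned and
demeaned. Segments whose LFP fails a KPSS level-stationarity screen
(Bartlett-kernel long-run variance, lag $\lfloor 4 (T/100)^{1/4}\rfloor$,
5% critical value 0.463) are excluded. A bivariate VAR is fitted by least
squares pooled across the surviving segments, with lagged rows never
crossing segment boundaries; the order is selected by AIC (capped at 15 —
200-sample segments bound the usable order; the session-level wrapper uses
a cap of 8), and stability is checked via the companion-matrix spectral
radius. The spectral measure is
$$G_{j\to i}(f) = -\ln\!\Big(1 - \big(\Sigma_{jj} - \Sigma_{ij}^2/\Sigma_{ii}\big)\,|H_{ij}(f)|^2 / S_{ii}(f)\Big),$$
with $H(f) = (I - \sum_k A_k e^{-i2\pi f k/f_s})^{-1}$ and
$S = H \Sigma H^*$. A time-domain Geweke measure
($\ln$ of restricted/full residual variance) serves as an independent
oracle: the frequency-averaged spectral measure must match it within 5% on
long simulated series. Spike trains enter as demeaned binned counts at the
sampling rate — a convention the package states rather than infers.
Condition contrasts are theta-band means in
$(G_D - G_T)/(G_D + G_T)$ form, per direction.

## Group-level statistics

Per area: a binomial test of the flagged-unit proportion against chance,
where chance is the selection alpha (0.05) — the selection tests run at
5%, so 5% is the null flag rate; a chi-squared test (uncorrected Pearson)
of proportion differences between areas; a two-sample t test of the
attention index between axis and non-axis units; and a chi-squared
enrichment test of attention selectivity within axis units, Bonferroni
corrected across areas.

## Numerical choices and degenerate inputs

* Half-open windows everywhere; times in ms; spike times sorted.
* All-zero rate vectors: `normalize_to_max` and the SI error rather than
  return NaN; zero-variance stimuli are named in the DM error.
* Coherence values are clamped only by the Cauchy-Schwarz identity (tested
  to 1e-9); frequency bins without power return `NA`.
* GC values are clamped at 0 against `-ln(1+eps)` rounding; a singular
  transfer-matrix inversion reports the offending frequency.
* Every stochastic routine takes an explicit integer seed and is a pure
  function of its arguments; derived per-unit seeds stay below $2^{31}$.

## Problem sizes in the test-suite

The packaged tests run the calibration suite at 500 null units x 200
permutation runs, and the end-to-end recovery suite on 20 simulated
sessions under the default configuration (these sizes are the package's
own desk-scale choices; the procedures themselves scale to arbitrary
session counts). Qualitative axis-versus-non-axis comparisons (attention
index, late-window distance contrast, theta desynchronisation) are
asserted as paired tests across the 20 sessions at p < 0.05.

## Known limitations

* The simulator's fixation sequence is a stand-in: real search obeys
  saliency, inhibition-of-return and return-fixation statistics that are
  not modelled (the task imposes no constraints, but monkeys do).
* Receptive-field classes other than focal-foveal are implemented from
  search-task responses only; there is no saccade-task mapping in the
  synthetic sessions.
* The spike-to-continuous convention for Granger causality (binned counts)
  and the VAR order policy are stated conventions; results at theta are
  insensitive to the order cap in simulation, but no claim is made for
  real data.
* Coherence comparisons assume the equal-fixation/equal-spike rule removes
  sample-size bias; residual bias from rate differences within segments is
  not corrected.
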