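# fixsearch

Analysis of how visual feature coding interacts with attentional modulation
in fixation-aligned primate electrophysiology, for researchers working with
spike and local field potential (LFP) recordings from free-gaze visual
search tasks — and for anyone who wants a fully testable, simulation-backed
implementation of that analysis chain.

During free-gaze search, every fixation is a trial. A unit is
**axis-coding** when its firing rate is a (near-)linear function of the
fixated stimulus's position in a high-dimensional visual feature space
(e.g. deep-network embeddings): `r(s) ≈ w · x_s + b`. Because the feature
dimension `D` (default 512) exceeds the number of stimuli, the encoding
model is fitted with partial least squares (PLS, 4 components) and judged
by a split-and-permute test: over `n_perm` runs, a random 50/50
stimulus split is drawn and the held-out prediction correlation is computed
with true and with shuffled labels; the unit is flagged when the observed
correlation exceeds the 95th percentile of the null distribution, and the
observed correlation is the *strength* of axis coding.

Around that core the package implements:

* **Unit screening** — visual responsiveness (rank-sum vs baseline),
  receptive-field class, category selectivity via
  `SI = (R_face − R_house)/(R_face + R_house)` with sign clamps and the
  ±0.13 threshold, and attention selectivity (late-window signed-rank over
  per-stimulus target/distractor pairs) with the attention index
  `(FR_T − FR_D)/(FR_T + FR_D)`.
* **Representational geometry** — dissimilarity matrices (`1 − r`),
  Spearman DM correspondence with permutation nulls, and pairwise
  Euclidean distances / cosine angles between population vectors,
  contrasted target vs distractor in early (50–150 ms) and late
  (150–225 ms) windows.
* **Spike–LFP coherence** — `C_xy(f) = |S_xy| / sqrt(S_x S_y)` over 200 ms
  fixation windows (single Hanning taper, spectra averaged across
  fixations, cross-electrode pairs only), with fixation *and* spike counts
  equalised between conditions before comparison; theta-band (4–12 Hz)
  desynchronisation index `(C_D − C_T)/(C_D + C_T)`.
* **Spectral Granger causality** — detrended, ensemble-demeaned,
  KPSS-screened segments; pooled bivariate VAR (AIC order selection);
  `G_{j→i}(f) = −ln(1 − (Σ_jj − Σ_ij²/Σ_ii)|H_ij(f)|²/S_ii(f))`, checked
  against a time-domain Geweke oracle.
* **A synthetic-session simulator** with planted ground truth (axis units,
  attentional gain, condition-dependent theta spike–field coupling), so
  every stage is testable without any recordings.

See `vignettes/fixsearch-methods.Rmd` for the full model description and
design rationale.

## Worked example

```r
library(fixsearch)

cfg <- synthetic_config(n_units = c(V4 = 4, TEO = 4, TE = 4, OFC = 4),
                        n_trials = 120, seed = 7)
stimuli <- generate_stimulus_features(seed = 7)
truth   <- generate_unit_population(cfg, stimuli)
session <- generate_session(cfg, stimuli, truth)
session
#> <session> 120 trials, 16 units, 8 LFP channels @ 1000 Hz, 578 s

# axis-coding test for one unit: early-window rates on distractor fixations
frm   <- fixation_rate_matrix(session, rate_window("feature"))
rates <- stimulus_rate_matrix(frm, is_target = FALSE,
                              stimulus_ids = stimuli$stimulus_id)
keep  <- rowSums(is.na(rates)) == 0
fit   <- axis_permutation_test(stimuli$features[keep, ], rates[keep, 1],
                               n_perm = 200, seed = 7)
#> unit 1: planted axis = TRUE, flagged = TRUE, strength = 0.29, perm p = 0.010

# theta spike-LFP desynchronisation for the same unit (cross-electrode)
cp <- coherence_pair(session, unit_id = 1, channel_id = 2, seed = 7)
#> theta coherence: distractor 0.383, target 0.127, desync index 0.50
```

The unit was planted as axis-coding and is recovered (held-out prediction
correlation 0.29, above the null's 95th percentile, permutation p = 0.01);
its spike–LFP coherence in the theta band drops from 0.383 on distractor
fixations to 0.127 on target fixations — the planted target-induced
desynchronisation, summarised by a positive index of 0.50.

## The analysis workflow

`analysis/` contains numbered drivers that run the full study on one
simulated session, writing tables under `results/`:

```sh
Rscript analysis/01_simulate_session.R   # session + ground truth on disk
Rscript analysis/02_screen_units.R       # responsiveness, RF, SI, attention
Rscript analysis/03_axis_model.R         # PLS + permutation axis screen
Rscript analysis/04_geometry.R           # distances, angles, RSA, PCA map
Rscript analysis/05_coherence.R          # theta desynchronisation by class
Rscript analysis/06_granger.R            # directed spike-LFP contrasts
Rscript analysis/07_report.R             # group stats + recovery scorecard
```

On the default conditions this recovers the planted structure end to end,
e.g. axis detection sensitivity 0.83 / specificity 0.96; a stronger theta
desynchronisation for axis-coding than non-axis units (0.435 vs 0.165,
t ≈ 6.9); axis-population representational structure matching the feature
space (Spearman rho 0.14, permutation p < 0.001) while the non-axis
population does not (p = 0.10).

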