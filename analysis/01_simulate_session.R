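#!/usr/bin/env Rscript
# Simulate one synthetic recording session under the default study
# conditions and store it in the plain-file session layout.
#
# The session carries planted ground truth: half the units in each area are
# axis-coding (rates linear in the stimulus features through a softplus
# link), every unit gains on target fixations in the late window (axis
# units more), and spikes phase-lock to the area's theta oscillation more
# strongly on distractor than on target fixations (axis units drop more).

library(fixsearch)

seed <- 20260920L
out <- "results/session"

cfg <- synthetic_config(seed = seed)
stimuli <- generate_stimulus_features(cfg$n_stimuli_per_category, cfg$D,
                                      seed = seed)
truth <- generate_unit_population(cfg, stimuli, seed = seed + 1L)
session <- generate_session(cfg, stimuli, truth, seed = seed + 2L)

write_session(session, out, stimuli = stimuli, truth = truth)

n_fix <- sum(session$events$event_type == "fixation")
cat("Wrote", out, "\n")
cat(sprintf("%d trials, %d fixations (%d on targets), %d units, %d LFP channels, %.0f s\n",
            cfg$n_trials, n_fix,
            sum(session$events$is_target %in% TRUE),
            length(session$units), length(session$lfp),
            session$duration_ms / 1000))
cat(sprintf("planted axis-coding units: %d of %d\n",
            sum(truth$units$is_axis), nrow(truth$units)))
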