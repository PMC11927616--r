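#!/usr/bin/env Rscript
# Screen every unit of the simulated session: visual responsiveness
# (cue/array vs baseline rank-sum), receptive-field class, category
# selectivity (SI with its clamps and the 0.13 threshold), and attention
# selectivity (late-window signed-rank over per-stimulus target/distractor
# pairs, with the attention index).

library(fixsearch)

session <- read_session("results/session")
stimuli <- attr(session, "stimuli")

screen <- screen_units(session, stimuli)
dir.create("results/analysis", recursive = TRUE, showWarnings = FALSE)
write.csv(screen, "results/analysis/unit_screen.csv", row.names = FALSE)

cat(sprintf("visually responsive: %d/%d\n",
            sum(screen$visually_responsive), nrow(screen)))
cat("RF classes:\n"); print(table(screen$rf_class))
cat("category classes:\n"); print(table(screen$category_class))
cat(sprintf("attention-selective: %d/%d, mean attention index %.3f\n",
            sum(screen$attention_selective %in% TRUE), nrow(screen),
            mean(screen$attention_index, na.rm = TRUE)))
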