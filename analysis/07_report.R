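#!/usr/bin/env Rscript
# Group-level statistics and the ground-truth recovery scorecard.

library(fixsearch)

screen <- read.csv("results/analysis/unit_screen.csv")
axis <- read.csv("results/analysis/axis_fits.csv")
truth <- read.csv("results/session/ground_truth.csv")

gs <- group_comparison_stats(screen, axis)
write.csv(gs$binomial_by_area, "results/analysis/binomial_by_area.csv",
          row.names = FALSE)
write.csv(gs$enrichment, "results/analysis/enrichment.csv",
          row.names = FALSE)

cat("flagged proportions per area (binomial test vs 5% chance):\n")
print(gs$binomial_by_area)
cat(sprintf("\nareas differ in axis proportion: chi2(%d) = %.2f, p = %.2g\n",
            gs$area_chisq$df, gs$area_chisq$chisq, gs$area_chisq$p))
cat(sprintf("attention index, axis vs non-axis: t(%d) = %.2f, p = %.2g\n",
            gs$attention_by_class$df, gs$attention_by_class$t,
            gs$attention_by_class$p))

planted <- truth$is_axis[match(as.integer(axis$unit_id), truth$unit_id)]
scorecard <- data.frame(
  metric = c("axis_sensitivity", "axis_specificity",
             "mean_attention_index"),
  value = c(mean(axis$is_axis[planted]), mean(!axis$is_axis[!planted]),
            mean(screen$attention_index, na.rm = TRUE))
)
write.csv(scorecard, "results/analysis/scorecard.csv", row.names = FALSE)
cat("\nground-truth recovery scorecard:\n")
print(scorecard)
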