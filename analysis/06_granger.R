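#!/usr/bin/env Rscript
# Frequency-domain Granger causality between spikes and LFPs per condition
# (detrend + ensemble demean + KPSS screening + pooled bivariate VAR), and
# the theta-band target-induced reduction (GC_D - GC_T)/(GC_D + GC_T) per
# direction, compared between axis-coding and non-axis-coding units.

library(fixsearch)

session <- read_session("results/session")
axis <- read.csv("results/analysis/axis_fits.csv")

rows <- list()
for (u in session$units) {
  ch <- NULL
  for (c0 in session$lfp) {
    if (c0$area == u$area && c0$electrode_id != u$electrode_id) {
      ch <- c0; break
    }
  }
  if (is.null(ch)) next
  gp <- tryCatch(granger_pair(session, u$unit_id, ch$channel_id),
                 error = function(e) NULL)
  if (is.null(gp)) next
  rows[[length(rows) + 1L]] <- data.frame(
    spike_unit = u$unit_id, lfp_channel = ch$channel_id, area = u$area,
    is_axis = axis$is_axis[match(u$unit_id, axis$unit_id)],
    gc_spike_to_lfp_contrast = gp$contrast$x_to_y,
    gc_lfp_to_spike_contrast = gp$contrast$y_to_x,
    n_excluded_target = gp$n_excluded["target"],
    n_excluded_distractor = gp$n_excluded["distractor"]
  )
}
gc <- do.call(rbind, rows)
write.csv(gc, "results/analysis/granger.csv", row.names = FALSE)

cat(sprintf("spike-LFP pairs analysed: %d\n", nrow(gc)))
for (dir in c("gc_spike_to_lfp_contrast", "gc_lfp_to_spike_contrast")) {
  cat(sprintf("%s: axis %.3f, non-axis %.3f\n", dir,
              mean(gc[[dir]][gc$is_axis]), mean(gc[[dir]][!gc$is_axis])))
}
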