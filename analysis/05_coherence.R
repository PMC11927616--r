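#!/usr/bin/env Rscript
# Fixation-windowed spike-LFP coherence with condition equalisation.
# For each unit paired with a same-area LFP channel on a different
# electrode: target and distractor coherence spectra (0-200 ms windows,
# Hanning taper, fixation and spike counts equalised over 20 subsamples)
# and the theta-band desynchronisation index (C_D - C_T)/(C_D + C_T).

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
  cp <- tryCatch(
    coherence_pair(session, u$unit_id, ch$channel_id,
                   seed = 20260925L + u$unit_id),
    error = function(e) NULL
  )
  if (is.null(cp)) next
  rows[[length(rows) + 1L]] <- data.frame(
    spike_unit = u$unit_id, lfp_channel = ch$channel_id, area = u$area,
    is_axis = axis$is_axis[match(u$unit_id, axis$unit_id)],
    theta_distractor = cp$theta_distractor,
    theta_target = cp$theta_target,
    desync_index = cp$desync_index,
    n_fix = cp$n_fix, n_spikes = cp$n_spikes
  )
}
coh <- do.call(rbind, rows)
write.csv(coh, "results/analysis/coherence.csv", row.names = FALSE)

cat(sprintf("spike-LFP pairs analysed: %d\n", nrow(coh)))
cat(sprintf("theta desynchronisation index: axis %.3f, non-axis %.3f\n",
            mean(coh$desync_index[coh$is_axis]),
            mean(coh$desync_index[!coh$is_axis])))
tt <- t.test(coh$desync_index[coh$is_axis],
             coh$desync_index[!coh$is_axis])
cat(sprintf("axis vs non-axis: t(%.1f) = %.2f, p = %.2g\n",
            tt$parameter, tt$statistic, tt$p.value))
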