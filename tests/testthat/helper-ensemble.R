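# Ensemble of complete simulated sessions under the default study
# conditions, analysed end to end. Built once and memoised; only compact
# per-session summaries are kept.

E2E_N_SESSIONS <- 20L

e2e_ensemble <- function() {
  memo("e2e_ensemble", function() {
    lapply(seq_len(E2E_N_SESSIONS), function(k) {
      out <- file.path(tempdir(), sprintf("e2e_%02d", k))
      res <- run_pipeline(
        synthetic_config(), out, seed = 5000L + 37L * k, n_perm = 200,
        stages = c("screen", "axis", "geometry", "coherence")
      )
      truth_ax <- res$truth$units$is_axis[
        match(as.integer(res$axis$unit_id), res$truth$units$unit_id)]
      m <- merge(res$screen, res$axis[, c("unit_id", "is_axis")],
                 by = "unit_id")
      g <- res$geometry
      late <- g[g$window == "late", ]
      co <- res$coherence
      unlink(out, recursive = TRUE)
      list(
        truth_axis = truth_ax,
        detected_axis = res$axis$is_axis,
        att_index = m$attention_index,
        att_is_axis = m$is_axis,
        att_axis = mean(m$attention_index[m$is_axis], na.rm = TRUE),
        att_nonaxis = mean(m$attention_index[!m$is_axis], na.rm = TRUE),
        dist_contrast_axis =
          late$mean_distance_contrast[late$unit_class == "axis"],
        dist_contrast_nonaxis =
          late$mean_distance_contrast[late$unit_class == "nonaxis"],
        desync_all = mean(co$desync_index),
        desync_axis = mean(co$desync_index[co$is_axis %in% TRUE]),
        desync_nonaxis = mean(co$desync_index[co$is_axis %in% FALSE])
      )
    })
  })
}
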