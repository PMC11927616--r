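#!/usr/bin/env Rscript
# Representational geometry and RSA. Per window (early/late) and unit
# class (all / detected axis / non-axis): pairwise Euclidean distances and
# angles between population vectors for stimuli fixated in both roles,
# contrasted target vs distractor. Plus the dissimilarity-matrix
# correspondence of the axis-coding (and, as a null case, non-axis)
# population with the stimulus feature space.

library(fixsearch)

session <- read_session("results/session")
stimuli <- attr(session, "stimuli")
axis <- read.csv("results/analysis/axis_fits.csv")

geo <- geometry_stage(session, stimuli, axis)
write.csv(geo, "results/analysis/geometry.csv", row.names = FALSE)
cat("late-window geometry contrasts by unit class:\n")
print(geo[geo$window == "late",
          c("unit_class", "n_units", "mean_distance_contrast",
            "mean_angle_contrast", "distance_t", "distance_df")])

# RSA: does the axis-coding population share representational structure
# with the stimulus feature space? (Non-axis population as the null case.)
frm <- fixation_rate_matrix(session, rate_window("feature"))
rates <- stimulus_rate_matrix(frm, FALSE, stimuli$stimulus_id)
keep <- rowSums(is.na(rates)) == 0
R <- t(rates[keep, ])
ax <- axis$is_axis[match(rownames(R), axis$unit_id)]
dm_feat <- dissimilarity_matrix(t(stimuli$features[keep, ]))
dm_axis <- dissimilarity_matrix(R[ax, , drop = FALSE])
dm_non <- dissimilarity_matrix(R[!ax, , drop = FALSE])
rsa_ax <- rsa_correspondence(dm_axis, dm_feat, n_perm = 1000,
                             seed = 20260924L)
rsa_nx <- rsa_correspondence(dm_non, dm_feat, n_perm = 1000,
                             seed = 20260926L)
rsa <- data.frame(
  pair = c("axis_vs_features", "nonaxis_vs_features"),
  spearman_rho = c(rsa_ax$spearman_rho, rsa_nx$spearman_rho),
  p_perm = c(rsa_ax$p_perm, rsa_nx$p_perm),
  p_bonferroni = pmin(1, 2 * c(rsa_ax$p_perm, rsa_nx$p_perm))
)
write.csv(rsa, "results/analysis/rsa.csv", row.names = FALSE)
cat("\nDM correspondence with the feature space:\n")
print(rsa)

# 2-D embedding of the stimuli in neural state space, for the report
emb <- pca_embedding(R, 2)
write.csv(data.frame(stimulus_id = as.integer(colnames(R)),
                     category = as.character(
                       stimuli$category[match(as.integer(colnames(R)),
                                              stimuli$stimulus_id)]),
                     pc1 = emb[, 1], pc2 = emb[, 2]),
          "results/analysis/pca_embedding.csv", row.names = FALSE)
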