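#' Run the full analysis pipeline on a synthetic or stored session
#'
#' Orchestrates simulate -> screen -> axis -> geometry -> coherence ->
#' granger -> report. Every stage writes a CSV table into `out_dir`; a
#' `manifest.csv` records the seed and a hash of the configuration so that
#' reruns are reproducible (deterministic stages are byte-identical given
#' the same config and seed). A stage failure halts with the stage name;
#' tables already written are retained.
#'
#' @param config A [synthetic_config()], or a path to a session directory
#'   written by [write_session()] (which must include `features.csv`).
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @param n_perm Permutation runs for the axis and RSA tests (default 200
#'   at session scale).
#' @param stages Character subset of
#'   `c("screen", "axis", "geometry", "coherence", "granger")`.
#' @param coherence_pairs,granger_pairs Maximum number of spike-LFP pairs
#'   analysed per stage (units paired with a same-area, different-electrode
#'   channel; default 16 and 8).
#' @return Invisibly, a list with the stage tables and the report.
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir, seed = 1,
                         n_perm = 200,
                         stages = c("screen", "axis", "geometry",
                                    "coherence", "granger"),
                         coherence_pairs = 16, granger_pairs = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.character(config)) {
    session <- read_session(config)
    stimuli <- attr(session, "stimuli")
    if (is.null(stimuli)) {
      stop("stage simulate: features.csv not found in ", config,
           call. = FALSE)
    }
    cfg_for_hash <- list(path = config)
  } else {
    stimuli <- generate_stimulus_features(config$n_stimuli_per_category,
                                          config$D, seed = seed)
    truth <- generate_unit_population(config, stimuli, seed = seed + 1L)
    session <- generate_session(config, stimuli, truth, seed = seed + 2L)
    if (!is.null(truth)) {
      utils::write.csv(truth$units, file.path(out_dir, "ground_truth.csv"),
                       row.names = FALSE)
    }
    cfg_for_hash <- unclass(config)
  }
  manifest <- data.frame(
    key = c("seed", "config_hash", "r_version"),
    value = c(seed, config_hash(cfg_for_hash),
              paste(R.version$major, R.version$minor, sep = ".")),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  res <- list(truth = truth)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if ("screen" %in% stages) {
    res$screen <- run_stage("screen", screen_units(session, stimuli))
    utils::write.csv(res$screen, file.path(out_dir, "unit_screen.csv"),
                     row.names = FALSE)
  }
  if ("axis" %in% stages) {
    res$axis <- run_stage("axis", {
      frm <- fixation_rate_matrix(session, rate_window("feature"))
      sm <- stimulus_rate_matrix(frm, FALSE, stimuli$stimulus_id)
      keep <- rowSums(is.na(sm)) == 0
      axis_screen_population(t(sm[keep, , drop = FALSE]),
                             stimuli$features[keep, , drop = FALSE],
                             n_perm = n_perm, seed = seed + 3L)
    })
    utils::write.csv(res$axis, file.path(out_dir, "axis_fits.csv"),
                     row.names = FALSE)
  }
  if ("geometry" %in% stages) {
    res$geometry <- run_stage("geometry",
                              geometry_stage(session, stimuli, res$axis))
    utils::write.csv(res$geometry, file.path(out_dir, "geometry.csv"),
                     row.names = FALSE)
  }
  if ("coherence" %in% stages) {
    res$coherence <- run_stage("coherence",
      pairwise_stage(session, res$axis, coherence_pairs, seed + 4L,
                     function(s, u, ch, sd) {
                       cp <- coherence_pair(s, u, ch, seed = sd)
                       data.frame(theta_target = cp$theta_target,
                                  theta_distractor = cp$theta_distractor,
                                  desync_index = cp$desync_index,
                                  n_fix = cp$n_fix, n_spikes = cp$n_spikes)
                     }))
    if (!is.null(res$coherence)) {
      utils::write.csv(res$coherence, file.path(out_dir, "coherence.csv"),
                       row.names = FALSE)
    }
  }
  if ("granger" %in% stages) {
    res$granger <- run_stage("granger",
      pairwise_stage(session, res$axis, granger_pairs, seed + 5L,
                     function(s, u, ch, sd) {
                       gp <- granger_pair(s, u, ch)
                       data.frame(
                         gc_spike_to_lfp_contrast = gp$contrast$x_to_y,
                         gc_lfp_to_spike_contrast = gp$contrast$y_to_x)
                     }))
    if (!is.null(res$granger)) {
      utils::write.csv(res$granger, file.path(out_dir, "granger.csv"),
                       row.names = FALSE)
    }
  }
  res$report <- build_report(res)
  utils::write.csv(res$report$summary, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  invisible(res)
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f)
  unname(tools::md5sum(f))
}

#' Session-level geometry summaries by window and unit class
#'
#' For each window (early/late) and unit class (all units, detected
#' axis-coding, non-axis), computes target-vs-distractor population
#' geometry over the stimuli fixated in both roles: per-pair distance and
#' angle contrasts with their paired t tests.
#'
#' @param session A `session`.
#' @param stimuli The session's `stimulus_set`.
#' @param axis_fits Output of [axis_screen_population()], or `NULL` to
#'   summarise all units together.
#' @return data.frame, one row per window x unit class (the
#'   `geometry.csv` layout).
#' @export
geometry_stage <- function(session, stimuli, axis_fits = NULL) {
  rows <- list()
  for (win in c("feature", "attention")) {
    wname <- if (win == "feature") "early" else "late"
    frm <- fixation_rate_matrix(session, rate_window(win))
    st <- stimulus_rate_matrix(frm, TRUE, stimuli$stimulus_id)
    sd_ <- stimulus_rate_matrix(frm, FALSE, stimuli$stimulus_id)
    ok <- rowSums(is.na(st)) == 0 & rowSums(is.na(sd_)) == 0
    rt <- t(st[ok, , drop = FALSE])
    rd <- t(sd_[ok, , drop = FALSE])
    classes <- list(all = rep(TRUE, nrow(rt)))
    if (!is.null(axis_fits)) {
      ax <- axis_fits$is_axis[match(rownames(rt), axis_fits$unit_id)]
      ax[is.na(ax)] <- FALSE
      if (sum(ax) >= 2) classes$axis <- ax
      if (sum(!ax) >= 2) classes$nonaxis <- !ax
    }
    for (cl in names(classes)) {
      sel <- classes[[cl]]
      geo <- population_geometry(rt[sel, , drop = FALSE],
                                 rd[sel, , drop = FALSE], wname)
      con <- geometry_contrast(geo$target, geo$distractor)
      rows[[length(rows) + 1L]] <- data.frame(
        window = wname, unit_class = cl, n_units = sum(sel),
        n_pairs = length(con$distance_contrast),
        mean_distance_contrast = mean(con$distance_contrast, na.rm = TRUE),
        mean_angle_contrast = mean(con$angle_contrast, na.rm = TRUE),
        distance_t = con$distance_test$t, distance_df = con$distance_test$df,
        distance_p = con$distance_test$p,
        angle_t = con$angle_test$t, angle_df = con$angle_test$df,
        angle_p = con$angle_test$p
      )
    }
  }
  do.call(rbind, rows)
}

# Shared machinery for the coherence and granger stages: pair each unit
# with a same-area channel on a different electrode, run `fun`, bind rows.
pairwise_stage <- function(session, axis_fits, max_pairs, seed, fun) {
  ch_by_area <- split(session$lfp,
                      vapply(session$lfp, `[[`, "", "area"))
  rows <- list()
  for (u in session$units) {
    if (length(rows) >= max_pairs) break
    chs <- ch_by_area[[u$area]]
    ch <- NULL
    for (c0 in chs) if (c0$electrode_id != u$electrode_id) { ch <- c0; break }
    if (is.null(ch)) next
    is_axis <- if (!is.null(axis_fits)) {
      a <- axis_fits$is_axis[match(as.character(u$unit_id),
                                   axis_fits$unit_id)]
      !is.na(a) && a
    } else NA
    out <- tryCatch(
      fun(session, u$unit_id, ch$channel_id, seed + u$unit_id),
      error = function(e) NULL
    )
    if (is.null(out)) next
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(spike_unit = u$unit_id, lfp_channel = ch$channel_id,
                 area = u$area, is_axis = is_axis),
      out
    )
  }
  do.call(rbind, rows)
}

#' Group-level statistics across units and areas
#'
#' The population-level tests reported alongside the unit screens: a
#' binomial test per area of the flagged-unit proportion against the
#' chance rate (the selection alpha, 0.05), a chi-squared test of
#' proportion differences between areas, a two-sample t test of the
#' attentional effect (attention index) between axis-coding and
#' non-axis-coding units, and a chi-squared enrichment test of attention
#' selectivity within axis-coding units (Bonferroni-corrected across
#' areas).
#'
#' @param unit_table Output of [screen_units()].
#' @param axis_fits Output of [axis_screen_population()] (matched by
#'   `unit_id`).
#' @param alpha Selection level and chance rate (default 0.05).
#' @return List of data.frames: `binomial_by_area`, `area_chisq`,
#'   `attention_by_class`, `enrichment`.
#' @export
group_comparison_stats <- function(unit_table, axis_fits, alpha = 0.05) {
  ut <- merge(unit_table,
              axis_fits[, c("unit_id", "is_axis", "strength")],
              by = "unit_id", all.x = TRUE)
  ut$is_axis[is.na(ut$is_axis)] <- FALSE
  areas <- sort(unique(ut$area))
  if (length(areas) < 2L || nrow(ut) < 4L) {
    stop("insufficient data: need >= 2 areas with >= 2 units",
         call. = FALSE)
  }
  binom_rows <- lapply(areas, function(a) {
    sub <- ut[ut$area == a, ]
    for_test <- list(
      axis = sum(sub$is_axis),
      attention = sum(sub$attention_selective %in% TRUE)
    )
    do.call(rbind, lapply(names(for_test), function(what) {
      k <- for_test[[what]]
      n <- nrow(sub)
      bt <- stats::binom.test(k, n, p = alpha, alternative = "greater")
      data.frame(area = a, flag = what, n_flagged = k, n_units = n,
                 proportion = k / n, p_binomial = bt$p.value)
    }))
  })
  binomial_by_area <- do.call(rbind, binom_rows)
  tab <- table(ut$area, ut$is_axis)
  area_chisq <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  att <- ut[!is.na(ut$attention_index), ]
  ax_att <- att$attention_index[att$is_axis]
  nx_att <- att$attention_index[!att$is_axis]
  att_test <- if (length(ax_att) >= 2 && length(nx_att) >= 2) {
    tt <- stats::t.test(ax_att, nx_att, var.equal = TRUE)
    data.frame(mean_axis = mean(ax_att), mean_nonaxis = mean(nx_att),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  } else {
    data.frame(mean_axis = NA_real_, mean_nonaxis = NA_real_,
               t = NA_real_, df = NA_real_, p = NA_real_)
  }
  enr_rows <- lapply(areas, function(a) {
    sub <- ut[ut$area == a & !is.na(ut$attention_selective), ]
    t2 <- table(factor(sub$is_axis, c(FALSE, TRUE)),
                factor(sub$attention_selective %in% TRUE, c(FALSE, TRUE)))
    p <- if (all(dim(t2) == 2) && all(rowSums(t2) > 0)) {
      suppressWarnings(stats::chisq.test(t2, correct = FALSE)$p.value)
    } else NA_real_
    data.frame(area = a, p_chisq = p)
  })
  enrichment <- do.call(rbind, enr_rows)
  enrichment$p_bonferroni <- pmin(1, enrichment$p_chisq *
                                    sum(!is.na(enrichment$p_chisq)))
  list(
    binomial_by_area = binomial_by_area,
    area_chisq = data.frame(chisq = unname(area_chisq$statistic),
                            df = unname(area_chisq$parameter),
                            p = area_chisq$p.value),
    attention_by_class = att_test,
    enrichment = enrichment
  )
}

#' Assemble a summary report from pipeline stage outputs
#'
#' One summary row per analysis family (axis-coding proportions per area,
#' attentional effect by unit class, geometry contrasts by window, theta
#' desynchronisation and Granger contrasts by unit class) plus a
#' ground-truth recovery scorecard for synthetic runs. Missing stages are
#' listed as skipped, not fatal.
#'
#' @param res List of stage outputs as assembled by [run_pipeline()].
#' @return List: `summary` (data.frame), `skipped` (character),
#'   `scorecard` (data.frame or `NULL`).
#' @export
build_report <- function(res) {
  rows <- list()
  skipped <- character()
  add <- function(family, metric, value) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, metric = metric, value = value)
  }
  if (!is.null(res$axis)) {
    add("axis", "prop_flagged", mean(res$axis$is_axis))
    add("axis", "median_strength", stats::median(res$axis$strength))
  } else skipped <- c(skipped, "axis")
  if (!is.null(res$screen)) {
    add("screen", "prop_visually_responsive",
        mean(res$screen$visually_responsive))
    add("screen", "prop_attention_selective",
        mean(res$screen$attention_selective %in% TRUE))
    if (!is.null(res$axis)) {
      m <- merge(res$screen, res$axis[, c("unit_id", "is_axis")],
                 by = "unit_id")
      for (cl in c(TRUE, FALSE)) {
        v <- m$attention_index[m$is_axis == cl & !is.na(m$attention_index)]
        add("attention", paste0("mean_index_",
                                if (cl) "axis" else "nonaxis"),
            if (length(v)) mean(v) else NA_real_)
      }
    }
  } else skipped <- c(skipped, "screen")
  if (!is.null(res$geometry)) {
    g <- res$geometry
    for (i in seq_len(nrow(g))) {
      add("geometry",
          paste("distance_contrast", g$window[i], g$unit_class[i],
                sep = "_"),
          g$mean_distance_contrast[i])
    }
  } else skipped <- c(skipped, "geometry")
  if (!is.null(res$coherence)) {
    for (cl in c(TRUE, FALSE)) {
      v <- res$coherence$desync_index[res$coherence$is_axis %in% cl]
      add("coherence", paste0("mean_desync_",
                              if (cl) "axis" else "nonaxis"),
          if (length(v)) mean(v) else NA_real_)
    }
  } else skipped <- c(skipped, "coherence")
  if (!is.null(res$granger)) {
    for (cl in c(TRUE, FALSE)) {
      v <- res$granger$gc_spike_to_lfp_contrast[
        res$granger$is_axis %in% cl]
      add("granger", paste0("mean_spike_to_lfp_contrast_",
                            if (cl) "axis" else "nonaxis"),
          if (length(v)) mean(v) else NA_real_)
    }
  } else skipped <- c(skipped, "granger")
  scorecard <- NULL
  if (!is.null(res$truth) && !is.null(res$axis)) {
    truth_ax <- res$truth$units$is_axis[
      match(as.integer(res$axis$unit_id), res$truth$units$unit_id)]
    sens <- if (any(truth_ax)) mean(res$axis$is_axis[truth_ax]) else NA
    spec <- if (any(!truth_ax)) mean(!res$axis$is_axis[!truth_ax]) else NA
    scorecard <- data.frame(metric = c("axis_sensitivity",
                                       "axis_specificity"),
                            value = c(sens, spec))
  }
  list(summary = do.call(rbind, rows), skipped = skipped,
       scorecard = scorecard)
}
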