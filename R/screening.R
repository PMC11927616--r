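#' Test for a visually evoked response
#'
#' A unit counts as visually responsive when its response to the cue or to
#' the search array is significantly greater than its baseline activity
#' (one-sided Wilcoxon rank-sum test at p < 0.05 for either comparison).
#'
#' @param cue_rates,array_rates,baseline_rates Numeric vectors of per-trial
#'   rates (spikes/s), at least 5 observations each.
#' @return List: `flag`, `p_cue`, `p_array`.
#' @export
assess_visual_responsiveness <- function(cue_rates, array_rates,
                                         baseline_rates) {
  ns <- c(length(cue_rates), length(array_rates), length(baseline_rates))
  if (any(ns < 5L)) {
    stop("insufficient data: need at least 5 observations per sample",
         call. = FALSE)
  }
  p_cue <- ranksum_greater(cue_rates, baseline_rates)
  p_array <- ranksum_greater(array_rates, baseline_rates)
  list(flag = (p_cue < 0.05) || (p_array < 0.05),
       p_cue = p_cue, p_array = p_array)
}

ranksum_greater <- function(x, y) {
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
  )
}

#' Classify a unit's receptive field from its cue and array responses
#'
#' Focal foveal: responds to the (foveated) cue but not to the search array
#' in the periphery; broad foveal: responds to both; peripheral: responds
#' only to the array; otherwise unclassified.
#'
#' @param cue_response_p,array_response_p p-values from
#'   [assess_visual_responsiveness()].
#' @return One of `"focal_foveal"`, `"broad_foveal"`, `"peripheral"`,
#'   `"unclassified"`.
#' @export
classify_rf <- function(cue_response_p, array_response_p) {
  cue <- cue_response_p < 0.05
  arr <- array_response_p < 0.05
  if (cue && !arr) "focal_foveal"
  else if (cue && arr) "broad_foveal"
  else if (!cue && arr) "peripheral"
  else "unclassified"
}

#' Category selectivity index
#'
#' `SI = (R_face - R_house) / (R_face + R_house)` on baseline-subtracted
#' responses, with sign clamps for mixed-sign inputs: SI is set to 1 when
#' `R_face > 0` and `R_house < 0`, and to -1 when `R_face < 0` and
#' `R_house > 0`; otherwise the formula value is clipped into `[-1, 1]`.
#' The face-selective criterion `R_face >= 130% of R_house` corresponds to
#' SI > 0.13.
#'
#' @param R_face,R_house Baseline-subtracted responses, spikes/s.
#' @return SI in `[-1, 1]`.
#' @export
#' @examples
#' category_selectivity_index(1.3, 1.0)  # 0.1304
#' category_selectivity_index(2, -1)     # clamped to 1
category_selectivity_index <- function(R_face, R_house) {
  if (R_face == 0 && R_house == 0) {
    stop("undefined SI: both responses are zero", call. = FALSE)
  }
  if (R_face > 0 && R_house < 0) return(1)
  if (R_face < 0 && R_house > 0) return(-1)
  si <- (R_face - R_house) / (R_face + R_house)
  max(-1, min(1, si))
}

#' Classify category selectivity from face- and house-cue responses
#'
#' Face-selective: rank-sum p < 0.05 and SI > 0.13; house-selective:
#' p < 0.05 and SI < -0.13; nonselective: p >= 0.05; undefined: significant
#' difference but SI within the threshold band.
#'
#' @param face_rates,house_rates Baseline-subtracted per-trial responses
#'   (spikes/s), at least 5 each.
#' @return List: `class` in face/house/nonselective/undefined, `p`, `SI`.
#' @export
classify_category <- function(face_rates, house_rates) {
  if (length(face_rates) < 5L || length(house_rates) < 5L) {
    stop("insufficient data: need at least 5 responses per category",
         call. = FALSE)
  }
  p <- suppressWarnings(
    stats::wilcox.test(face_rates, house_rates, exact = FALSE)$p.value
  )
  si <- category_selectivity_index(mean(face_rates), mean(house_rates))
  cls <- if (p >= 0.05) "nonselective"
  else if (si > 0.13) "face"
  else if (si < -0.13) "house"
  else "undefined"
  list(class = cls, p = p, SI = si)
}

#' Attention selectivity from paired target/distractor responses
#'
#' Pairs responses per stimulus (the mean rate when the stimulus was
#' fixated as a target vs as a distractor), applies a two-tailed Wilcoxon
#' signed-rank test at p < 0.05, and computes the attention index
#' `(FR_target - FR_distractor) / (FR_target + FR_distractor)` from the
#' condition means. Responses are taken in the late (150-225 ms) window by
#' the session-level screen.
#'
#' @param target_rates,distractor_rates Numeric vectors aligned by
#'   stimulus; at least 6 stimuli fixated in both roles.
#' @return List: `flag`, `p`, `attention_index`.
#' @export
detect_attention_selectivity <- function(target_rates, distractor_rates) {
  if (length(target_rates) != length(distractor_rates)) {
    stop("target/distractor rate vectors must be aligned by stimulus",
         call. = FALSE)
  }
  if (length(target_rates) < 6L) {
    stop("insufficient data: need at least 6 stimuli fixated in both roles",
         call. = FALSE)
  }
  d <- target_rates - distractor_rates
  if (all(d == 0)) {
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(target_rates, distractor_rates, paired = TRUE,
                         exact = FALSE)$p.value
    )
  }
  mt <- mean(target_rates)
  md <- mean(distractor_rates)
  idx <- if (mt + md == 0) 0 else normalized_contrast(mt, md)
  list(flag = p < 0.05, p = p, attention_index = idx)
}

# --- session-level screen -------------------------------------------------

# Spike counts in [starts, ends) per window, via two binary searches on the
# sorted spike train.
count_in_windows <- function(spike_times, starts, ends) {
  findInterval(ends, spike_times, left.open = TRUE) -
    findInterval(starts, spike_times, left.open = TRUE)
}

#' Per-fixation firing rates for every unit
#'
#' @param session A `session`.
#' @param window A [rate_window()]; rates are computed in
#'   `[onset + start, onset + end)` per fixation.
#' @return List: `fixations` (the fixation event rows) and `rates`
#'   (`[n_fixations x n_units]` matrix, spikes/s, columns named by unit id).
#' @export
fixation_rate_matrix <- function(session, window = rate_window("feature")) {
  fix <- session$events[session$events$event_type == "fixation", ]
  iv <- window$interval
  starts <- fix$t_on_ms + iv[1]
  ends <- fix$t_on_ms + iv[2]
  len_s <- (iv[2] - iv[1]) / 1000
  rates <- vapply(session$units, function(u) {
    count_in_windows(u$spike_times, starts, ends) / len_s
  }, numeric(nrow(fix)))
  colnames(rates) <- vapply(session$units, function(u) {
    as.character(u$unit_id)
  }, character(1))
  list(fixations = fix, rates = rates)
}

#' Mean rate per stimulus x unit for one fixation role
#'
#' Averages per-fixation rates over all fixations on each stimulus in the
#' requested role. Stimuli never fixated in that role get `NA`.
#'
#' @param frm Output of [fixation_rate_matrix()].
#' @param is_target `TRUE` for target fixations, `FALSE` for distractor.
#' @param stimulus_ids Stimulus ids defining row order of the result.
#' @return `[n_stimuli x n_units]` matrix of mean rates.
#' @export
stimulus_rate_matrix <- function(frm, is_target, stimulus_ids) {
  keep <- frm$fixations$is_target == is_target
  f <- frm$fixations[keep, ]
  r <- frm$rates[keep, , drop = FALSE]
  out <- matrix(NA_real_, length(stimulus_ids), ncol(r),
                dimnames = list(as.character(stimulus_ids), colnames(r)))
  means <- rowsum(r, group = f$stimulus_id) /
    as.vector(table(f$stimulus_id))
  out[rownames(means), ] <- means
  out
}

#' Run the full unit screen on a session
#'
#' Computes, per unit: visual responsiveness (cue/array vs baseline,
#' rank-sum), RF class, baseline-subtracted face/house cue responses and
#' the SI with its category class, and attention selectivity with the
#' attention index (late window, paired per stimulus).
#'
#' @param session A `session`.
#' @param stimuli The `stimulus_set` shown in the session.
#' @return data.frame with one `UnitScreenRecord` row per unit
#'   (`unit_screen.csv` layout).
#' @export
screen_units <- function(session, stimuli) {
  ev <- session$events
  cues <- ev[ev$event_type == "cue_on", ]
  arrays <- ev[ev$event_type == "array_on", ]
  cue_win <- rate_window("cue_response")
  base_win <- rate_window("baseline")
  late <- rate_window("attention")
  frm_late <- fixation_rate_matrix(session, late)
  cue_cat <- as.character(stimuli$category[match(cues$stimulus_id,
                                                 stimuli$stimulus_id)])
  out <- vector("list", length(session$units))
  for (i in seq_along(session$units)) {
    u <- session$units[[i]]
    cue_r <- count_in_windows(u$spike_times,
                              cues$t_on_ms + cue_win$interval[1],
                              cues$t_on_ms + cue_win$interval[2]) /
      diff(cue_win$interval) * 1000
    arr_r <- count_in_windows(u$spike_times,
                              arrays$t_on_ms + cue_win$interval[1],
                              arrays$t_on_ms + cue_win$interval[2]) /
      diff(cue_win$interval) * 1000
    base_r <- count_in_windows(u$spike_times,
                               cues$t_on_ms + base_win$interval[1],
                               cues$t_on_ms + base_win$interval[2]) /
      diff(base_win$interval) * 1000
    vis <- assess_visual_responsiveness(cue_r, arr_r, base_r)
    rf <- classify_rf(vis$p_cue, vis$p_array)
    bsub <- cue_r - mean(base_r)
    face_r <- bsub[cue_cat == "face"]
    house_r <- bsub[cue_cat == "house"]
    cat_res <- classify_category(face_r, house_r)
    att <- attention_screen_unit(frm_late, i)
    out[[i]] <- data.frame(
      unit_id = u$unit_id, area = u$area,
      visually_responsive = vis$flag, p_cue = vis$p_cue,
      p_array = vis$p_array, rf_class = rf,
      R_face = mean(face_r), R_house = mean(house_r),
      SI = cat_res$SI, category_class = cat_res$class,
      category_p = cat_res$p,
      attention_selective = att$flag, attention_p = att$p,
      attention_index = att$attention_index,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

# Paired per-stimulus attention screen for unit column i of the late-window
# fixation rate matrix.
attention_screen_unit <- function(frm_late, i) {
  f <- frm_late$fixations
  r <- frm_late$rates[, i]
  mt <- tapply(r[f$is_target], f$stimulus_id[f$is_target], mean)
  md <- tapply(r[!f$is_target], f$stimulus_id[!f$is_target], mean)
  common <- intersect(names(mt), names(md))
  if (length(common) < 6L) {
    return(list(flag = NA, p = NA_real_, attention_index = NA_real_))
  }
  detect_attention_selectivity(as.numeric(mt[common]),
                               as.numeric(md[common]))
}
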