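#' Configuration for synthetic session generation
#'
#' Bundles and validates all parameters of the synthetic-session simulator.
#' Defaults reflect the free-gaze visual search design the simulator
#' emulates: four stimulus categories of 40 images each, 512-dimensional
#' feature embeddings, search arrays of 11 items (2 targets) drawn from 20
#' locations, fixation durations with mean/SD of about 208/154 ms, a
#' 4-12 Hz theta band, and LFPs sampled at 1 kHz.
#'
#' Attentional gain and theta phase-locking defaults are class-specific:
#' axis-coding units receive a larger target-fixation gain and a larger
#' drop in locking on targets than non-axis units, planting the
#' axis-vs-non-axis asymmetries the downstream analyses are designed to
#' detect. Passing scalar `attention_gain` or `locking_target` sets both
#' classes to that value.
#'
#' @param n_stimuli_per_category Stimuli per category (default 40).
#' @param D Feature dimension (default 512).
#' @param n_units Named integer vector of units per area
#'   (default `c(V4 = 12, TEO = 12, TE = 12, OFC = 12)`).
#' @param n_channels Named integer vector of LFP channels per area
#'   (default 2 per area, each on its own electrode).
#' @param fraction_axis Proportion of planted axis-coding units per area
#'   (default 0.5).
#' @param baseline_rate_range Range (spikes/s) from which per-unit baseline
#'   rates are drawn log-uniformly (default `c(8, 20)`).
#' @param rate_mod_sd Across-stimulus SD of the stimulus-driven rate, as a
#'   fraction of the unit's baseline rate (default 0.8).
#' @param attention_gain Multiplicative rate gain on target fixations in
#'   the late (150-225 ms) window; scalar, or `NULL` to use the
#'   class-specific defaults below.
#' @param attention_gain_axis,attention_gain_nonaxis Class-specific gain
#'   means (defaults 1.4 and 1.15).
#' @param attention_gain_sd Per-unit SD of the gain around its class mean
#'   (default 0.1; draws are truncated below at 0.5).
#' @param locking_distractor Theta phase-locking depth on distractor
#'   fixations, in `[0, 1)` (default 0.6, both classes).
#' @param locking_target Locking depth on target fixations; scalar, or
#'   `NULL` for class-specific defaults.
#' @param locking_target_axis,locking_target_nonaxis Class-specific target
#'   locking (defaults 0.2 and 0.45; both < `locking_distractor`, so target
#'   fixations desynchronise).
#' @param theta_band Hz interval of the planted oscillation (default
#'   `c(4, 12)`).
#' @param theta_amp,lfp_noise_sd LFP theta amplitude and 1/f-noise SD in
#'   arbitrary units (defaults 2 and 1).
#' @param fs LFP sampling rate, Hz (default 1000; must be at least twice
#'   the upper theta edge).
#' @param n_trials Number of search trials (default 200).
#' @param n_fixations_per_trial Fixations generated per search array
#'   (default 10).
#' @param fixation_duration_ms Mean and SD of fixation durations, ms
#'   (default `c(208.24, 153.77)`); durations are log-normal, truncated
#'   below at 80 ms.
#' @param seed Integer seed stored with the config.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_stimuli_per_category = 40,
                             D = 512,
                             n_units = c(V4 = 12, TEO = 12, TE = 12, OFC = 12),
                             n_channels = c(V4 = 2, TEO = 2, TE = 2, OFC = 2),
                             fraction_axis = 0.5,
                             baseline_rate_range = c(8, 20),
                             rate_mod_sd = 0.8,
                             attention_gain = NULL,
                             attention_gain_axis = 1.4,
                             attention_gain_nonaxis = 1.15,
                             attention_gain_sd = 0.1,
                             locking_distractor = 0.6,
                             locking_target = NULL,
                             locking_target_axis = 0.2,
                             locking_target_nonaxis = 0.45,
                             theta_band = c(4, 12),
                             theta_amp = 2,
                             lfp_noise_sd = 1,
                             fs = 1000,
                             n_trials = 200,
                             n_fixations_per_trial = 10,
                             fixation_duration_ms = c(208.24, 153.77),
                             seed = 1) {
  if (!is.null(attention_gain)) {
    attention_gain_axis <- attention_gain_nonaxis <- attention_gain
  }
  if (!is.null(locking_target)) {
    locking_target_axis <- locking_target_nonaxis <- locking_target
  }
  cfg <- list(
    n_stimuli_per_category = as.integer(n_stimuli_per_category),
    D = as.integer(D),
    n_units = n_units, n_channels = n_channels,
    fraction_axis = fraction_axis,
    baseline_rate_range = baseline_rate_range,
    rate_mod_sd = rate_mod_sd,
    attention_gain_axis = attention_gain_axis,
    attention_gain_nonaxis = attention_gain_nonaxis,
    attention_gain_sd = attention_gain_sd,
    locking_distractor = locking_distractor,
    locking_target_axis = locking_target_axis,
    locking_target_nonaxis = locking_target_nonaxis,
    theta_band = theta_band, theta_amp = theta_amp,
    lfp_noise_sd = lfp_noise_sd,
    fs = fs, n_trials = as.integer(n_trials),
    n_fixations_per_trial = as.integer(n_fixations_per_trial),
    fixation_duration_ms = fixation_duration_ms,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(
    cfg$n_stimuli_per_category >= 2, cfg$D >= 2,
    all(cfg$n_units >= 1), all(cfg$n_channels >= 1),
    cfg$fraction_axis >= 0, cfg$fraction_axis <= 1,
    all(cfg$baseline_rate_range > 0),
    cfg$n_trials >= 1, cfg$n_fixations_per_trial >= 1,
    cfg$fs > 0, length(cfg$theta_band) == 2,
    cfg$theta_band[1] < cfg$theta_band[2]
  )
  lk <- c(cfg$locking_distractor, cfg$locking_target_axis,
          cfg$locking_target_nonaxis)
  if (any(lk < 0) || any(lk >= 1)) {
    stop("locking depths must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$attention_gain_axis <= 0 || cfg$attention_gain_nonaxis <= 0) {
    stop("attention gain must be positive", call. = FALSE)
  }
  if (cfg$fs < 2 * cfg$theta_band[2]) {
    stop("fs must be at least twice the upper theta edge", call. = FALSE)
  }
  invisible(cfg)
}
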