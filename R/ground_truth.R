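#' Generate a unit population with planted ground truth
#'
#' Draws the per-unit parameters that the synthetic session realises and
#' that recovery tests score against. A fixed fraction of units in each
#' area are axis-coding: their mean rate for stimulus `s` is a softplus of
#' a linear function of the stimulus features,
#' `r(s) = softplus(baseline + m * z_s)` with `z_s` the standardised
#' projection of the features onto the unit's random axis `w` and `m` the
#' modulation amplitude (`rate_mod_sd * baseline`). Because baseline rates
#' sit well above zero the softplus is effectively linear there, so the
#' planted code is recoverable by a linear encoding model. Non-axis units
#' get per-stimulus rates drawn independently of the features (log-normal
#' around baseline with matched spread) — an exact null for the
#' permutation-selection calibration.
#'
#' Attentional gain (applied by the session generator to target fixations
#' in the late window) and theta phase-locking depths are drawn per unit
#' around class-specific means from the config.
#'
#' @param config A [synthetic_config()].
#' @param stimuli A [generate_stimulus_features()] output.
#' @param seed Integer seed.
#' @return A `ground_truth` object: list with `units` (data.frame:
#'   unit_id, area, electrode_id, is_axis, baseline_rate, attention_gain,
#'   locking_distractor, locking_target), `axis_weights`
#'   (`[n_units x D]`, zero rows for non-axis units) and `stim_rates`
#'   (`[n_units x n_stimuli]` mean rates, spikes/s).
#' @export
generate_unit_population <- function(config, stimuli, seed = config$seed) {
  validate_synthetic_config(config)
  X <- stimuli$features
  if (ncol(X) != config$D) {
    stop("stimuli feature dimension does not match config D", call. = FALSE)
  }
  areas <- rep(names(config$n_units), times = config$n_units)
  n_units <- length(areas)
  n_stim <- nrow(X)
  withr::with_seed(seed, {
    is_axis <- unlist(lapply(config$n_units, function(k) {
      n_ax <- round(config$fraction_axis * k)
      sample(c(rep(TRUE, n_ax), rep(FALSE, k - n_ax)))
    }), use.names = FALSE)
    lr <- log(config$baseline_rate_range)
    baseline <- exp(stats::runif(n_units, lr[1], lr[2]))
    gain_mean <- ifelse(is_axis, config$attention_gain_axis,
                        config$attention_gain_nonaxis)
    attention_gain <- pmax(0.5, stats::rnorm(n_units, gain_mean,
                                             config$attention_gain_sd))
    locking_d <- rep(config$locking_distractor, n_units)
    locking_t <- ifelse(is_axis, config$locking_target_axis,
                        config$locking_target_nonaxis)
    W <- matrix(0, n_units, config$D)
    stim_rates <- matrix(0, n_units, n_stim)
    sdlog <- sqrt(log(1 + config$rate_mod_sd^2))
    for (i in seq_len(n_units)) {
      if (is_axis[i]) {
        w <- stats::rnorm(config$D)
        w <- w / sqrt(sum(w^2))
        z <- drop(X %*% w)
        z <- (z - mean(z)) / stats::sd(z)
        W[i, ] <- w
        stim_rates[i, ] <- softplus(baseline[i] +
                                      config$rate_mod_sd * baseline[i] * z)
      } else {
        stim_rates[i, ] <- baseline[i] *
          stats::rlnorm(n_stim, -sdlog^2 / 2, sdlog)
      }
    }
    # Units spread round-robin over the area's electrodes so that
    # cross-electrode spike-LFP pairs always exist.
    electrode <- unlist(lapply(names(config$n_units), function(a) {
      k <- config$n_units[[a]]
      ne <- config$n_channels[[a]]
      rep_len(seq_len(ne), k)
    }), use.names = FALSE)
  })
  units <- data.frame(
    unit_id = seq_len(n_units), area = areas, electrode_id = electrode,
    is_axis = is_axis, baseline_rate = baseline,
    attention_gain = attention_gain,
    locking_distractor = locking_d, locking_target = locking_t,
    stringsAsFactors = FALSE
  )
  structure(list(units = units, axis_weights = W, stim_rates = stim_rates),
            class = "ground_truth")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
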