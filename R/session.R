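#' Simulate a fixation-aligned recording session
#'
#' Realises a full synthetic session from a stimulus set and planted ground
#' truth. The trial timeline follows the free-gaze search design: 400 ms
#' initial fixation, a cue of uniform 500-1300 ms duration, a 500 ms delay,
#' then a search array of 11 items (2 targets of the cue's category plus 9
#' distractors from the other categories, placed at 11 of 20 locations)
#' over which a sequence of fixations is generated. Fixation durations are
#' log-normal matched to the configured mean/SD (default 208/154 ms) and
#' truncated below at 80 ms; items are visited uniformly at random.
#'
#' Spikes are drawn from an inhomogeneous Poisson process whose rate is the
#' unit's stimulus-driven rate (with a 50 ms response latency), multiplied
#' by `(1 + locking * cos(theta phase))` within each fixation's first
#' 200 ms (locking depth per the fixated item's target/distractor role) and
#' by the unit's attentional gain in the 150-225 ms window of target
#' fixations. Outside stimulus drive, units fire at half their baseline
#' rate. Each area has one drifting theta oscillator (4-12 Hz) whose phase
#' is shared between that area's spike modulation and LFP channels; LFP =
#' theta sinusoid + 1/f noise, sampled at `fs`.
#'
#' @param config A [synthetic_config()].
#' @param stimuli A `stimulus_set`.
#' @param truth A `ground_truth` from [generate_unit_population()].
#' @param seed Integer seed.
#' @return A `session`: list with `events` (data.frame: trial_id,
#'   event_type, t_on_ms, t_off_ms, stimulus_id, is_target, location_id),
#'   `arrays` (11 rows per trial: trial_id, stimulus_id, is_target,
#'   location_id), `units` (list: unit_id, area, electrode_id,
#'   spike_times ms, sorted), `lfp` (list: channel_id, area, electrode_id,
#'   samples, fs), `fs` and `duration_ms`.
#' @export
generate_session <- function(config, stimuli, truth, seed = config$seed) {
  validate_synthetic_config(config)
  n_stim_total <- length(stimuli$stimulus_id)
  if (ncol(truth$stim_rates) != n_stim_total) {
    stop("invalid argument: truth/stimuli size mismatch", call. = FALSE)
  }
  fs <- config$fs
  withr::with_seed(seed, {
    tl <- build_timeline(config, stimuli)
    n_ms <- tl$duration_ms
    phase <- area_theta_phase(names(config$n_units), n_ms, config)
    cosphase <- lapply(phase, cos)
    units <- simulate_spikes(config, truth, tl, cosphase, n_ms)
    lfp <- simulate_lfp(config, phase, n_ms)
  })
  structure(
    list(events = tl$events, arrays = tl$arrays, units = units, lfp = lfp,
         fs = fs, duration_ms = tl$duration_ms),
    class = "session"
  )
}

#' @export
print.session <- function(x, ...) {
  cat("<session> ", length(unique(x$events$trial_id)), " trials, ",
      length(x$units), " units, ", length(x$lfp), " LFP channels @ ",
      x$fs, " Hz, ", round(x$duration_ms / 1000), " s\n", sep = "")
  invisible(x)
}

# --- timeline -------------------------------------------------------------

N_ARRAY_ITEMS <- 11L
N_TARGETS <- 2L
N_LOCATIONS <- 20L
DRIVE_LATENCY_MS <- 50
SACCADE_GAP_MS <- 30
LOCKING_SPAN_MS <- 200

build_timeline <- function(config, stimuli) {
  cat_ids <- split(stimuli$stimulus_id, stimuli$category)
  fx_par <- lognormal_params(config$fixation_duration_ms[1],
                             config$fixation_duration_ms[2])
  ev <- list()
  ar <- list()
  t <- 500
  for (tr in seq_len(config$n_trials)) {
    ev[[length(ev) + 1L]] <- event_row(tr, "initial_fixation", t, t + 400)
    t <- t + 400
    cue_cat <- sample(c("face", "house"), 1L)
    pool <- cat_ids[[cue_cat]]
    picked <- sample(pool, N_TARGETS + 1L)  # cue + 2 distinct targets
    cue_stim <- picked[1L]
    targets <- picked[-1L]
    cue_dur <- stats::runif(1, 500, 1300)
    ev[[length(ev) + 1L]] <- event_row(tr, "cue_on", t, t + cue_dur,
                                       stimulus_id = cue_stim)
    t <- t + cue_dur
    ev[[length(ev) + 1L]] <- event_row(tr, "delay", t, t + 500)
    t <- t + 500
    distr <- sample(unlist(cat_ids[setdiff(names(cat_ids), cue_cat)],
                           use.names = FALSE), N_ARRAY_ITEMS - N_TARGETS)
    items <- c(targets, distr)
    locs <- sample.int(N_LOCATIONS, N_ARRAY_ITEMS)
    ord <- sample.int(N_ARRAY_ITEMS)
    items <- items[ord]
    is_tgt <- items %in% targets
    locs <- locs[ord]
    ar[[length(ar) + 1L]] <- data.frame(
      trial_id = tr, stimulus_id = items, is_target = is_tgt,
      location_id = locs
    )
    array_on <- t
    ft <- t + 100  # first-saccade latency
    for (k in seq_len(config$n_fixations_per_trial)) {
      dur <- 0
      while (dur < 80) {
        dur <- stats::rlnorm(1, fx_par$meanlog, fx_par$sdlog)
      }
      pick <- sample.int(N_ARRAY_ITEMS, 1L)
      ev[[length(ev) + 1L]] <- event_row(
        tr, "fixation", ft, ft + dur,
        stimulus_id = items[pick], is_target = is_tgt[pick],
        location_id = locs[pick]
      )
      ft <- ft + dur + SACCADE_GAP_MS
    }
    ev[[length(ev) + 1L]] <- event_row(tr, "array_on", array_on, ft)
    t <- ft + 250
  }
  events <- do.call(rbind, ev)
  events <- events[order(events$t_on_ms), ]
  rownames(events) <- NULL
  list(events = events, arrays = do.call(rbind, ar),
       duration_ms = ceiling(t + 500))
}

event_row <- function(trial_id, type, t_on, t_off, stimulus_id = NA_integer_,
                      is_target = NA, location_id = NA_integer_) {
  data.frame(trial_id = trial_id, event_type = type, t_on_ms = t_on,
             t_off_ms = t_off, stimulus_id = stimulus_id,
             is_target = is_target, location_id = location_id,
             stringsAsFactors = FALSE)
}

lognormal_params <- function(m, s) {
  cv2 <- (s / m)^2
  sdlog <- sqrt(log(1 + cv2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

# --- neural signals -------------------------------------------------------

# One drifting theta oscillator per area: instantaneous frequency follows a
# mean-reverting walk reflected into the configured band; phase shared by
# the area's LFP channels and its units' spike modulation.
area_theta_phase <- function(areas, n_ms, config) {
  fs <- config$fs
  n <- ceiling(n_ms * fs / 1000)
  band <- config$theta_band
  mid <- mean(band)
  out <- list()
  for (a in areas) {
    df <- stats::rnorm(n, 0, 0.5 / sqrt(fs))
    f <- numeric(n)
    f[1] <- stats::runif(1, band[1], band[2])
    rev_rate <- 0.5 / fs
    for (i in 2:n) {
      fi <- f[i - 1] + rev_rate * (mid - f[i - 1]) + df[i]
      if (fi < band[1]) fi <- 2 * band[1] - fi
      if (fi > band[2]) fi <- 2 * band[2] - fi
      f[i] <- fi
    }
    out[[a]] <- cumsum(2 * pi * f / fs) + stats::runif(1, 0, 2 * pi)
  }
  out
}

simulate_spikes <- function(config, truth, tl, cosphase, n_ms) {
  ev <- tl$events
  cues <- ev[ev$event_type == "cue_on", ]
  fix <- ev[ev$event_type == "fixation", ]
  ut <- truth$units
  n_units <- nrow(ut)
  units <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    base <- ut$baseline_rate[i]
    rate <- rep(0.5 * base, n_ms)
    # cue drive (foveal response with onset latency)
    for (j in seq_len(nrow(cues))) {
      rng <- ms_range(cues$t_on_ms[j] + DRIVE_LATENCY_MS, cues$t_off_ms[j],
                      n_ms)
      rate[rng] <- truth$stim_rates[i, cues$stimulus_id[j]]
    }
    # fixation drive + locking + attentional gain
    cph <- cosphase[[ut$area[i]]]
    for (j in seq_len(nrow(fix))) {
      on <- fix$t_on_ms[j]
      r0 <- truth$stim_rates[i, fix$stimulus_id[j]]
      drive <- ms_range(on + DRIVE_LATENCY_MS,
                        fix$t_off_ms[j] + DRIVE_LATENCY_MS, n_ms)
      rate[drive] <- r0
      lock <- if (fix$is_target[j]) ut$locking_target[i] else
        ut$locking_distractor[i]
      lrng <- ms_range(on, on + LOCKING_SPAN_MS, n_ms)
      rate[lrng] <- r0 * (1 + lock * cph[lrng])
      if (fix$is_target[j]) {
        arng <- ms_range(on + 150, on + 225, n_ms)
        rate[arng] <- rate[arng] * ut$attention_gain[i]
      }
    }
    counts <- stats::rpois(n_ms, rate / 1000)
    idx <- which(counts > 0L)
    times <- rep(idx, counts[idx]) - 1 + stats::runif(sum(counts[idx]))
    units[[i]] <- list(unit_id = ut$unit_id[i], area = ut$area[i],
                       electrode_id = ut$electrode_id[i],
                       spike_times = sort(times))
  }
  units
}

ms_range <- function(from, to, n_ms) {
  lo <- max(1L, floor(from) + 1L)
  hi <- min(n_ms, ceiling(to))
  if (hi < lo) integer(0) else lo:hi
}

simulate_lfp <- function(config, phase, n_ms) {
  fs <- config$fs
  n <- ceiling(n_ms * fs / 1000)
  lfp <- list()
  ch_id <- 0L
  for (a in names(config$n_channels)) {
    theta <- config$theta_amp * cos(phase[[a]])
    for (e in seq_len(config$n_channels[[a]])) {
      ch_id <- ch_id + 1L
      samples <- theta + config$lfp_noise_sd * pink_noise(n)
      lfp[[ch_id]] <- list(channel_id = ch_id, area = a, electrode_id = e,
                           samples = samples, fs = fs)
    }
  }
  lfp
}

# 1/f ("pink") noise via spectral shaping, unit variance.
pink_noise <- function(n) {
  m <- stats::nextn(n, 2)
  white <- stats::rnorm(m)
  spec <- stats::fft(white)
  f <- c(1, seq_len(m - 1))  # avoid dividing DC by zero
  f <- pmin(f, m - f + 1)    # fold to two-sided frequency magnitudes
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  (x - mean(x)) / stats::sd(x)
}
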