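COHERENCE_WINDOW_MS <- 200

#' Extract paired spike/LFP segments around fixation onsets
#'
#' For each fixation event, takes the LFP samples in
#' `[onset, onset + 200 ms)` and the unit's spike times re-referenced to
#' the fixation onset. The 200 ms window is fixed regardless of fixation
#' duration. Spikes and LFP must come from different electrodes so that
#' spike waveforms cannot leak into the paired LFP; a same-electrode pair
#' is an error. Segments that would run past the end of the recording are
#' dropped and counted.
#'
#' @param session A `session`.
#' @param events Fixation event rows (subset of `session$events`, e.g. one
#'   target/distractor condition).
#' @param channel_id LFP channel id.
#' @param unit_id Spiking unit id.
#' @return List of `list(spikes, lfp)` segments; attributes `n_dropped`,
#'   `fs`, `unit_id`, `channel_id`.
#' @export
extract_fixation_segments <- function(session, events, channel_id,
                                      unit_id) {
  ch <- session$lfp[[which(vapply(session$lfp, `[[`, 0L, "channel_id") ==
                             channel_id)]]
  un <- session$units[[which(vapply(session$units, `[[`, 0L, "unit_id") ==
                               unit_id)]]
  if (is.null(ch) || is.null(un)) {
    stop("unknown unit or channel id", call. = FALSE)
  }
  if (ch$area == un$area && ch$electrode_id == un$electrode_id) {
    stop("same-electrode pair: spikes and LFP must come from different ",
         "electrodes", call. = FALSE)
  }
  fs <- ch$fs
  n_samp <- round(COHERENCE_WINDOW_MS * fs / 1000)
  onsets <- events$t_on_ms[events$event_type == "fixation"]
  segs <- list()
  dropped <- 0L
  for (on in onsets) {
    i0 <- floor(on * fs / 1000) + 1L
    i1 <- i0 + n_samp - 1L
    if (i1 > length(ch$samples) || i0 < 1L) {
      dropped <- dropped + 1L
      next
    }
    sp <- un$spike_times
    sp <- sp[sp >= on & sp < on + COHERENCE_WINDOW_MS] - on
    segs[[length(segs) + 1L]] <- list(spikes = sp,
                                      lfp = ch$samples[i0:i1])
  }
  attr(segs, "n_dropped") <- dropped
  attr(segs, "fs") <- fs
  attr(segs, "unit_id") <- unit_id
  attr(segs, "channel_id") <- channel_id
  segs
}

#' Equalise fixation and spike counts between two conditions
#'
#' To remove sample-size bias from coherence comparisons, each repeat
#' subsamples the fixations of the larger condition (without replacement)
#' down to the smaller count, then randomly deletes spikes from whichever
#' condition still has more until total spike counts match. Downstream
#' estimates are averaged over repeats.
#'
#' @param segs_a,segs_b Segment lists from [extract_fixation_segments()].
#' @param n_repeats Number of equalisation repeats (default 20).
#' @param seed Integer seed.
#' @return List of `n_repeats` elements, each `list(a = segs, b = segs)`.
#' @export
equalize_condition_samples <- function(segs_a, segs_b, n_repeats = 20,
                                       seed = 1) {
  if (length(segs_a) == 0L || length(segs_b) == 0L) {
    stop("both conditions must have at least one segment", call. = FALSE)
  }
  spk <- function(s) sum(vapply(s, function(x) length(x$spikes), 0L))
  if (spk(segs_a) == 0L || spk(segs_b) == 0L) {
    stop("insufficient spikes: a condition has zero spikes", call. = FALSE)
  }
  n_fix <- min(length(segs_a), length(segs_b))
  fs <- attr(segs_a, "fs")
  withr::with_seed(seed, {
    reps <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      a <- segs_a[sample.int(length(segs_a), n_fix)]
      b <- segs_b[sample.int(length(segs_b), n_fix)]
      na <- spk(a); nb <- spk(b)
      if (na > nb) a <- delete_spikes(a, na - nb)
      if (nb > na) b <- delete_spikes(b, nb - na)
      attr(a, "fs") <- fs; attr(b, "fs") <- fs
      reps[[r]] <- list(a = a, b = b)
    }
  })
  reps
}

# Randomly delete n spikes from a segment list (uniform over all spikes).
delete_spikes <- function(segs, n_delete) {
  counts <- vapply(segs, function(x) length(x$spikes), 0L)
  total <- sum(counts)
  kill <- sample.int(total, n_delete)
  seg_of <- rep(seq_along(segs), counts)
  pos_in <- sequence(counts)
  for (k in kill) {
    s <- seg_of[k]
    segs[[s]]$spikes[pos_in[k]] <- NA_real_
  }
  for (s in seq_along(segs)) {
    segs[[s]]$spikes <- segs[[s]]$spikes[!is.na(segs[[s]]$spikes)]
  }
  segs
}

#' Spike-field coherence from fixation segments
#'
#' Spikes are binned as counts at the LFP sampling rate and mean-subtracted
#' per segment; the LFP is mean-subtracted per segment; both are tapered
#' with a single Hanning window. Auto- and cross-spectra are averaged
#' across segments before the coherence calculation
#' `C_xy(f) = |S_xy(f)| / sqrt(S_x(f) S_y(f))`, which is bounded in
#' `[0, 1]`.
#'
#' @param segments Segment list (one equalisation repeat, or raw output of
#'   [extract_fixation_segments()]).
#' @param fs Sampling rate; defaults to the `fs` attribute.
#' @param min_segments,min_spikes Quality floors (defaults 10 and 50).
#' @return A `spectral_estimate`: list with `freqs` (Hz, up to Nyquist),
#'   `values` (coherence), `n_fixations_used`, `n_spikes_used`,
#'   `taper = "hanning"`.
#' @export
spike_field_coherence <- function(segments, fs = attr(segments, "fs"),
                                  min_segments = 10, min_spikes = 50) {
  n_seg <- length(segments)
  n_spk <- sum(vapply(segments, function(x) length(x$spikes), 0L))
  if (n_seg < min_segments || n_spk < min_spikes) {
    stop(sprintf(
      "insufficient data: %d segments (need %d), %d spikes (need %d)",
      n_seg, min_segments, n_spk, min_spikes), call. = FALSE)
  }
  n <- length(segments[[1L]]$lfp)
  taper <- hanning_taper(n)
  Sx <- Sy <- numeric(n)
  Sxy <- complex(n)
  for (seg in segments) {
    x <- bin_spikes(seg$spikes, n, fs)
    y <- seg$lfp
    x <- (x - mean(x)) * taper
    y <- (y - mean(y)) * taper
    X <- stats::fft(x)
    Y <- stats::fft(y)
    Sx <- Sx + Mod(X)^2
    Sy <- Sy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  keep <- seq_len(n %/% 2 + 1L)
  freqs <- (keep - 1L) * fs / n
  denom <- sqrt(Sx[keep] * Sy[keep])
  coh <- ifelse(denom > 0, Mod(Sxy[keep]) / denom, NA_real_)
  structure(
    list(freqs = freqs, values = coh, n_fixations_used = n_seg,
         n_spikes_used = n_spk, taper = "hanning"),
    class = "spectral_estimate"
  )
}

hanning_taper <- function(n) {
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

bin_spikes <- function(spike_times_ms, n, fs) {
  x <- numeric(n)
  if (length(spike_times_ms)) {
    idx <- floor(spike_times_ms * fs / 1000) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    tb <- tabulate(idx, nbins = n)
    x <- as.numeric(tb)
  }
  x
}

#' Average a spectral estimate over a frequency band
#'
#' Mean of the values at frequency bins inside the closed band.
#'
#' @param est A `spectral_estimate` (or anything with `freqs`/`values`).
#' @param band Hz interval, default the theta band `c(4, 12)`.
#' @return Scalar band mean.
#' @export
band_average <- function(est, band = c(4, 12)) {
  sel <- est$freqs >= band[1] & est$freqs <= band[2]
  if (!any(sel)) {
    stop("invalid band: no frequency bins inside [", band[1], ", ",
         band[2], "] Hz", call. = FALSE)
  }
  mean(est$values[sel])
}

#' Condition-equalised coherence for one spike-LFP pair
#'
#' Convenience wrapper: extracts target and distractor fixation segments,
#' equalises fixation and spike counts over `n_repeats` subsamples,
#' computes the repeat-averaged coherence spectrum per condition, and the
#' theta desynchronisation index
#' `(Coh_distractor - Coh_target) / (Coh_distractor + Coh_target)` on the
#' band means. Optionally subtracts the baseline coherence estimated from
#' the initial fixations preceding the cue.
#'
#' @param session A `session`.
#' @param unit_id,channel_id Spike and LFP sources (different electrodes).
#' @param band Hz band for the summary (default theta, `c(4, 12)`).
#' @param n_repeats Equalisation repeats (default 20).
#' @param baseline_subtract Subtract initial-fixation coherence (default
#'   `FALSE`).
#' @param seed Integer seed.
#' @return List: `freqs`, `coh_target`, `coh_distractor` (repeat-averaged
#'   spectra), `theta_target`, `theta_distractor` (band means),
#'   `desync_index`, `n_fix`, `n_spikes`.
#' @export
coherence_pair <- function(session, unit_id, channel_id, band = c(4, 12),
                           n_repeats = 20, baseline_subtract = FALSE,
                           seed = 1) {
  fix <- session$events[session$events$event_type == "fixation", ]
  segs_t <- extract_fixation_segments(session, fix[fix$is_target, ],
                                      channel_id, unit_id)
  segs_d <- extract_fixation_segments(session, fix[!fix$is_target, ],
                                      channel_id, unit_id)
  reps <- equalize_condition_samples(segs_d, segs_t,
                                     n_repeats = n_repeats, seed = seed)
  acc_d <- acc_t <- NULL
  for (r in reps) {
    cd <- spike_field_coherence(r$a)
    ct <- spike_field_coherence(r$b)
    acc_d <- if (is.null(acc_d)) cd$values else acc_d + cd$values
    acc_t <- if (is.null(acc_t)) ct$values else acc_t + ct$values
    freqs <- cd$freqs
    n_fix <- cd$n_fixations_used
    n_spk <- cd$n_spikes_used
  }
  coh_d <- acc_d / length(reps)
  coh_t <- acc_t / length(reps)
  if (baseline_subtract) {
    init <- session$events[session$events$event_type == "initial_fixation", ]
    init$event_type <- "fixation"
    segs_b <- extract_fixation_segments(session, init, channel_id, unit_id)
    cb <- spike_field_coherence(segs_b)
    coh_d <- coh_d - cb$values
    coh_t <- coh_t - cb$values
  }
  th_d <- band_average(list(freqs = freqs, values = coh_d), band)
  th_t <- band_average(list(freqs = freqs, values = coh_t), band)
  list(freqs = freqs, coh_target = coh_t, coh_distractor = coh_d,
       theta_target = th_t, theta_distractor = th_d,
       desync_index = normalized_contrast(th_d, th_t),
       n_fix = n_fix, n_spikes = n_spk)
}
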