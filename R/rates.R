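#' Analysis time windows relative to an anchor event
#'
#' The canonical fixation- and cue-aligned windows used throughout the
#' pipeline, in milliseconds relative to the anchor event onset. Windows are
#' half-open `[start, end)` so adjacent windows never double-count a spike.
#'
#' * `feature` (early): 50 to 150 ms after fixation onset, the window in
#'   which units primarily reflect the visual features of the fixated item.
#' * `attention` (late): 150 to 225 ms after fixation onset, the window in
#'   which target/distractor modulation is expressed.
#' * `baseline`: -150 to 0 ms before the anchor (cue onset).
#' * `cue_response`: 50 to 200 ms after cue or array onset.
#'
#' @param name One of `"feature"`, `"attention"`, `"baseline"`,
#'   `"cue_response"`, or a custom label when `interval` is supplied.
#' @param interval Optional length-2 numeric, ms relative to the anchor;
#'   overrides the named default.
#' @return A `rate_window` object: list with `name` and `interval`.
#' @export
#' @examples
#' rate_window("feature")
#' rate_window("custom", c(0, 300))
rate_window <- function(name, interval = NULL) {
  defaults <- list(
    feature      = c(50, 150),
    attention    = c(150, 225),
    baseline     = c(-150, 0),
    cue_response = c(50, 200)
  )
  if (is.null(interval)) {
    if (!name %in% names(defaults)) {
      stop("unknown window '", name, "' and no interval supplied",
           call. = FALSE)
    }
    interval <- defaults[[name]]
  }
  interval <- as.numeric(interval)
  if (length(interval) != 2L || !all(is.finite(interval)) ||
      interval[1] >= interval[2]) {
    stop("interval must be an increasing pair of finite ms values",
         call. = FALSE)
  }
  structure(list(name = name, interval = interval), class = "rate_window")
}

#' Spike density function with an EPSP-like causal kernel
#'
#' Convolves a spike train with the causal kernel
#' `K(t) = (1 - exp(-t/growth)) * exp(-t/decay)` for `t >= 0` (0 for
#' `t < 0`), which projects activity forward in time and approximates an
#' excitatory postsynaptic potential. The kernel is normalised to unit area
#' so that an isolated spike contributes area 1 and the trace is a rate
#' estimate in spikes/s.
#'
#' @param spike_times Numeric vector of spike times, ms.
#' @param t_grid Strictly increasing numeric vector of evaluation times, ms.
#' @param growth_ms,decay_ms Kernel time constants, ms (defaults 1 and 20).
#' @return Numeric vector of rates (spikes/s), one per grid point.
#' @export
spike_density_function <- function(spike_times, t_grid,
                                   growth_ms = 1, decay_ms = 20) {
  if (growth_ms <= 0 || decay_ms <= 0) {
    stop("kernel time constants must be positive", call. = FALSE)
  }
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) > 1L && any(diff(t_grid) <= 0)) {
    stop("t_grid must be strictly increasing", call. = FALSE)
  }
  out <- numeric(length(t_grid))
  if (length(spike_times) == 0L) return(out)
  # Kernel area in ms: int (1 - e^{-t/g}) e^{-t/d} dt = d - gd/(g+d)
  area_ms <- decay_ms - growth_ms * decay_ms / (growth_ms + decay_ms)
  for (s in as.numeric(spike_times)) {
    dt <- t_grid - s
    pos <- dt >= 0
    if (any(pos)) {
      k <- (1 - exp(-dt[pos] / growth_ms)) * exp(-dt[pos] / decay_ms)
      out[pos] <- out[pos] + k / area_ms * 1000  # ms^-1 -> s^-1
    }
  }
  out
}

#' Mean firing rate in a window relative to an anchor
#'
#' Counts spikes with `t` in `[anchor + start, anchor + end)` (half-open)
#' and divides by the window length in seconds.
#'
#' @param spike_times Numeric vector of spike times, ms.
#' @param anchor_ms Anchor event time, ms.
#' @param window A [rate_window()] (or anything with an `interval` field).
#' @return Rate in spikes/s.
#' @export
windowed_rate <- function(spike_times, anchor_ms, window) {
  iv <- window$interval
  lo <- anchor_ms + iv[1]
  hi <- anchor_ms + iv[2]
  n <- sum(spike_times >= lo & spike_times < hi)
  n / ((iv[2] - iv[1]) / 1000)
}

#' Normalise condition rates to their maximum
#'
#' Divides each entry by the maximum across conditions, so the preferred
#' condition maps to 1. Errors on an all-zero (or non-positive-max) input,
#' for which the normalisation is undefined.
#'
#' @param condition_rates Numeric vector of rates.
#' @return Numeric vector with maximum 1.
#' @export
normalize_to_max <- function(condition_rates) {
  m <- max(condition_rates)
  if (!is.finite(m) || m <= 0) {
    stop("normalisation undefined: maximum rate is not positive",
         call. = FALSE)
  }
  condition_rates / m
}

#' Normalised contrast between two non-negative quantities
#'
#' `(a - b) / (a + b)`, the index used throughout: the attention index
#' (target first), the desynchronisation index (distractor-condition
#' coherence first), the Granger-causality reduction (distractor first), and
#' the geometry contrasts (target first). Antisymmetric and bounded in
#' `[-1, 1]` for non-negative inputs.
#'
#' @param a,b Non-negative numerics (vectorised).
#' @return `(a - b) / (a + b)`.
#' @export
normalized_contrast <- function(a, b) {
  s <- a + b
  if (any(s == 0)) {
    stop("undefined contrast: a + b = 0", call. = FALSE)
  }
  (a - b) / s
}
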