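# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete synthetic session: 8 units over 4 areas, 30 trials,
# reduced stimulus set and feature dimension for speed.
small_world <- function() {
  memo("small_world", function() {
    cfg <- synthetic_config(
      n_stimuli_per_category = 10, D = 64,
      n_units = c(V4 = 2, TEO = 2, TE = 2, OFC = 2),
      n_trials = 45, seed = 11
    )
    stimuli <- generate_stimulus_features(10, 64, separation = 4, seed = 11)
    truth <- generate_unit_population(cfg, stimuli, seed = 12)
    session <- generate_session(cfg, stimuli, truth, seed = 13)
    list(cfg = cfg, stimuli = stimuli, truth = truth, session = session)
  })
}

# Synthetic fixation segments (no session needed): Poisson spikes plus an
# independent white-noise LFP, optionally with the spikes phase-locked to a
# theta oscillation shared with the LFP.
make_segments <- function(n_seg, rate_hz = 25, locking = 0, theta_hz = 8,
                          fs = 1000, seed = 1) {
  withr::with_seed(seed, {
    n <- round(200 * fs / 1000)
    tt <- (seq_len(n) - 1) / fs
    segs <- lapply(seq_len(n_seg), function(i) {
      ph <- runif(1, 0, 2 * pi)
      lam <- rate_hz * (1 + locking * cos(2 * pi * theta_hz * tt + ph)) / fs
      counts <- rpois(n, lam)
      spikes <- (rep(seq_len(n), counts) - runif(sum(counts))) / fs * 1000
      lfp <- if (locking > 0) {
        cos(2 * pi * theta_hz * tt + ph) + rnorm(n, 0, 0.5)
      } else {
        rnorm(n)
      }
      list(spikes = sort(spikes), lfp = lfp)
    })
    attr(segs, "fs") <- fs
    segs
  })
}

# Simulate a bivariate VAR as one long segment.
simulate_var2 <- function(A_list, T, sd = c(1, 1), seed = 1, burn = 200) {
  withr::with_seed(seed, {
    p <- length(A_list)
    x <- matrix(0, T + burn, 2)
    for (t in (p + 1):(T + burn)) {
      acc <- c(0, 0)
      for (l in seq_len(p)) acc <- acc + A_list[[l]] %*% x[t - l, ]
      x[t, ] <- acc + stats::rnorm(2, 0, sd)
    }
    x <- x[(burn + 1):(burn + T), , drop = FALSE]
  })
  list(x = list(x[, 1]), y = list(x[, 2]), fs = 1000)
}
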