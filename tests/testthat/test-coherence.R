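test_that("fixation segment extraction enforces the cross-electrode rule", {
  w <- small_world()
  s <- w$session
  fix <- s$events[s$events$event_type == "fixation", ]
  # unit 1 (V4, electrode 1) with channel 2 (V4, electrode 2): allowed
  segs <- extract_fixation_segments(s, fix, channel_id = 2, unit_id = 1)
  expect_equal(length(segs) + attr(segs, "n_dropped"), nrow(fix))
  expect_true(all(vapply(segs, function(x) length(x$lfp), 0L) == 200L))
  expect_true(all(unlist(lapply(segs, `[[`, "spikes")) >= 0))
  expect_true(all(unlist(lapply(segs, `[[`, "spikes")) < 200))
  # same electrode: error
  expect_error(extract_fixation_segments(s, fix, channel_id = 1,
                                         unit_id = 1),
               "same-electrode")
  # the window stays 200 ms even for fixations shorter than 200 ms
  short <- fix[fix$t_off_ms - fix$t_on_ms < 200, ][1, ]
  seg1 <- extract_fixation_segments(s, short, channel_id = 2, unit_id = 1)
  expect_equal(length(seg1[[1]]$lfp), 200L)
})

test_that("condition equalisation matches fixation and spike counts", {
  a <- make_segments(120, rate_hz = 25, seed = 1)   # ~600 spikes
  b <- make_segments(80, rate_hz = 25, seed = 2)    # ~400 spikes
  n_spk <- function(s) sum(vapply(s, function(x) length(x$spikes), 0L))
  reps <- equalize_condition_samples(a, b, n_repeats = 5, seed = 3)
  for (r in reps) {
    expect_equal(length(r$a), 80L)
    expect_equal(length(r$b), 80L)
    expect_equal(n_spk(r$a), n_spk(r$b))
  }
  # equal inputs: nothing deleted
  same <- equalize_condition_samples(a, a, n_repeats = 2, seed = 4)
  expect_equal(n_spk(same[[1]]$a), n_spk(same[[1]]$b))
  expect_equal(length(same[[1]]$a), 120L)

  empty <- lapply(1:20, function(i) list(spikes = numeric(0),
                                         lfp = rnorm(200)))
  attr(empty, "fs") <- 1000
  expect_error(equalize_condition_samples(a, empty), "zero spikes")
})

test_that("coherence of a signal with itself is 1 wherever there is power", {
  segs <- make_segments(50, rate_hz = 40, seed = 5)
  # replace the LFP by the binned spike train itself
  for (i in seq_along(segs)) {
    counts <- tabulate(floor(segs[[i]]$spikes) + 1L, nbins = 200)
    segs[[i]]$lfp <- as.numeric(counts)
  }
  attr(segs, "fs") <- 1000
  est <- spike_field_coherence(segs)
  powered <- !is.na(est$values)
  expect_true(any(powered))
  expect_true(all(abs(est$values[powered] - 1) < 1e-9))
})

test_that("independent noise coherence sits at the analytic bias level", {
  segs <- make_segments(500, rate_hz = 25, locking = 0, seed = 6)
  est <- spike_field_coherence(segs)
  expect_true(all(est$values >= 0 & est$values <= 1 + 1e-9, na.rm = TRUE))
  m <- mean(est$values[est$freqs > 0], na.rm = TRUE)
  expect_gt(m, 0.6 / sqrt(500))
  expect_lt(m, 1.4 / sqrt(500))
})

test_that("planted theta locking produces a theta-band coherence peak", {
  segs <- make_segments(300, rate_hz = 30, locking = 0.6, theta_hz = 8,
                        seed = 7)
  est <- spike_field_coherence(segs)
  theta <- band_average(est, c(4, 12))
  high <- band_average(est, c(40, 100))
  expect_gt(theta, 2 * high)
})

test_that("quality floors and band averaging guard their inputs", {
  few <- make_segments(5, seed = 8)
  expect_error(spike_field_coherence(few), "insufficient data: 5 segments")
  est <- list(freqs = seq(0, 500, by = 5), values = rep(0.3, 101))
  expect_equal(band_average(est, c(4, 12)), 0.3)
  # 200 ms window at 1 kHz: 5 Hz resolution, theta band uses bins {5, 10}
  est2 <- list(freqs = seq(0, 500, by = 5),
               values = seq(0, 500, by = 5))
  expect_equal(band_average(est2, c(4, 12)), 7.5)
  expect_error(band_average(est, c(600, 700)), "invalid band")
})

test_that("repeat-averaged equalised coherence is less variable than single", {
  withr::with_seed(9, {
    single <- numeric(8)
    averaged <- numeric(8)
    for (i in 1:8) {
      a <- make_segments(60, rate_hz = 30, locking = 0.5,
                         seed = 100 + i)
      b <- make_segments(40, rate_hz = 30, locking = 0.5,
                         seed = 200 + i)
      reps <- equalize_condition_samples(a, b, n_repeats = 10,
                                         seed = 300 + i)
      vals <- vapply(reps, function(r) {
        band_average(spike_field_coherence(r$a), c(4, 12))
      }, numeric(1))
      single[i] <- vals[1]
      averaged[i] <- mean(vals)
    }
  })
  expect_lt(var(averaged), var(single))
})

test_that("condition-equalised pair analysis recovers planted desynchronisation", {
  w <- small_world()
  cp <- coherence_pair(w$session, unit_id = 1, channel_id = 2, seed = 10)
  expect_true(is.finite(cp$desync_index))
  expect_true(all(cp$coh_target >= 0 & cp$coh_target <= 1, na.rm = TRUE))
  # axis unit 1 has locking 0.6 (distractor) vs 0.2 (target) planted
  if (w$truth$units$is_axis[1]) {
    expect_gt(cp$theta_distractor, cp$theta_target)
  }
})
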