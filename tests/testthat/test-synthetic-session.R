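test_that("stimulus features are seed-deterministic with category structure", {
  a <- generate_stimulus_features(40, 512, separation = 4, seed = 1)
  b <- generate_stimulus_features(40, 512, separation = 4, seed = 1)
  expect_identical(a$features, b$features)
  expect_equal(length(a$stimulus_id), 160)
  expect_true(all(table(a$category) == 40))
  expect_true(all(is.finite(a$features)))
  expect_error(generate_stimulus_features(0, 512), "positive")
})

test_that("zero separation plants no category signal", {
  ss <- generate_stimulus_features(20, 64, separation = 0, seed = 3)
  grand <- colMeans(ss$features)
  between <- 0
  within <- 0
  for (cat in levels(ss$category)) {
    rows <- ss$features[ss$category == cat, , drop = FALSE]
    between <- between + nrow(rows) * sum((colMeans(rows) - grand)^2)
    within <- within + sum(sweep(rows, 2, colMeans(rows))^2)
  }
  # between/within variance ratio at its chance level (roughly D*(k-1)/N)
  expect_lt(between / within, 0.05)
})

test_that("default separation supports near-perfect linear category readout", {
  ss <- generate_stimulus_features(40, 512, separation = 4, seed = 2)
  withr::with_seed(9, {
    train <- sort(sample(160, 80))
  })
  test_idx <- setdiff(1:160, train)
  # linear readout oracle: nearest centroid in the subspace spanned by the
  # training class-centroid contrasts (a supervised linear classifier)
  cents <- sapply(levels(ss$category), function(cat) {
    colMeans(ss$features[intersect(train, which(ss$category == cat)), ,
                         drop = FALSE])
  })
  Q <- qr.Q(qr(sweep(cents, 1, rowMeans(cents))))[, 1:3]
  tr_p <- ss$features[train, ] %*% Q
  te_p <- ss$features[test_idx, ] %*% Q
  cc <- sapply(levels(ss$category), function(cat) {
    colMeans(tr_p[ss$category[train] == cat, , drop = FALSE])
  })
  d2 <- sapply(seq_len(ncol(cc)), function(k) {
    rowSums(sweep(te_p, 2, cc[, k])^2)
  })
  pred <- levels(ss$category)[apply(d2, 1, which.min)]
  acc <- mean(pred == as.character(ss$category[test_idx]))
  expect_gt(acc, 0.95)
})

test_that("unit population plants axis structure as configured", {
  w <- small_world()
  cfg0 <- w$cfg

  cfg_none <- synthetic_config(n_stimuli_per_category = 10, D = 64,
                               n_units = c(V4 = 2, TEO = 2, TE = 2, OFC = 2),
                               n_trials = 5, fraction_axis = 0)
  gt0 <- generate_unit_population(cfg_none, w$stimuli, seed = 5)
  expect_true(all(gt0$axis_weights == 0))
  expect_true(all(!gt0$units$is_axis))

  cfg_all <- synthetic_config(n_stimuli_per_category = 10, D = 64,
                              n_units = c(V4 = 2, TEO = 2, TE = 2, OFC = 2),
                              n_trials = 5, fraction_axis = 1)
  gt1 <- generate_unit_population(cfg_all, w$stimuli, seed = 5)
  expect_true(all(gt1$units$is_axis))
  # noiseless construction: each planted rate profile is a monotone
  # (softplus) transform of its own linear predictor, so the rank
  # correlation is exact and the Pearson correlation stays high
  for (i in seq_len(nrow(gt1$units))) {
    z <- drop(w$stimuli$features %*% gt1$axis_weights[i, ])
    expect_equal(cor(gt1$stim_rates[i, ], z, method = "spearman"), 1)
    expect_gt(abs(cor(gt1$stim_rates[i, ], z)), 0.9)
  }

  # axis units track the feature PC1 more strongly than non-axis units
  gt <- w$truth
  pc1 <- prcomp(w$stimuli$features)$x[, 1]
  r <- abs(apply(gt$stim_rates, 1, cor, y = pc1))
  expect_gt(median(r[gt$units$is_axis]), median(r[!gt$units$is_axis]))
})

test_that("session timeline and arrays respect the task design", {
  w <- small_world()
  s <- w$session
  ar <- s$arrays
  per_trial <- split(ar, ar$trial_id)
  expect_true(all(vapply(per_trial, nrow, 0L) == 11L))
  expect_true(all(vapply(per_trial, function(x) sum(x$is_target), 0L) == 2L))
  # locations distinct within an array
  expect_true(all(vapply(per_trial, function(x) {
    length(unique(x$location_id)) == 11L
  }, logical(1))))
  # targets share the cue's category
  cues <- s$events[s$events$event_type == "cue_on", ]
  cue_cat <- w$stimuli$category[match(cues$stimulus_id,
                                      w$stimuli$stimulus_id)]
  for (tr in cues$trial_id) {
    tgt <- ar$stimulus_id[ar$trial_id == tr & ar$is_target]
    expect_true(all(w$stimuli$category[match(tgt, w$stimuli$stimulus_id)] ==
                      cue_cat[cues$trial_id == tr]))
  }
  # events within a trial do not overlap; fixations carry stimulus + role
  for (tr in unique(s$events$trial_id)) {
    ev <- s$events[s$events$trial_id == tr, ]
    ev <- ev[ev$event_type != "array_on", ]  # array epoch spans fixations
    ev <- ev[order(ev$t_on_ms), ]
    expect_true(all(diff(as.vector(rbind(ev$t_on_ms, ev$t_off_ms))) >= 0))
  }
  fx <- s$events[s$events$event_type == "fixation", ]
  expect_true(all(!is.na(fx$stimulus_id)))
  expect_true(all(!is.na(fx$is_target)))
  expect_true(all(fx$t_off_ms - fx$t_on_ms >= 80))
  # spikes sorted and inside the session
  for (u in s$units) {
    expect_true(!is.unsorted(u$spike_times))
    expect_true(all(u$spike_times >= 0 & u$spike_times <= s$duration_ms))
  }
})

test_that("session generation is a pure function of its seed", {
  w <- small_world()
  s2 <- generate_session(w$cfg, w$stimuli, w$truth, seed = 13)
  expect_identical(w$session$events, s2$events)
  expect_identical(w$session$units[[3]]$spike_times,
                   s2$units[[3]]$spike_times)
  expect_identical(w$session$lfp[[5]]$samples, s2$lfp[[5]]$samples)
})

test_that("spike counts in known-rate periods obey Poisson statistics", {
  w <- small_world()
  s <- w$session
  # during the initial fixation the rate is 0.5 * baseline by construction
  init <- s$events[s$events$event_type == "initial_fixation", ]
  for (i in c(1, 5)) {
    u <- s$units[[i]]
    expected <- 0.5 * w$truth$units$baseline_rate[i] *
      sum(init$t_off_ms - init$t_on_ms) / 1000
    got <- sum(fixsearch:::count_in_windows(u$spike_times, init$t_on_ms,
                                            init$t_off_ms))
    expect_lt(abs(got - expected), 3 * sqrt(expected) + 1)
  }
})

test_that("unit attentional gain is expressed only in the late window", {
  # gain = 1 everywhere: late-window target/distractor difference is noise
  cfg <- synthetic_config(n_stimuli_per_category = 10, D = 16,
                          n_units = c(V4 = 2, TEO = 1, TE = 1, OFC = 1),
                          n_trials = 60, attention_gain = 1,
                          locking_target = 0.4, locking_distractor = 0.4)
  ss <- generate_stimulus_features(10, 16, seed = 21)
  gt <- generate_unit_population(cfg, ss, seed = 22)
  s <- generate_session(cfg, ss, gt, seed = 23)
  frm <- fixation_rate_matrix(s, rate_window("attention"))
  p <- sapply(seq_along(s$units), function(i) {
    t.test(frm$rates[frm$fixations$is_target, i],
           frm$rates[!frm$fixations$is_target, i])$p.value
  })
  # no unit shows an effect beyond multiple-comparison noise
  expect_gt(min(p) * length(p), 0.01)
})

test_that("session round-trips through the directory layout", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_session(w$session, dir, stimuli = w$stimuli, truth = w$truth)
  s2 <- read_session(dir)
  expect_equal(s2$events$t_on_ms, w$session$events$t_on_ms)
  expect_equal(s2$events$event_type, w$session$events$event_type)
  expect_equal(length(s2$units), length(w$session$units))
  for (i in seq_along(s2$units)) {
    expect_equal(s2$units[[i]]$spike_times,
                 w$session$units[[i]]$spike_times, tolerance = 1e-6)
  }
  # LFP equal up to float32 representation
  expect_equal(s2$lfp[[1]]$samples, w$session$lfp[[1]]$samples,
               tolerance = 1e-6)
  expect_equal(attr(s2, "stimuli")$features, w$stimuli$features,
               ignore_attr = TRUE)

  file.remove(file.path(dir, "events.csv"))
  expect_error(read_session(dir), "events.csv not found")
})

test_that("a hand-written two-unit toy layout reads into a session", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "spikes"))
  dir.create(file.path(dir, "lfp"))
  writeLines(c(
    "trial_id,event_type,t_on_ms,t_off_ms,stimulus_id,is_target,location_id",
    "1,initial_fixation,0,400,NA,NA,NA",
    "1,cue_on,400,1000,1,NA,NA",
    "1,fixation,1600,1800,2,TRUE,5"
  ), file.path(dir, "events.csv"))
  writeLines(c("unit_id,area,electrode_id", "1,V4,1", "2,TE,1"),
             file.path(dir, "units.csv"))
  writeLines(c("spike_time_ms", "10.5", "20"),
             file.path(dir, "spikes/unit_1.csv"))
  writeLines("spike_time_ms", file.path(dir, "spikes/unit_2.csv"))
  writeLines(c("channel_id,area,electrode_id,fs_hz,n_samples", "1,V4,2,1000,100"),
             file.path(dir, "lfp_meta.csv"))
  con <- file(file.path(dir, "lfp/channel_1.f32"), "wb")
  writeBin(as.numeric(1:100), con, size = 4L, endian = "little")
  close(con)
  s <- read_session(dir)
  expect_equal(length(s$units), 2L)
  expect_equal(s$units[[1]]$spike_times, c(10.5, 20))
  expect_equal(length(s$units[[2]]$spike_times), 0L)
  expect_equal(s$lfp[[1]]$samples, as.numeric(1:100))
})
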