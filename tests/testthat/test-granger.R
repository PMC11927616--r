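test_that("preprocessing removes trends, ensemble mean and segment means", {
  ramps <- lapply(1:4, function(i) i * (1:100) + i)
  pp <- preprocess_segments(ramps, lapply(1:4, function(i) numeric(0)),
                            fs = 1000)
  expect_true(all(abs(unlist(pp$y)) < 1e-10))

  same <- lapply(1:5, function(i) sin((1:200) / 10))
  pp2 <- preprocess_segments(same, lapply(1:5, function(i) c(10, 50)),
                             fs = 1000)
  expect_true(all(abs(unlist(pp2$y)) < 1e-10))

  withr::with_seed(1, {
    segs <- lapply(1:6, function(i) cumsum(rnorm(200)))
    spk <- lapply(1:6, function(i) runif(8, 0, 200))
  })
  pp3 <- preprocess_segments(segs, spk, fs = 1000)
  expect_true(all(abs(vapply(pp3$x, mean, 0)) < 1e-10))
  expect_error(preprocess_segments(segs[1], spk[1]), "insufficient")
})

test_that("KPSS screen is calibrated against its published critical value", {
  withr::with_seed(2, {
    wn <- mean(replicate(400, kpss_screen(rnorm(200))$stationary))
    rw <- mean(replicate(200, kpss_screen(cumsum(rnorm(200)))$stationary))
  })
  expect_gt(wn, 0.90)   # ~95% of white noise accepted at the 5% level
  expect_lt(wn, 0.99)
  expect_lt(rw, 0.5)    # random walks mostly rejected
  const <- kpss_screen(rep(3, 100))
  expect_equal(const$statistic, 0)
  expect_true(const$stationary)
  expect_error(kpss_screen(rnorm(20)), "insufficient")
})

test_that("VAR fit recovers known coefficients and selects the right order", {
  A <- list(matrix(c(0.5, 0.0, 0.4, 0.3), 2, 2),
            matrix(c(-0.2, 0.0, 0.2, 0.1), 2, 2))
  pairs <- simulate_var2(A, T = 10000, seed = 3)
  m <- fit_var(pairs, max_order = 6)
  expect_equal(m$order, 2L)
  # coefficient recovery within ~3 SE at T = 10,000
  expect_lt(max(abs(m$A[, , 1] - A[[1]])), 0.05)
  expect_lt(max(abs(m$A[, , 2] - A[[2]])), 0.05)
  expect_true(fixsearch:::companion_radius(m$A) < 1)

  # independent white noise: off-diagonal coefficients near zero
  wn <- simulate_var2(list(matrix(0, 2, 2)), T = 5000, seed = 4)
  m0 <- fit_var(wn, order = 1)
  expect_lt(max(abs(m0$A[1, 2, 1]), abs(m0$A[2, 1, 1])), 0.05)

  const <- list(x = list(rep(1, 500)), y = list(rep(2, 500)), fs = 1000)
  expect_error(fit_var(const), "degenerate")
})

test_that("VAR pooling respects segment boundaries", {
  A <- list(matrix(c(0.6, 0.2, -0.3, 0.4), 2, 2))
  long <- simulate_var2(A, T = 8000, seed = 5)
  x <- long$x[[1]]; y <- long$y[[1]]
  cut <- function(v) split(v, rep(1:40, each = 200))
  segged <- list(x = unname(cut(x)), y = unname(cut(y)), fs = 1000)
  m <- fit_var(segged, order = 1)
  expect_equal(m$A[, , 1], A[[1]], tolerance = 0.06)
})

test_that("spectral GC is non-negative, directional and Geweke-consistent", {
  # unidirectional coupling x -> y
  A <- list(matrix(c(0.5, 0.4, 0.0, 0.3), 2, 2),
            matrix(c(-0.2, 0.2, 0.0, 0.1), 2, 2))
  pairs <- simulate_var2(A, T = 10000, seed = 6)
  m <- fit_var(pairs, max_order = 6)
  g <- spectral_granger(m, freqs = seq(0, 500, by = 1))
  expect_true(all(g$gc_x_to_y >= 0))
  expect_true(all(g$gc_y_to_x >= 0))
  fwd <- mean(g$gc_x_to_y)
  rev <- mean(g$gc_y_to_x)
  expect_lt(rev, 0.1 * fwd)
  td <- time_domain_granger_oracle(pairs, order = m$order)
  expect_equal(fwd, td$x_to_y, tolerance = 0.05 * td$x_to_y)

  # no coupling: both directions near zero
  d <- list(matrix(c(0.5, 0, 0, 0.5), 2, 2))
  m0 <- fit_var(simulate_var2(d, T = 10000, seed = 7), order = 1)
  g0 <- spectral_granger(m0)
  expect_lt(mean(g0$gc_x_to_y), 0.005)
  expect_lt(mean(g0$gc_y_to_x), 0.005)
})

test_that("time-domain oracle grows monotonically with coupling strength", {
  vals <- sapply(c(0.1, 0.3, 0.6), function(c) {
    A <- list(matrix(c(0.5, c, 0, 0.3), 2, 2))
    time_domain_granger_oracle(simulate_var2(A, T = 6000, seed = 8),
                               order = 1)$x_to_y
  })
  expect_true(all(diff(vals) > 0))
  ind <- simulate_var2(list(matrix(0, 2, 2)), T = 6000, seed = 9)
  expect_lt(abs(time_domain_granger_oracle(ind, order = 1)$x_to_y), 0.005)
})

test_that("GC band contrast arithmetic and grid checks", {
  freqs <- seq(0, 500, by = 5)
  mk <- function(v) structure(list(freqs = freqs,
                                   gc_x_to_y = rep(v, length(freqs)),
                                   gc_y_to_x = rep(v / 2, length(freqs))),
                              class = "gc_estimate")
  eq <- gc_contrast(mk(0.4), mk(0.4))
  expect_equal(eq$x_to_y, 0)
  dbl <- gc_contrast(mk(0.4), mk(0.2))
  expect_equal(dbl$x_to_y, 1 / 3)
  bad <- mk(0.4); bad$freqs <- freqs + 1
  expect_error(gc_contrast(mk(0.4), bad), "grids")
})

test_that("session-level GC pair shows target-induced reduction", {
  w <- small_world()
  gp <- granger_pair(w$session, unit_id = 1, channel_id = 2)
  expect_true(is.finite(gp$contrast$x_to_y))
  expect_true(all(gp$gc_target$gc_x_to_y >= 0))
  if (w$truth$units$is_axis[1]) {
    # planted locking drop on targets reduces spike-LFP coupling
    expect_gt(gp$contrast$x_to_y, 0)
  }
})
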