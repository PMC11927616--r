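#' Preprocess LFP and spike segments for VAR fitting
#'
#' Per segment, the LFP has its least-squares line subtracted (detrend) and
#' then the across-segment ensemble mean subtracted sample-wise; spikes are
#' binned as counts at the sampling rate and demeaned per segment.
#'
#' @param lfp_segments List of numeric vectors (equal length).
#' @param spike_segments List of spike-time vectors (ms within segment),
#'   same length as `lfp_segments`.
#' @param fs Sampling rate, Hz.
#' @return List: `x` (spike count segments), `y` (LFP segments), `fs`.
#' @export
preprocess_segments <- function(lfp_segments, spike_segments, fs = 1000) {
  m <- length(lfp_segments)
  if (m < 2L) {
    stop("insufficient data: ensemble mean needs at least 2 segments",
         call. = FALSE)
  }
  n <- length(lfp_segments[[1L]])
  tt <- seq_len(n)
  tc <- tt - mean(tt)
  ss <- sum(tc^2)
  detr <- lapply(lfp_segments, function(y) {
    slope <- sum(tc * y) / ss
    y - mean(y) - slope * tc
  })
  ens <- Reduce(`+`, detr) / m
  y <- lapply(detr, function(v) v - ens)
  x <- lapply(spike_segments, function(sp) {
    v <- bin_spikes(sp, n, fs)
    v - mean(v)
  })
  list(x = x, y = y, fs = fs)
}

#' KPSS level-stationarity screen
#'
#' KPSS statistic under the level-stationarity null: partial sums of the
#' demeaned series, normalised by a Bartlett-kernel long-run variance with
#' lag `floor(4 * (T/100)^(1/4))`. The segment is flagged nonstationary
#' when the statistic exceeds 0.463, the 5% critical value.
#'
#' @param segment Numeric vector, length at least 50.
#' @param lag Bartlett truncation lag; default the rule above.
#' @return List: `statistic`, `stationary` (flag), `lag`.
#' @export
kpss_screen <- function(segment, lag = NULL) {
  x <- as.numeric(segment)
  T <- length(x)
  if (T < 50L) {
    stop("insufficient data: KPSS needs at least 50 samples", call. = FALSE)
  }
  if (is.null(lag)) lag <- floor(4 * (T / 100)^0.25)
  e <- x - mean(x)
  S <- cumsum(e)
  g0 <- sum(e^2) / T
  lrv <- g0
  if (lag > 0) {
    for (j in seq_len(lag)) {
      gj <- sum(e[(j + 1):T] * e[1:(T - j)]) / T
      lrv <- lrv + 2 * (1 - j / (lag + 1)) * gj
    }
  }
  stat <- if (lrv <= 0) 0 else sum(S^2) / (T^2 * lrv)
  if (g0 == 0) stat <- 0  # constant series
  list(statistic = stat, stationary = stat <= 0.463, lag = lag)
}

#' Fit a bivariate VAR pooled across segments
#'
#' Least-squares fit of a 2-variable VAR with the model order selected by
#' AIC over `1..max_order`. Lagged design rows never cross segment
#' boundaries (each segment contributes rows `p+1..T` only). Inputs are
#' assumed demeaned, so no intercept is fitted. The fit is checked for
#' stability (companion-matrix spectral radius < 1).
#'
#' @param pairs Output of [preprocess_segments()] (fields `x`, `y`, `fs`),
#'   or a list with those fields.
#' @param max_order Largest order tried (default 15).
#' @param order Fixed order; skips AIC selection when given.
#' @return A `var_model`: list with `order`, `A` (`[2 x 2 x p]`
#'   coefficient array, rows = equation/receiver), `Sigma` (noise
#'   covariance), `fs`, `aic` (per tried order).
#' @export
fit_var <- function(pairs, max_order = 15, order = NULL) {
  segs <- Map(function(x, y) cbind(x = x, y = y), pairs$x, pairs$y)
  T_tot <- sum(vapply(segs, nrow, 0L))
  orders <- if (is.null(order)) seq_len(max_order) else order
  aic <- rep(NA_real_, length(orders))
  best <- NULL
  for (k in seq_along(orders)) {
    p <- orders[k]
    if (T_tot <= 10 * (4 * p + 2)) next
    f <- var_ls(segs, p)
    if (is.null(f)) next
    aic[k] <- log(det(f$Sigma)) + 2 * (4 * p) / f$n_rows
    if (is.null(best) || aic[k] < best$aic) {
      best <- c(f, list(order = p, aic = aic[k]))
    }
  }
  if (is.null(best)) {
    stop("degenerate input: no VAR order could be fitted", call. = FALSE)
  }
  A <- array(0, c(2, 2, best$order))
  for (l in seq_len(best$order)) {
    A[, , l] <- t(best$B[(2 * l - 1):(2 * l), ])
  }
  if (companion_radius(A) >= 1) {
    stop("unstable model: companion spectral radius >= 1", call. = FALSE)
  }
  structure(list(order = best$order, A = A, Sigma = best$Sigma,
                 fs = pairs$fs, aic = stats::setNames(aic, orders)),
            class = "var_model")
}

# Pooled LS for one order; returns NULL on rank deficiency.
var_ls <- function(segs, p) {
  Xs <- list(); Ys <- list()
  for (s in segs) {
    T <- nrow(s)
    if (T <= p) next
    rows <- (p + 1):T
    lagmat <- do.call(cbind, lapply(seq_len(p), function(l) {
      s[rows - l, , drop = FALSE]
    }))
    Xs[[length(Xs) + 1L]] <- lagmat
    Ys[[length(Ys) + 1L]] <- s[rows, , drop = FALSE]
  }
  X <- do.call(rbind, Xs)
  Y <- do.call(rbind, Ys)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  B <- qr.coef(qrX, Y)           # (2p) x 2
  res <- Y - X %*% B
  n <- nrow(X)
  Sigma <- crossprod(res) / (n - ncol(X))
  if (det(Sigma) <= 0) return(NULL)
  list(B = B, Sigma = Sigma, n_rows = n)
}

companion_radius <- function(A) {
  p <- dim(A)[3]
  k <- 2 * p
  C <- matrix(0, k, k)
  for (l in seq_len(p)) C[1:2, (2 * l - 1):(2 * l)] <- A[, , l]
  if (p > 1) C[3:k, 1:(k - 2)] <- diag(k - 2)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Frequency-domain Granger causality from a VAR model
#'
#' Computes the spectral transfer matrix
#' `H(f) = (I - sum_k A_k e^(-i 2 pi f k / fs))^(-1)` and spectral matrix
#' `S(f) = H Sigma H*`, then the directed measure
#' `G_{j->i}(f) = -ln(1 - (Sigma_jj - Sigma_ij^2 / Sigma_ii) |H_ij(f)|^2 /
#' S_ii(f))` at each frequency. Values are non-negative; tiny negative
#' rounding is clamped to 0.
#'
#' @param model A `var_model` (variable 1 = x, variable 2 = y).
#' @param freqs Hz grid; default `seq(0, fs/2, by = fs/200)` to match the
#'   coherence module's 200-sample window resolution.
#' @return A `gc_estimate`: list with `freqs`, `gc_x_to_y`, `gc_y_to_x`.
#' @export
spectral_granger <- function(model, freqs = NULL) {
  fs <- model$fs
  if (is.null(freqs)) freqs <- seq(0, fs / 2, by = fs / 200)
  p <- model$order
  A <- model$A
  Sg <- model$Sigma
  gxy <- gyx <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    z <- exp(-1i * 2 * pi * freqs[k] * seq_len(p) / fs)
    Af <- diag(2) + 0i
    for (l in seq_len(p)) Af <- Af - A[, , l] * z[l]
    H <- tryCatch(solve(Af), error = function(e) NULL)
    if (is.null(H)) {
      stop("numeric conditioning failure inverting transfer matrix at ",
           freqs[k], " Hz", call. = FALSE)
    }
    S <- H %*% Sg %*% Conj(t(H))
    # x -> y: source j = 1, receiver i = 2
    gxy[k] <- gc_formula(Sg[1, 1], Sg[2, 2], Sg[1, 2], H[2, 1], S[2, 2])
    # y -> x: source j = 2, receiver i = 1
    gyx[k] <- gc_formula(Sg[2, 2], Sg[1, 1], Sg[1, 2], H[1, 2], S[1, 1])
  }
  structure(list(freqs = freqs, gc_x_to_y = gxy, gc_y_to_x = gyx),
            class = "gc_estimate")
}

gc_formula <- function(sig_jj, sig_ii, sig_ij, H_ij, S_ii) {
  val <- 1 - (sig_jj - sig_ij^2 / sig_ii) * Mod(H_ij)^2 / Re(S_ii)
  g <- -log(max(val, .Machine$double.eps))
  max(g, 0)
}

#' Time-domain Granger causality oracle
#'
#' The Geweke time-domain measure: `ln(var_restricted / var_full)` of the
#' receiving variable's residuals, where the restricted model regresses the
#' receiver on its own lags only and the full model adds the sender's
#' lags. Used as an independent cross-check: the frequency-integrated
#' spectral measure should match this on long stationary series.
#'
#' @param pairs As for [fit_var()].
#' @param order VAR order; default selected by AIC via [fit_var()].
#' @return List: `x_to_y`, `y_to_x`, `order`.
#' @export
time_domain_granger_oracle <- function(pairs, order = NULL) {
  if (is.null(order)) order <- fit_var(pairs)$order
  segs <- Map(function(x, y) cbind(x = x, y = y), pairs$x, pairs$y)
  full <- var_ls(segs, order)
  if (is.null(full)) stop("degenerate input", call. = FALSE)
  restricted_var <- function(target) {
    Xs <- list(); Ys <- list()
    for (s in segs) {
      T <- nrow(s)
      if (T <= order) next
      rows <- (order + 1):T
      lagmat <- do.call(cbind, lapply(seq_len(order), function(l) {
        s[rows - l, target]
      }))
      Xs[[length(Xs) + 1L]] <- lagmat
      Ys[[length(Ys) + 1L]] <- s[rows, target]
    }
    X <- do.call(rbind, Xs)
    yv <- unlist(Ys)
    r <- stats::lsfit(X, yv, intercept = FALSE)$residuals
    sum(r^2) / (length(yv) - order)
  }
  list(
    x_to_y = log(restricted_var(2L) / full$Sigma[2, 2]),
    y_to_x = log(restricted_var(1L) / full$Sigma[1, 1]),
    order = order
  )
}

#' Band-limited Granger-causality contrast between conditions
#'
#' Band-means each estimate and forms
#' `(GC_distractor - GC_target) / (GC_distractor + GC_target)` per
#' direction (positive = target-induced reduction).
#'
#' @param gc_distractor,gc_target `gc_estimate` objects on matching grids.
#' @param band Hz band (default theta, `c(4, 12)`).
#' @return List: `x_to_y`, `y_to_x` (contrasts), plus the band means.
#' @export
gc_contrast <- function(gc_distractor, gc_target, band = c(4, 12)) {
  if (!isTRUE(all.equal(gc_distractor$freqs, gc_target$freqs))) {
    stop("invalid argument: frequency grids do not match", call. = FALSE)
  }
  bm <- function(est, dir) {
    band_average(list(freqs = est$freqs, values = est[[dir]]), band)
  }
  d_xy <- bm(gc_distractor, "gc_x_to_y")
  t_xy <- bm(gc_target, "gc_x_to_y")
  d_yx <- bm(gc_distractor, "gc_y_to_x")
  t_yx <- bm(gc_target, "gc_y_to_x")
  list(
    x_to_y = normalized_contrast(d_xy, t_xy),
    y_to_x = normalized_contrast(d_yx, t_yx),
    band_means = c(distractor_x_to_y = d_xy, target_x_to_y = t_xy,
                   distractor_y_to_x = d_yx, target_y_to_x = t_yx)
  )
}

#' Condition-wise spectral Granger causality for one spike-LFP pair
#'
#' Extracts fixation segments per condition, preprocesses (detrend,
#' ensemble demean, spike binning), drops segments whose LFP fails the
#' KPSS stationarity screen, fits a pooled bivariate VAR per condition and
#' returns the spectral GC estimates plus the theta-band contrast.
#' Direction `x_to_y` is spikes -> LFP.
#'
#' @param session A `session`.
#' @param unit_id,channel_id Spike and LFP sources (different electrodes).
#' @param band Hz band for the contrast (default `c(4, 12)`).
#' @param max_order Passed to [fit_var()] (default 8 at session scale).
#' @param kpss Apply the stationarity screen (default `TRUE`).
#' @return List: `gc_target`, `gc_distractor` (`gc_estimate`s),
#'   `contrast` (from [gc_contrast()]), `n_excluded` per condition.
#' @export
granger_pair <- function(session, unit_id, channel_id, band = c(4, 12),
                         max_order = 8, kpss = TRUE) {
  fix <- session$events[session$events$event_type == "fixation", ]
  one <- function(cond) {
    segs <- extract_fixation_segments(session, fix[fix$is_target == cond, ],
                                      channel_id, unit_id)
    pp <- preprocess_segments(lapply(segs, `[[`, "lfp"),
                              lapply(segs, `[[`, "spikes"),
                              fs = attr(segs, "fs"))
    if (kpss) {
      ok <- vapply(pp$y, function(y) kpss_screen(y)$stationary, logical(1))
      pp$x <- pp$x[ok]
      pp$y <- pp$y[ok]
      excl <- sum(!ok)
    } else excl <- 0L
    model <- fit_var(pp, max_order = max_order)
    list(gc = spectral_granger(model), n_excluded = excl)
  }
  tgt <- one(TRUE)
  dst <- one(FALSE)
  list(gc_target = tgt$gc, gc_distractor = dst$gc,
       contrast = gc_contrast(dst$gc, tgt$gc, band),
       n_excluded = c(target = tgt$n_excluded,
                      distractor = dst$n_excluded))
}
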