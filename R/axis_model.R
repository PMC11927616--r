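#' Fit a partial-least-squares encoding model (SIMPLS, univariate response)
#'
#' Fits firing rate as a linear function of a high-dimensional stimulus
#' feature matrix using PLS regression. Because the feature dimension (e.g.
#' 512 deep-network activations) typically exceeds the number of stimuli,
#' ordinary least squares is ill-posed; PLS extracts a small number of
#' latent components that maximise covariance with the response. Components
#' follow the SIMPLS criterion with centred `X` and `y`; for a univariate
#' response SIMPLS and NIPALS coincide up to scaling.
#'
#' @param features Numeric matrix `[n_stimuli x D]` of stimulus features.
#' @param rates Numeric vector of length `n_stimuli` (response per stimulus).
#' @param n_components Number of latent components (default 4).
#' @return A `pls_fit` object: list with `coefficients` (length `D`),
#'   `intercept`, `x_center`, `n_components`, and a `predict` method via
#'   [predict.pls_fit()].
#' @export
fit_pls_encoding <- function(features, rates, n_components = 4) {
  X <- as.matrix(features)
  y <- as.numeric(rates)
  n <- nrow(X)
  if (length(y) != n) stop("features/rates length mismatch", call. = FALSE)
  if (n <= n_components) {
    stop("insufficient data: need more observations than components",
         call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("degenerate response: rates have zero variance", call. = FALSE)
  }
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2L, xm, check.margin = FALSE)
  yc <- y - ym
  B <- simpls_coef(Xc, yc, n_components)
  structure(
    list(coefficients = B, intercept = ym, x_center = xm,
         n_components = n_components),
    class = "pls_fit"
  )
}

# SIMPLS core on pre-centred data, univariate y. Returns the D-vector of
# regression coefficients. Kept lean: this sits inside permutation loops.
simpls_coef <- function(Xc, yc, ncomp) {
  D <- ncol(Xc)
  s <- crossprod(Xc, yc)            # D x 1
  R <- matrix(0, D, ncomp)
  Q <- numeric(ncomp)
  V <- matrix(0, D, ncomp)
  for (a in seq_len(ncomp)) {
    r <- s                          # univariate: dominant direction is s
    t <- Xc %*% r
    nt <- sqrt(sum(t * t))
    if (nt < .Machine$double.eps^0.5) {
      # response variance exhausted; stop early
      R <- R[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[seq_len(a - 1L)]
      break
    }
    t <- t / nt
    r <- r / nt
    p <- crossprod(Xc, t)           # loading
    q <- sum(yc * t)
    v <- p
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p)
    }
    nv <- sqrt(sum(v * v))
    if (nv < .Machine$double.eps^0.5) {
      R <- R[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[seq_len(a - 1L)]
      break
    }
    v <- v / nv
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r
    Q[a] <- q
    V[, a] <- v
  }
  drop(R %*% Q)
}

#' Predict from a PLS encoding fit
#'
#' @param object A `pls_fit` from [fit_pls_encoding()].
#' @param newdata Feature matrix `[m x D]` (or a single feature vector).
#' @param ... Unused.
#' @return Predicted rates, length `m`.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else
    as.matrix(newdata)
  drop(sweep(X, 2L, object$x_center, check.margin = FALSE) %*%
         object$coefficients) + object$intercept
}

#' Split-and-permute significance test for axis coding
#'
#' Decides whether a unit encodes a linear combination of stimulus features
#' (an "axis-coding" unit). On each of `n_perm` runs a random 50/50
#' train/test split of the stimuli is drawn; a PLS encoding model is fitted
#' on the training half and the Pearson correlation between predicted and
#' actual rates on the held-out half is recorded, once with the true
#' stimulus labels (`r_obs`) and once with the rate vector shuffled against
#' the feature rows before splitting (`r_null`). The unit is flagged as
#' axis-coding when the observed correlation exceeds the 95th percentile of
#' the null distribution; the observed correlation also serves as the
#' strength of axis coding.
#'
#' By default the observed statistic is the held-out correlation of a
#' single split, which makes it exchangeable with the single-split null
#' draws and calibrates the percentile rule exactly at its nominal 5%
#' false-flag rate. Averaging the observed statistic over the whole split
#' ensemble (`observed = "ensemble"`) reduces split-choice variance but
#' shrinks its null variance below that of the null draws, making the
#' selection conservative.
#'
#' @param features Numeric matrix `[n_stimuli x D]`.
#' @param rates Numeric vector, length `n_stimuli`.
#' @param n_components PLS components (default 4).
#' @param n_perm Number of permutation runs (default 1000).
#' @param seed Integer seed; the test is deterministic given the seed.
#' @param observed One of `"single"` (default: observed statistic from the
#'   first split) or `"ensemble"` (averaged over the same split ensemble
#'   as the null).
#' @return An `axis_fit` object: list with `n_components`, `r_observed`,
#'   `r_null` (the null distribution), `p_perm`, `is_axis`, `strength`
#'   (= `r_observed`) and `coefficients` (from a fit on all stimuli).
#' @export
axis_permutation_test <- function(features, rates, n_components = 4,
                                  n_perm = 1000, seed = 1,
                                  observed = c("single", "ensemble")) {
  observed <- match.arg(observed)
  X <- as.matrix(features)
  y <- as.numeric(rates)
  n <- nrow(X)
  if (n < 20L) {
    stop("insufficient data: need at least 20 stimuli with responses",
         call. = FALSE)
  }
  if (length(y) != n) stop("features/rates length mismatch", call. = FALSE)
  n_train <- floor(n / 2)
  r_obs <- numeric(n_perm)
  r_null <- numeric(n_perm)
  # All SIMPLS quantities live in the span of the training rows, so the
  # permutation loop runs in the n x n Gram space (n << D): the Gram matrix
  # is computed once per unit and each split only re-centres submatrices.
  G <- tcrossprod(X)
  withr::with_seed(seed, {
    for (k in seq_len(n_perm)) {
      idx <- sample.int(n, n_train)
      ks <- split_gram(G, idx)
      r_obs[k] <- held_out_r_gram(ks, y, idx, n_components)
      y_sh <- y[sample.int(n)]
      r_null[k] <- held_out_r_gram(ks, y_sh, idx, n_components)
    }
  })
  r_observed <- if (observed == "ensemble") mean(r_obs) else r_obs[1L]
  p_perm <- mean(r_null >= r_observed)
  is_axis <- r_observed > stats::quantile(r_null, 0.95, names = FALSE)
  full <- fit_pls_encoding(X, y, n_components)
  structure(
    list(n_components = n_components, r_observed = r_observed,
         r_obs_runs = r_obs, r_null = r_null, p_perm = p_perm,
         is_axis = is_axis, strength = r_observed,
         coefficients = full$coefficients),
    class = "axis_fit"
  )
}

# Centred Gram blocks for one train/test split: K = Xc_tr Xc_tr' and
# K_et = Xc_te Xc_tr', where centring uses the training column means.
split_gram <- function(G, train_idx) {
  Gtt <- G[train_idx, train_idx, drop = FALSE]
  Get <- G[-train_idx, train_idx, drop = FALSE]
  n <- length(train_idx)
  cm <- colMeans(Gtt)            # (1/n) 1'Gtt
  mm <- mean(cm)                 # (1/n^2) 1'Gtt 1
  K <- Gtt - outer(rowMeans(Gtt), rep(1, n)) - outer(rep(1, n), cm) + mm
  Ket <- Get - outer(rowMeans(Get), rep(1, n)) -
    outer(rep(1, nrow(Get)), cm) + mm
  list(K = K, Ket = Ket)
}

# Held-out Pearson r for one split, computed entirely in Gram space.
# Dual SIMPLS: every feature-space vector (s, p, v, r) is Xc' alpha for a
# dual vector alpha, and inner products become alpha' K beta. Matches the
# primal held_out_r() to rounding.
held_out_r_gram <- function(ks, y, train_idx, ncomp) {
  ytr <- y[train_idx]
  if (stats::var(ytr) == 0) return(0)
  yc <- ytr - mean(ytr)
  K <- ks$K
  n <- length(yc)
  a_s <- yc                       # dual of s = Xc' yc
  Rd <- matrix(0, n, ncomp)       # dual weights
  Q <- numeric(ncomp)
  Vd <- matrix(0, n, ncomp)       # dual orthonormal loadings
  for (a in seq_len(ncomp)) {
    t <- K %*% a_s
    nt <- sqrt(sum(t * t))
    if (nt < .Machine$double.eps^0.5) {
      Rd <- Rd[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[seq_len(a - 1L)]
      break
    }
    rd <- a_s / nt
    t <- t / nt
    vd <- t                       # dual of p = Xc' t
    if (a > 1L) {
      Vp <- Vd[, seq_len(a - 1L), drop = FALSE]
      vd <- vd - Vp %*% crossprod(Vp, K %*% t)
    }
    nv2 <- drop(crossprod(vd, K %*% vd))
    if (nv2 < .Machine$double.eps) {
      Rd <- Rd[, seq_len(a - 1L), drop = FALSE]
      Q <- Q[seq_len(a - 1L)]
      break
    }
    vd <- vd / sqrt(nv2)
    a_s <- a_s - vd * drop(crossprod(vd, K %*% a_s))
    Rd[, a] <- rd
    Q[a] <- sum(yc * t)
    Vd[, a] <- vd
  }
  if (length(Q) == 0L) return(0)
  pred <- drop(ks$Ket %*% (Rd %*% Q)) + mean(ytr)
  yte <- y[-train_idx]
  if (stats::sd(pred) == 0 || stats::sd(yte) == 0) return(0)
  stats::cor(pred, yte)
}

# Held-out Pearson r for one split: fit on idx, correlate on the rest.
# Primal-space reference path (used by tests as a cross-check of the Gram
# fast path). Returns 0 when either side of the correlation is degenerate.
held_out_r <- function(X, y, train_idx, ncomp) {
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  if (stats::var(ytr) == 0) return(0)
  xm <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2L, xm, check.margin = FALSE)
  B <- simpls_coef(Xc, ytr - mean(ytr), ncomp)
  Xte <- X[-train_idx, , drop = FALSE]
  pred <- drop(sweep(Xte, 2L, xm, check.margin = FALSE) %*% B)
  yte <- y[-train_idx]
  if (stats::sd(pred) == 0 || stats::sd(yte) == 0) return(0)
  stats::cor(pred, yte)
}

#' Axis-coding screen for a population of units
#'
#' Runs [axis_permutation_test()] on each row of a unit-by-stimulus rate
#' matrix and returns one row per unit, matching the `axis_fits.csv` layout.
#'
#' @param rate_matrix Numeric matrix `[n_units x n_stimuli]` of mean rates
#'   per stimulus (typically distractor-fixation rates in the early window).
#' @param features Stimulus feature matrix `[n_stimuli x D]`.
#' @param n_components,n_perm,seed Passed to [axis_permutation_test()];
#'   each unit gets an independent substream derived from `seed`.
#' @return data.frame: unit (rowname or index), n_components, r_observed,
#'   p_perm, is_axis, strength.
#' @export
axis_screen_population <- function(rate_matrix, features, n_components = 4,
                                   n_perm = 1000, seed = 1) {
  rate_matrix <- as.matrix(rate_matrix)
  n_units <- nrow(rate_matrix)
  ids <- rownames(rate_matrix)
  if (is.null(ids)) ids <- as.character(seq_len(n_units))
  seeds <- derive_seeds(seed, n_units)
  res <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    fit <- axis_permutation_test(features, rate_matrix[i, ],
                                 n_components = n_components,
                                 n_perm = n_perm, seed = seeds[i])
    res[[i]] <- data.frame(
      unit_id = ids[i], n_components = fit$n_components,
      r_observed = fit$r_observed, p_perm = fit$p_perm,
      is_axis = fit$is_axis, strength = fit$strength,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, res)
}

# Deterministic derived seeds (kept below 2^31).
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% 2147483629L
}

#' Specificity calibration of the axis-coding selection on null units
#'
#' Generates `n_units` synthetic null units whose rates are drawn
#' independently of a shared Gaussian stimulus feature matrix — the exact
#' null of the split-and-permute selection — runs the permutation test on
#' each, and reports the fraction not flagged. With a calibrated test this
#' specificity sits near 95% (the percentile rule's nominal level).
#'
#' @param n_units Number of null units (default 500).
#' @param n_stimuli Stimuli per unit (default 80).
#' @param D Feature dimension (default 512).
#' @param n_perm Permutation runs per unit (default 200; the percentile
#'   rule is unbiased in the number of runs, which only sets the
#'   resolution of the null quantile).
#' @param seed Integer seed.
#' @return List: `flags` (logical per unit), `specificity` (fraction not
#'   flagged), `n_units`.
#' @export
axis_null_calibration <- function(n_units = 500, n_stimuli = 80, D = 512,
                                  n_perm = 200, seed = 1) {
  X <- withr::with_seed(seed, {
    matrix(stats::rnorm(n_stimuli * D), n_stimuli, D)
  })
  seeds <- derive_seeds(seed + 7L, n_units)
  flags <- logical(n_units)
  for (i in seq_len(n_units)) {
    y <- withr::with_seed(seeds[i], stats::rnorm(n_stimuli))
    flags[i] <- axis_permutation_test(X, y, n_perm = n_perm,
                                      seed = seeds[i] + 1L)$is_axis
  }
  list(flags = flags, specificity = mean(!flags), n_units = n_units)
}
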