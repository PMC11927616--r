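#' Representational dissimilarity matrix
#'
#' Entry (i, j) is `1 - Pearson r` between the population response patterns
#' (columns) for stimuli i and j. Symmetric, zero diagonal, entries in
#' `[0, 2]`.
#'
#' @param response Numeric matrix `[n_units x n_stimuli]`; columns ideally
#'   named by stimulus id.
#' @return A `dissimilarity_matrix`: list with `labels` and `values`.
#' @export
dissimilarity_matrix <- function(response) {
  response <- as.matrix(response)
  if (nrow(response) < 2L) {
    stop("need at least 2 units to correlate response patterns",
         call. = FALSE)
  }
  labels <- colnames(response)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(response)))
  sds <- apply(response, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- labels[which(sds == 0)[1]]
    stop("degenerate stimulus '", bad,
         "': response pattern has zero variance", call. = FALSE)
  }
  values <- 1 - stats::cor(response)
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values),
            class = "dissimilarity_matrix")
}

#' Correspondence between two dissimilarity matrices
#'
#' Spearman correlation over the lower triangles, with a permutation null
#' built by jointly shuffling the stimulus labels (rows and columns) of one
#' matrix per run; `p_perm` is the fraction of null correlations at least
#' as large as the observed one. Bonferroni correction across comparisons
#' is the caller's responsibility.
#'
#' @param dm_a,dm_b `dissimilarity_matrix` objects over the same label set.
#' @param n_perm Permutation runs (default 1000).
#' @param seed Integer seed.
#' @return List: `spearman_rho`, `p_perm`, `null` (the null rho values).
#' @export
rsa_correspondence <- function(dm_a, dm_b, n_perm = 1000, seed = 1) {
  if (!setequal(dm_a$labels, dm_b$labels)) {
    stop("invalid argument: label sets of the two DMs differ",
         call. = FALSE)
  }
  A <- dm_a$values
  B <- dm_b$values[dm_a$labels, dm_a$labels]
  lt <- lower.tri(A)
  rho <- stats::cor(A[lt], B[lt], method = "spearman")
  n <- length(dm_a$labels)
  null <- numeric(n_perm)
  withr::with_seed(seed, {
    for (k in seq_len(n_perm)) {
      p <- sample.int(n)
      Bp <- B[p, p]
      null[k] <- stats::cor(A[lt], Bp[lt], method = "spearman")
    }
  })
  list(spearman_rho = rho, p_perm = mean(null >= rho), null = null)
}

#' Population geometry for one condition pair
#'
#' Treats each stimulus as a point in unit space: `v_s` is the population
#' mean-rate vector for stimulus `s` in a condition. For every stimulus
#' pair (i, j) the Euclidean distance `||v_i - v_j||` and the angle
#' `acos(v_i . v_j / (||v_i|| ||v_j||))` (degrees) are returned, per
#' condition. Pairs involving a zero vector get `NA` angles and are
#' counted in `n_undefined_angles`, never silently dropped.
#'
#' @param response_target,response_distractor Numeric matrices
#'   `[n_units x n_stimuli]` over the same stimulus set.
#' @param window Label stored with the summaries (`"early"` or `"late"`).
#' @return List of two `geometry_summary` objects (`target`,
#'   `distractor`), each with `window`, `condition`, `pair_i`, `pair_j`,
#'   `pair_distances`, `pair_angles_deg`, `n_undefined_angles`.
#' @export
population_geometry <- function(response_target, response_distractor,
                                window = "early") {
  rt <- as.matrix(response_target)
  rd <- as.matrix(response_distractor)
  if (!all(dim(rt) == dim(rd))) {
    stop("invalid argument: condition matrices must share stimulus sets",
         call. = FALSE)
  }
  list(target = condition_geometry(rt, window, "target"),
       distractor = condition_geometry(rd, window, "distractor"))
}

condition_geometry <- function(resp, window, condition) {
  n <- ncol(resp)
  pr <- utils::combn(n, 2L)
  d <- as.numeric(stats::dist(t(resp)))
  norms <- sqrt(colSums(resp^2))
  gram <- crossprod(resp)
  i <- pr[1L, ]; j <- pr[2L, ]
  denom <- unname(norms[i] * norms[j])
  cosang <- ifelse(denom == 0, NA_real_,
                   pmin(1, pmax(-1, gram[cbind(i, j)] / denom)))
  ang <- unname(acos(cosang) * 180 / pi)
  structure(
    list(window = window, condition = condition, pair_i = i, pair_j = j,
         pair_distances = d, pair_angles_deg = ang,
         n_undefined_angles = sum(is.na(ang))),
    class = "geometry_summary"
  )
}

#' Target-vs-distractor geometry contrasts with paired tests
#'
#' Per stimulus pair, the normalised contrasts
#' `(Distance_T - Distance_D) / (Distance_T + Distance_D)` and the same for
#' angles, plus two-tailed paired t tests of target vs distractor values
#' across pairs (df = n_pairs - 1).
#'
#' @param summary_target,summary_distractor `geometry_summary` objects
#'   over matching pairs.
#' @return List: `distance_contrast`, `angle_contrast` (per-pair vectors),
#'   and `distance_test` / `angle_test` (lists with `t`, `df`, `p`).
#' @export
geometry_contrast <- function(summary_target, summary_distractor) {
  if (length(summary_target$pair_distances) !=
      length(summary_distractor$pair_distances)) {
    stop("invalid argument: pair sets do not match", call. = FALSE)
  }
  dc <- pairwise_contrast(summary_target$pair_distances,
                          summary_distractor$pair_distances)
  ac <- pairwise_contrast(summary_target$pair_angles_deg,
                          summary_distractor$pair_angles_deg)
  list(
    distance_contrast = dc,
    angle_contrast = ac,
    distance_test = paired_t(summary_target$pair_distances,
                             summary_distractor$pair_distances),
    angle_test = paired_t(summary_target$pair_angles_deg,
                          summary_distractor$pair_angles_deg)
  )
}

pairwise_contrast <- function(a, b) {
  s <- a + b
  out <- rep(NA_real_, length(a))
  ok <- !is.na(s) & s != 0
  out[ok] <- (a[ok] - b[ok]) / s[ok]
  out[!is.na(s) & s == 0] <- 0
  out
}

paired_t <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) return(list(t = NA_real_, df = n - 1L, p = NA_real_))
  if (stats::sd(d) == 0) {
    return(list(t = 0, df = n - 1L, p = 1))
  }
  tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Low-dimensional embedding of stimuli in neural state space
#'
#' Projects stimuli (points in unit space) onto the top principal
#' components of the average neural response; for report plots only.
#'
#' @param mean_responses `[n_units x n_stimuli]` matrix.
#' @param n_dims Number of components (default 2).
#' @return `[n_stimuli x n_dims]` coordinate matrix (fewer columns, with a
#'   warning, when the point cloud is degenerate).
#' @export
pca_embedding <- function(mean_responses, n_dims = 2) {
  M <- t(as.matrix(mean_responses))  # stimuli as rows
  if (ncol(M) < n_dims) {
    stop("need at least n_dims units", call. = FALSE)
  }
  pc <- stats::prcomp(M, center = TRUE, scale. = FALSE)
  informative <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  k <- min(n_dims, informative)
  if (k < n_dims) {
    warning("degenerate covariance: returning ", k, " dimension(s)")
  }
  pc$x[, seq_len(k), drop = FALSE]
}
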