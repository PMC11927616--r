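test_that("dissimilarity matrix has the defining identities", {
  withr::with_seed(1, {
    R <- matrix(rnorm(10 * 6), 10, 6)
  })
  R[, 2] <- R[, 1]        # duplicated stimulus
  R[, 4] <- -R[, 3] + 2 * mean(R[, 3])  # anti-correlated pattern
  colnames(R) <- paste0("s", 1:6)
  dm <- dissimilarity_matrix(R)
  expect_equal(dm$values[1, 2], 0)
  expect_equal(dm$values[3, 4], 2, tolerance = 1e-8)
  expect_equal(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
  expect_true(all(dm$values >= 0 & dm$values <= 2 + 1e-12))

  R[, 5] <- 7
  expect_error(dissimilarity_matrix(R), "degenerate stimulus 's5'")
})

test_that("DM label permutation invariance", {
  withr::with_seed(2, {
    R <- matrix(rnorm(8 * 10), 8, 10)
  })
  colnames(R) <- paste0("s", 1:10)
  dm <- dissimilarity_matrix(R)
  p <- sample(10)
  dm_p <- dissimilarity_matrix(R[, p])
  expect_equal(sort(dm_p$values[lower.tri(dm_p$values)]),
               sort(dm$values[lower.tri(dm$values)]))
})

test_that("RSA correspondence: identity, invariance and calibration", {
  withr::with_seed(3, {
    R <- matrix(rnorm(12 * 20), 12, 20)
  })
  colnames(R) <- paste0("s", 1:20)
  dm <- dissimilarity_matrix(R)
  self <- rsa_correspondence(dm, dm, n_perm = 200, seed = 1)
  expect_equal(self$spearman_rho, 1)
  expect_lt(self$p_perm, 0.05)

  # joint relabeling of both DMs leaves rho unchanged
  p <- sample(20)
  dm_p <- list(labels = dm$labels[p],
               values = dm$values[p, p])
  class(dm_p) <- "dissimilarity_matrix"
  withr::with_seed(4, {
    R2 <- matrix(rnorm(12 * 20), 12, 20)
  })
  colnames(R2) <- paste0("s", 1:20)
  dm2 <- dissimilarity_matrix(R2)
  dm2_p <- list(labels = dm2$labels[p], values = dm2$values[p, p])
  class(dm2_p) <- "dissimilarity_matrix"
  expect_equal(rsa_correspondence(dm_p, dm2_p, n_perm = 10, seed = 1)$spearman_rho,
               rsa_correspondence(dm, dm2, n_perm = 10, seed = 1)$spearman_rho)

  expect_error(rsa_correspondence(dm, dissimilarity_matrix(R2[, 1:5])),
               "label sets")

  # null rejection rate near alpha for independent random DMs
  withr::with_seed(5, {
    rej <- replicate(60, {
      A <- dissimilarity_matrix(matrix(rnorm(12 * 15), 12, 15))
      B <- dissimilarity_matrix(matrix(rnorm(12 * 15), 12, 15))
      rsa_correspondence(A, B, n_perm = 100,
                         seed = sample.int(1e6, 1))$p_perm < 0.05
    })
  })
  expect_gte(mean(rej), 0)
  expect_lt(mean(rej), 0.15)
})

test_that("population geometry distances and angles are exact on constructions", {
  v <- diag(3) * 2
  colnames(v) <- c("a", "b", "c")
  geo <- population_geometry(v, v, window = "early")
  # orthogonal vectors: all angles 90 degrees
  expect_equal(geo$target$pair_angles_deg, rep(90, 3))

  same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  g2 <- population_geometry(same, same)$target
  expect_equal(g2$pair_distances, 0)
  expect_equal(g2$pair_angles_deg, 0)

  # zero vector: undefined angle reported, not dropped
  z <- cbind(a = c(0, 0), b = c(1, 1))
  g3 <- population_geometry(z, z)$target
  expect_true(is.na(g3$pair_angles_deg[1]))
  expect_equal(g3$n_undefined_angles, 1L)
})

test_that("angles are invariant and distances linear under global scaling", {
  withr::with_seed(6, {
    R <- matrix(runif(20 * 30, 1, 10), 20, 30)
  })
  g1 <- population_geometry(R, R)$target
  g2 <- population_geometry(2.5 * R, R)$target
  expect_equal(g2$pair_angles_deg, g1$pair_angles_deg, tolerance = 1e-9)
  expect_equal(g2$pair_distances, 2.5 * g1$pair_distances,
               tolerance = 1e-9)
})

test_that("geometry contrasts and paired tests behave on known inputs", {
  withr::with_seed(7, {
    R <- matrix(runif(15 * 64, 1, 10), 15, 64)
  })
  geo <- population_geometry(R, R, window = "late")
  con0 <- geometry_contrast(geo$target, geo$distractor)
  expect_equal(length(con0$distance_contrast), 2016L)  # choose(64, 2)
  expect_equal(con0$distance_test$df, 2015L)
  expect_true(all(con0$distance_contrast == 0))
  expect_equal(con0$distance_test$t, 0)

  geo2 <- population_geometry(2 * R, R, window = "late")
  con2 <- geometry_contrast(geo2$target, geo2$distractor)
  expect_equal(mean(con2$distance_contrast), 1 / 3, tolerance = 1e-12)
  expect_gt(con2$distance_test$t, 10)
})

test_that("PCA embedding is a contraction and flags degeneracy", {
  withr::with_seed(8, {
    R <- matrix(rnorm(10 * 12), 10, 12)
  })
  emb <- pca_embedding(R, 2)
  expect_equal(dim(emb), c(12L, 2L))
  full_d <- as.matrix(dist(t(R)))
  emb_d <- as.matrix(dist(emb))
  expect_true(all(emb_d <= full_d + 1e-8))

  line <- outer(1:5, seq(0, 1, length.out = 8))  # collinear cloud
  expect_warning(e1 <- pca_embedding(line, 2), "degenerate")
  expect_equal(ncol(e1), 1L)
})
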