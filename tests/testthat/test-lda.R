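# Fisher discriminant axes, Z-scores and AUC validation.

test_that("identity covariance recovers the mean-difference direction", {
  set.seed(1)
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  A <- base
  B <- sweep(base, 2, c(1, 0, 0), "+")
  f <- fit_lda(A, B, shrinkage = 0)
  w <- f$weights / sqrt(sum(f$weights^2))
  expect_equal(abs(w), c(1, 0, 0), tolerance = 1e-10)
})

test_that("anisotropic toy matches the analytic Fisher solution", {
  a <- rbind(c(2, 0), c(-2, 0), c(0, sqrt(2)), c(0, -sqrt(2)))  # Sw prop diag(2,1)
  f <- fit_lda(a, sweep(a, 2, c(1, 1), "+"), shrinkage = 0)
  expect_equal(f$weights / f$weights[2], c(0.5, 1), tolerance = 1e-10)
  expect_error(fit_lda(a, a, shrinkage = 0), "degenerate-separation")
})

test_that("Z-scores are normalized, oriented and externally applicable", {
  set.seed(2)
  A <- matrix(rnorm(40 * 3), 40, 3)
  B <- matrix(rnorm(40 * 3), 40, 3); B[, 2] <- B[, 2] + 1.2
  f <- fit_lda(A, B, labels = c("neg", "pos"), positive = 2)
  z <- zscore(f, rbind(A, B))
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)
  expect_gt(mean(z[41:80]), mean(z[1:40]))
  # subject at the coefficient origin: Z = -score_mean / score_sd, bit-stable
  z0 <- zscore(f, rep(0, 3))
  expect_identical(z0, -f$score_mean / f$score_sd)
  expect_identical(z0, zscore(f, rep(0, 3)))
  expect_error(zscore(f, rep(0, 4)), "mode-count")
})

test_that("Z-scores and AUC are invariant to coefficient scaling", {
  set.seed(3)
  A <- matrix(rnorm(30 * 4), 30, 4)
  B <- matrix(rnorm(30 * 4), 30, 4); B[, 1] <- B[, 1] + 1
  f1 <- fit_lda(A, B)
  f2 <- fit_lda(5 * A, 5 * B)
  expect_equal(zscore(f1, rbind(A, B)), zscore(f2, 5 * rbind(A, B)),
               tolerance = 1e-9)
})

test_that("fitted axes reach the analytic Fisher criterion on Gaussian toys", {
  set.seed(4)
  fisher_J <- function(w, A, B) {
    d <- colMeans(B) - colMeans(A)
    Sw <- (crossprod(sweep(A, 2, colMeans(A))) +
           crossprod(sweep(B, 2, colMeans(B)))) / (nrow(A) + nrow(B) - 2)
    sum(w * d)^2 / drop(t(w) %*% Sw %*% w)
  }
  for (rep in 1:10) {
    p <- sample(2:6, 1)
    L <- matrix(rnorm(p * p), p)
    A <- matrix(rnorm(80 * p), 80, p) %*% L
    B <- matrix(rnorm(80 * p), 80, p) %*% L
    B <- sweep(B, 2, rnorm(p), "+")
    f <- fit_lda(A, B)    # default Ledoit-Wolf shrinkage
    Sw <- (crossprod(sweep(A, 2, colMeans(A))) +
           crossprod(sweep(B, 2, colMeans(B)))) / (158)
    w_star <- solve(Sw, colMeans(B) - colMeans(A))
    expect_gte(fisher_J(f$weights, A, B), 0.999 * fisher_J(w_star, A, B))
  }
})

test_that("AUC follows the Mann-Whitney tie convention", {
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("LOO separates disjoint groups and matches an independent oracle", {
  A <- matrix(c(0, 0.1, 0.2, 1, 1.1, 1.2, 0, 0, 0, 0, 0, 0), 6, 2)
  y <- c(0, 0, 0, 1, 1, 1)
  v <- loo_cv_auc(A, y, shrinkage = 0.5)
  expect_identical(v$auc_loo, 1)
  expect_identical(v$auc_resubstitution, 1)

  set.seed(5)
  X <- matrix(rnorm(6 * 2), 6, 2); X[y == 1, 1] <- X[y == 1, 1] + 1
  v2 <- loo_cv_auc(X, y, shrinkage = 0)
  z_oracle <- vapply(1:6, function(i)
    oracle_lda_z(X[-i, , drop = FALSE], y[-i], X[i, ]), numeric(1))
  expect_equal(v2$z_loo, z_oracle, tolerance = 1e-10)
  expect_identical(v2$auc_loo, auc(z_oracle, y))
})

test_that("axis extremes re-project to exactly +-k and straddle the mean", {
  set.seed(6)
  meshes <- random_mesh_cohort(16)
  ssm <- fit_pca(align_meshes(meshes))
  K <- ssm$n_modes_selected
  C <- coef(ssm)[, 1:K, drop = FALSE]
  y <- rep(c(0, 1), each = 8)
  f <- fit_lda(C[y == 0, , drop = FALSE], C[y == 1, , drop = FALSE])
  ex <- axis_extreme_shapes(f, ssm, 3)
  z_plus <- zscore(f, project(ssm, as_shape_vector(ex$plus), n_modes = K))
  z_minus <- zscore(f, project(ssm, as_shape_vector(ex$minus), n_modes = K))
  expect_equal(z_plus, 3, tolerance = 1e-6)
  expect_equal(z_minus, -3, tolerance = 1e-6)
  # LDA trained on the full PCA cohort: extremes straddle the mean shape
  mid <- (as_shape_vector(ex$plus) + as_shape_vector(ex$minus)) / 2
  expect_lt(max(abs(mid - ssm$mean_shape)), 1e-6)
})

test_that("permuted labels give chance-level LOO AUC", {
  set.seed(7)
  aucs <- replicate(40, {
    X <- matrix(rnorm(120 * 4), 120, 4)
    y <- sample(rep(0:1, each = 60))
    loo_cv_auc(X, y)$auc_loo
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})
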