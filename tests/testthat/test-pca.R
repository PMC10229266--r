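# PCA statistical shape model.

test_that("collinear shapes give one mode through their midpoint mean", {
  set.seed(1)
  x <- rnorm(30); y <- x + rnorm(30)
  X <- rbind(x, y, (x + y) / 2)
  ssm <- fit_pca(X)
  expect_equal(ssm$mean_shape, (x + y) / 2, ignore_attr = TRUE)
  expect_equal(ssm$explained_ratio[1], 1, tolerance = 1e-12)
  expect_lt(ssm$variances[2] / ssm$variances[1], 1e-12)
})

test_that("variance is conserved and modes are orthonormal, ordered and signed", {
  set.seed(2)
  meshes <- random_mesh_cohort(10)
  vecs <- align_meshes(meshes)
  ssm <- fit_pca(vecs)
  X <- do.call(rbind, lapply(vecs, as.numeric))
  total <- sum(apply(X, 2, var))
  expect_equal(sum(ssm$variances), total, tolerance = 1e-8 * total)
  K <- length(ssm$variances)
  expect_lt(max(abs(crossprod(ssm$modes) - diag(K))), 1e-8)
  expect_true(all(diff(ssm$variances) <= 1e-12))
  for (k in seq_len(K)) {
    j <- which.max(abs(ssm$modes[, k]))
    expect_gte(ssm$modes[j, k], 0)
  }
  # deterministic refit
  ssm2 <- fit_pca(vecs)
  expect_identical(ssm$modes, ssm2$modes)
})

test_that("mode selection respects the inclusive cumulative-variance rule", {
  fake <- function(r) list(explained_ratio = r)
  expect_identical(select_modes(fake(c(0.5, 0.3, 0.15, 0.05)), 0.90), 3L)
  expect_identical(select_modes(fake(c(0.95, 0.05)), 0.90), 1L)
  expect_identical(select_modes(fake(c(0.6, 0.3, 0.1)), 0.90), 2L)
  expect_error(select_modes(fake(c(0.5, 0.3)), 0), "threshold")
})

test_that("projection and reconstruction identities hold", {
  set.seed(3)
  vecs <- align_meshes(random_mesh_cohort(8))
  ssm <- fit_pca(vecs)
  X <- do.call(rbind, lapply(vecs, as.numeric))
  scale <- max(abs(X))

  expect_lt(max(abs(project(ssm, ssm$mean_shape))), 1e-9)
  x1 <- ssm$mean_shape + 3 * sqrt(ssm$variances[1]) * ssm$modes[, 1]
  c1 <- project(ssm, x1)
  expect_equal(as.numeric(c1), c(3, rep(0, length(ssm$variances) - 1)),
               tolerance = 1e-8)

  co <- coef(ssm)
  expect_lt(max(abs(reconstruct(ssm, co) - X)) / scale, 1e-8)
  # adjointness: raw score k = <mode_k, x - mean>
  raw <- coef(ssm, standardized = FALSE)
  expect_equal(raw[2, 3],
               sum(ssm$modes[, 3] * (X[2, ] - ssm$mean_shape)),
               tolerance = 1e-8)
  # truncated squared error equals (n-1) * discarded variance
  k <- 2
  err <- sum((reconstruct(ssm, co[, 1:k]) - X)^2)
  expect_equal(err, (nrow(X) - 1) * sum(ssm$variances[-(1:k)]),
               tolerance = 1e-6 * err)
})

test_that("extreme synthesis is linear about the mean", {
  set.seed(4)
  ssm <- fit_pca(align_meshes(random_mesh_cohort(6)))
  K <- length(ssm$variances)
  expect_equal(as_shape_vector(synthesize_extreme(ssm, c(1, rep(0, K - 1)), 0)),
               as.numeric(ssm$mean_shape), ignore_attr = TRUE)
  e1 <- c(1, rep(0, K - 1))
  plus <- synthesize_extreme(ssm, e1, 3)
  expect_equal(as_shape_vector(plus),
               reconstruct(ssm, c(3, rep(0, K - 1))), ignore_attr = TRUE)
  minus <- synthesize_extreme(ssm, e1, -3)
  mid <- (as_shape_vector(plus) + as_shape_vector(minus)) / 2
  expect_lt(max(abs(mid - ssm$mean_shape)), 1e-9 * max(abs(ssm$mean_shape)))
  expect_error(synthesize_extreme(ssm, rep(0, K), 3), "non-zero")
})

test_that("few latent factors concentrate the spectrum", {
  set.seed(5)
  base <- lv_geometry_params()
  meshes <- lapply(1:20, function(i) {
    p <- base
    p$length_mm <- 80 + rnorm(1, 0, 6)
    p$septal_bump_amp_mm <- max(4 + rnorm(1, 0, 2), 0.1)
    generate_lv_surface(p, 16, 8)
  })
  vecs <- align_meshes(meshes)
  X <- do.call(rbind, lapply(vecs, as.numeric))
  # measurement noise well under 5% of the factor-driven shape SD
  X <- X + matrix(rnorm(length(X), 0, 0.05), nrow(X))
  ssm <- fit_pca(X)
  expect_gte(cumsum(ssm$explained_ratio)[2], 0.95)
})

test_that("predict aligns raw meshes before projecting", {
  set.seed(6)
  meshes <- random_mesh_cohort(6)
  ssm <- fit_pca(align_meshes(meshes))
  co_direct <- coef(ssm)
  m3 <- meshes[[3]]
  R <- lvshape:::axis_rotation(c(1, 0, 1), 0.4)
  m3$endo <- sweep(m3$endo %*% t(R), 2, c(4, -2, 9), "+")
  m3$epi <- sweep(m3$epi %*% t(R), 2, c(4, -2, 9), "+")
  co <- predict(ssm, m3)
  expect_equal(as.numeric(co), co_direct[3, ], tolerance = 1e-4)
  expect_error(fit_pca(do.call(rbind, lapply(meshes[1:2], as_shape_vector))),
               "3 subjects")
})
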