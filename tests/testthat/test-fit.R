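# Template personalization and fitting-accuracy measurement.

test_that("self-fit at the true pose stays within the voxel half-diagonal", {
  m <- generate_lv_surface(lv_geometry_params(), 32, 16)
  vx <- voxelize(m, 2, 8)
  fit <- fit_template(vx$mask, m, init = "none")
  half_diag <- sqrt(2^2 + 2^2 + 8^2) / 2
  expect_lt(fit$report$mean_error_mm, half_diag)
  expect_true(fit$report$mean_error_mm <= fit$report$max_error_mm)
})

test_that("contours sampled on the surface have zero fitting error", {
  m <- generate_lv_surface(lv_geometry_params(), 32, 16)
  zs <- c(-10, -30, -50)
  stack <- structure(lapply(zs, function(z)
    list(z = z,
         endo = lvshape:::slice_polygon(m, "endo", z),
         epi = lvshape:::slice_polygon(m, "epi", z))),
    class = "lv_contour_stack")
  rep <- fitting_error(m, stack)
  expect_lt(rep$mean_error_mm, 1e-9 * 80)
  expect_error(fitting_error(m, structure(list(list(z = 0, endo = NULL, epi = NULL)),
                                          class = "lv_contour_stack")),
               "empty")
})

test_that("normal offsets and surface mix-ups measure known distances", {
  # near-vertical basal wall: in-plane radial displacement == normal offset
  p <- lv_geometry_params(septal_bump_amp_mm = 0, lvot_inward_mm = 0,
                          apical_dilation = 0)
  m <- generate_lv_surface(p, 48, 24)
  zs <- c(-6, -14, -22)
  shift_out <- function(poly, d) {
    r <- sqrt(rowSums(poly^2))
    poly * (r + d) / r
  }
  stack <- structure(lapply(zs, function(z)
    list(z = z,
         endo = shift_out(lvshape:::slice_polygon(m, "endo", z), -2),
         epi = NULL)),
    class = "lv_contour_stack")
  rep <- fitting_error(m, stack)
  expect_equal(rep$mean_error_mm, 2, tolerance = 0.05)

  # epi contours against the endo surface read the wall thickness
  stack2 <- structure(lapply(zs, function(z)
    list(z = z, endo = lvshape:::slice_polygon(m, "epi", z), epi = NULL)),
    class = "lv_contour_stack")
  rep2 <- fitting_error(m, stack2)
  expect_equal(rep2$mean_error_mm, 8, tolerance = 0.5)
})

test_that("fits are equivariant under translation of the mask", {
  set.seed(31)
  tpl <- generate_lv_surface(lv_geometry_params(), 32, 16)
  p <- lv_geometry_params(length_mm = 88, septal_bump_amp_mm = 7,
                          lvot_inward_mm = 3)
  m <- generate_lv_surface(p, 32, 16)
  f0 <- fit_template(voxelize(m)$mask, tpl, init = "auto")
  m2 <- m
  m2$endo[, 1] <- m2$endo[, 1] + 10
  m2$epi[, 1] <- m2$epi[, 1] + 10
  f1 <- fit_template(voxelize(m2)$mask, tpl, init = "auto")
  expect_equal(f1$report$mean_error_mm, f0$report$mean_error_mm,
               tolerance = 1e-6)
  expect_equal(mean(f1$mesh$endo[, 1]) - mean(f0$mesh$endo[, 1]), 10,
               tolerance = 0.5)
})

test_that("fit error does not grow as voxels get finer", {
  tpl <- generate_lv_surface(lv_geometry_params(), 32, 16)
  m <- generate_lv_surface(lv_geometry_params(length_mm = 85,
                                              base_thickness_mm = 10), 32, 16)
  e_coarse <- fit_template(voxelize(m, 2.5, 10)$mask, tpl, init = "auto")$report$mean_error_mm
  e_fine <- fit_template(voxelize(m, 1.25, 5)$mask, tpl, init = "auto")$report$mean_error_mm
  expect_lte(e_fine, e_coarse + 0.05)
})

test_that("degenerate masks are rejected", {
  tpl <- generate_lv_surface(lv_geometry_params(), 32, 16)
  empty <- structure(array(0L, c(4, 4, 2)), spacing = c(2, 2, 8),
                     origin = c(0, 0), z_centers = c(-4, -12),
                     class = "lv_mask")
  expect_error(fit_template(empty, tpl), "empty mask")
})

test_that("fitted thickness tracks the generator's baseline wall thickness", {
  set.seed(17)
  tpl <- generate_lv_surface(lv_geometry_params(), 32, 16)
  t0s <- seq(6, 13, length.out = 8)
  mean_th <- vapply(t0s, function(t0) {
    m <- generate_lv_surface(lv_geometry_params(base_thickness_mm = t0), 32, 16)
    fit <- fit_template(voxelize(m)$mask, tpl, init = "auto")
    mean(wall_thickness(fit$mesh), na.rm = TRUE)
  }, numeric(1))
  expect_gt(cor(mean_th, t0s), 0.95)
})
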