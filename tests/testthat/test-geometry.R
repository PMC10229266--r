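# Synthetic LV surface generator.

test_that("constant-offset construction gives a uniform wall", {
  p <- lv_geometry_params(base_thickness_mm = 8, septal_bump_amp_mm = 0,
                          lvot_inward_mm = 0, apical_dilation = 0)
  m <- generate_lv_surface(p, 32, 16)
  off <- sqrt(rowSums((m$epi - m$endo)^2))
  expect_equal(off, rep(8, length(off)), tolerance = 1e-12)
})

test_that("septal bump peaks at t0 + A_sept at the node nearest its centre", {
  p <- lv_geometry_params(base_thickness_mm = 8, septal_bump_amp_mm = 9,
                          septal_bump_center = c(0, 0.25),
                          spiral_drift_rad = 0, lvot_inward_mm = 0)
  m <- generate_lv_surface(p, 32, 17)   # u grid contains 0.25, theta grid 0
  off <- sqrt(rowSums((m$epi - m$endo)^2))
  expect_equal(max(off), 17, tolerance = 1e-9)
  k <- which.max(off)
  i <- (k - 1) %/% m$n_circ + 1
  j <- (k - 1) %% m$n_circ + 1
  expect_equal(m$u[i], 0.25)
  expect_equal(m$theta[j], 0)
})

test_that("endocardial cavity volume matches the semi-ellipsoid closed form", {
  p <- lv_geometry_params(apical_dilation = 0, sphericity_exp = 2,
                          lvot_inward_mm = 0)
  m <- generate_lv_surface(p, 64, 64)
  v <- mesh_volumes(m)$cavity_ml
  v_exact <- (2 / 3) * pi * 25^2 * 80 / 1000
  expect_lt(abs(v - v_exact) / v_exact, 0.02)
})

test_that("parameter validation and invalid geometries are rejected", {
  expect_error(lv_geometry_params(length_mm = -1), "length_mm")
  expect_error(lv_geometry_params(base_thickness_mm = 0), "base_thickness_mm")
  expect_error(lv_geometry_params(septal_bump_width = c(0, 0.1)), "width")
  expect_error(generate_lv_surface(lv_geometry_params(), n_circ = 8), "n_circ")
  # bump deeper than the baseline wall inverts the surfaces
  p_bad <- lv_geometry_params(base_thickness_mm = 5, septal_bump_amp_mm = -6)
  expect_error(generate_lv_surface(p_bad, 32, 16), "invalid geometry")
})

test_that("meshes are corresponded by construction and remodelling is monotone", {
  ms <- lapply(c(0, 3, 6), function(a)
    generate_lv_surface(lv_geometry_params(septal_bump_amp_mm = a), 32, 16))
  ids <- vapply(ms, `[[`, "", "topology_id")
  expect_length(unique(ids), 1)
  for (m in ms[-1]) {
    expect_identical(m$theta, ms[[1]]$theta)
    expect_identical(m$u, ms[[1]]$u)
  }
  peak <- vapply(ms, function(m) max(sqrt(rowSums((m$epi - m$endo)^2))),
                 numeric(1))
  expect_true(all(diff(peak) > 0))

  areas <- vapply(c(0, 2, 4), function(a) lvot_sector_area(
    generate_lv_surface(lv_geometry_params(lvot_inward_mm = a), 32, 16)),
    numeric(1))
  expect_true(all(diff(areas) < 0))
})

test_that("shape vectors round trip through mesh refolding", {
  m <- generate_lv_surface(lv_geometry_params(), 16, 8)
  v <- as_shape_vector(m)
  m2 <- mesh_from_vector(v)
  expect_equal(m2$endo, m$endo)
  expect_equal(m2$epi, m$epi)
  expect_error(mesh_from_vector(v[-1], attr(v, "topology")), "length")
})
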