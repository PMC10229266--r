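# Synthetic cohort generation and the Bernoulli pressure-drop relation.

test_that("simplified Bernoulli relation", {
  expect_identical(bernoulli_pressure_drop(0), 0)
  expect_equal(bernoulli_pressure_drop(1.5), 9)
  # velocity whose drop sits exactly at the 30 mmHg group threshold
  v_thr <- sqrt(30 / 4)
  expect_equal(bernoulli_pressure_drop(v_thr), 30)
  expect_equal(v_thr, 2.7386, tolerance = 1e-4)
  expect_error(bernoulli_pressure_drop(-0.1), ">= 0")
})

test_that("same seed reproduces the cohort byte for byte", {
  spec <- population_spec(n_per_group = 4, n_circ = 16, n_long = 8, seed = 7)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1$table, c2$table)
  expect_identical(c1$subjects[[3]]$mesh$endo, c2$subjects[[3]]$mesh$endo)
})

test_that("noise-free unremodelled cohort reproduces the Bernoulli composition", {
  p0 <- lv_geometry_params(lvot_inward_mm = 0)
  spec <- population_spec(n_per_group = 3,
                          group_param_means = list(p0, p0),
                          group_param_sds = c(length_mm = 0),
                          velocity_ref_m_s = 1.5, velocity_noise_cv = 0,
                          stress_test_fraction = 0,
                          n_circ = 16, n_long = 8, seed = 1)
  coh <- sample_cohort(spec)
  expect_equal(coh$table$drop_rest_mmHg, rep(9, 6), tolerance = 1e-9)
  expect_true(all(coh$table$group == "R-"))
})

test_that("sector-area narrowing drives velocity and the R+ label", {
  pA <- lv_geometry_params(lvot_inward_mm = 0)
  pB <- lv_geometry_params(lvot_inward_mm = 6)
  spec <- population_spec(n_per_group = 2,
                          group_param_means = list(pA, pB),
                          group_param_sds = c(length_mm = 0),
                          velocity_ref_m_s = 1.5, velocity_noise_cv = 0,
                          stress_test_fraction = 0,
                          n_circ = 32, n_long = 16, seed = 2)
  coh <- sample_cohort(spec)
  mB <- generate_lv_surface(pB, 32, 16)
  ratio <- lvot_sector_area(generate_lv_surface(pA, 32, 16)) /
    lvot_sector_area(mB)
  expect_gt(ratio, 1)
  drop_expected <- bernoulli_pressure_drop(1.5 * ratio)
  expect_equal(coh$table$drop_rest_mmHg[3:4], rep(drop_expected, 2),
               tolerance = 1e-9)
  lab <- if (drop_expected >= 30) "R+" else "R-"
  expect_true(all(coh$table$group[3:4] == lab))
})

test_that("label marginals converge to the specified fractions", {
  spec <- population_spec(n_per_group = 150,
                          genotype_positive_fraction = c(0.45, 0.30),
                          stress_test_fraction = 0.7,
                          n_circ = 16, n_long = 8, seed = 33)
  coh <- sample_cohort(spec)
  tab <- coh$table
  for (g in 1:2) {
    phat <- mean(tab$genotype[tab$true_group == c("A", "B")[g]] == "G+")
    p0 <- spec$genotype_positive_fraction[g]
    expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / 150))
  }
  shat <- mean(!is.na(tab$drop_stress_mmHg))
  expect_lt(abs(shat - 0.7), 3 * sqrt(0.7 * 0.3 / 300))
})

test_that("cohort tables round trip through CSV with missing stress kept empty", {
  spec <- population_spec(n_per_group = 3, n_circ = 16, n_long = 8,
                          stress_test_fraction = 0.5, seed = 5)
  coh <- sample_cohort(spec)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(back$drop_rest_mmHg, coh$table$drop_rest_mmHg)
  expect_identical(is.na(back$drop_stress_mmHg), is.na(coh$table$drop_stress_mmHg))
  expect_identical(back$group, coh$table$group)
})
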