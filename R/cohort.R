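# Synthetic two-group LV cohort generator.
#
# The generator states a plausible world for an obstructive-vs-nonobstructive
# hypertrophic cardiomyopathy cohort: group geometry distributions encode the
# four remodelling features of interest (basal septal hypertrophy, apical
# dilatation, LV lengthening, LVOT inward remodelling), outflow velocity
# scales inversely with the effective LVOT sector area, pressure drops follow
# the simplified Bernoulli relation, and genotype-positive fractions differ
# between groups so that genotype correlates with shape.

#' Simplified Bernoulli pressure drop
#'
#' `dP = 4 v^2`, the clinical conversion from peak Doppler velocity to LVOT
#' peak pressure drop.
#'
#' @param velocity_m_s peak velocity in m/s (>= 0, vectorized).
#' @return pressure drop in mmHg.
#' @export
#' @examples
#' bernoulli_pressure_drop(1.5) # 9 mmHg
bernoulli_pressure_drop <- function(velocity_m_s) {
  if (any(velocity_m_s < 0)) stop("velocity must be >= 0")
  4 * velocity_m_s^2
}

#' Specification of a two-group synthetic population
#'
#' Defaults state the package's synthetic world: a nonobstructive-leaning
#' group and an obstructive-leaning group whose means differ in LV length,
#' baseline thickness, septal bump amplitude, apical dilatation and LVOT
#' inward remodelling; reference outflow velocity 2.3 m/s with 15% lognormal
#' coefficient of variation; genotype-positive fraction 0.45 vs 0.30
#' (genotype-negative disease is the more obstructive phenotype).
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_param_means list of two [lv_geometry_params()] (group means).
#' @param group_param_sds named numeric vector of per-field standard
#'   deviations for the scalar geometry fields (shared by both groups;
#'   missing fields default to 0).
#' @param velocity_ref_m_s reference LVOT velocity for an unremodelled
#'   outflow (m/s).
#' @param velocity_noise_cv lognormal coefficient of variation on velocity.
#' @param genotype_positive_fraction length-2 vector, fraction of G+ per
#'   group.
#' @param stress_test_fraction fraction of subjects with a stress
#'   measurement (stress pressure drops are missing for the rest).
#' @param n_circ,n_long mesh resolution for generated surfaces.
#' @param seed RNG seed (single global stream; subject order is fixed).
#' @return an object of class `lv_population_spec`.
#' @export
population_spec <- function(n_per_group = 60,
                            group_param_means = list(
                              lv_geometry_params(),
                              lv_geometry_params(length_mm = 86,
                                                 base_thickness_mm = 9,
                                                 septal_bump_amp_mm = 9,
                                                 apical_dilation = 0.12,
                                                 lvot_inward_mm = 6)),
                            group_param_sds = c(length_mm = 6,
                                                endo_base_radius_mm = 2,
                                                base_thickness_mm = 1,
                                                septal_bump_amp_mm = 1.5,
                                                apical_dilation = 0.03,
                                                lvot_inward_mm = 0.8),
                            velocity_ref_m_s = 2.3,
                            velocity_noise_cv = 0.15,
                            genotype_positive_fraction = c(0.45, 0.30),
                            stress_test_fraction = 0.7,
                            n_circ = 48, n_long = 24,
                            seed = 1L) {
  stopifnot(n_per_group >= 2, length(group_param_means) == 2)
  if (any(genotype_positive_fraction < 0 | genotype_positive_fraction > 1))
    stop("genotype fractions must lie in [0, 1]")
  if (stress_test_fraction < 0 || stress_test_fraction > 1)
    stop("stress_test_fraction must lie in [0, 1]")
  if (any(group_param_sds < 0)) stop("all SDs must be >= 0")
  if (velocity_noise_cv < 0) stop("velocity_noise_cv must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_param_means = group_param_means,
                 group_param_sds = group_param_sds,
                 velocity_ref_m_s = velocity_ref_m_s,
                 velocity_noise_cv = velocity_noise_cv,
                 genotype_positive_fraction = genotype_positive_fraction,
                 stress_test_fraction = stress_test_fraction,
                 n_circ = as.integer(n_circ), n_long = as.integer(n_long),
                 seed = as.integer(seed)),
            class = "lv_population_spec")
}

# scalar geometry fields eligible for random variation
.scalar_fields <- c("length_mm", "endo_base_radius_mm", "base_thickness_mm",
                    "septal_bump_amp_mm", "spiral_drift_rad",
                    "apical_dilation", "lvot_inward_mm", "sphericity_exp")

# truncated-normal draw at +-3 SD, bounded retries
rtrunc3 <- function(mean, sd) {
  if (sd == 0) return(mean)
  for (i in 1:100) {
    x <- stats::rnorm(1, mean, sd)
    if (abs(x - mean) <= 3 * sd) return(x)
  }
  stop("generation error: truncated-normal retry budget exceeded")
}

#' Sample a synthetic LV cohort
#'
#' Per subject: geometry parameters are drawn from the group's truncated
#' normal (+-3 SD) field distributions (invalid geometries are redrawn, with
#' a bounded retry budget), the corresponded surface mesh is generated, the
#' LVOT peak velocity is `v = v_ref * (A_ref / A_sector) * noise` where
#' `A_sector` is the subject's effective LVOT sector area and `A_ref` the
#' same area with the inward remodelling removed, the rest pressure drop is
#' `4 v^2`, the stress drop is `4 (kappa v)^2` with a per-subject stress
#' multiplier `kappa ~ 1 + |N(0.4, 0.2)|` (missing for subjects without a
#' stress test), and genotype is drawn from the group's G+ fraction.  A
#' single seeded RNG stream with fixed subject order makes the cohort fully
#' reproducible.
#'
#' @param spec an [population_spec()] object.
#' @return an object of class `lv_cohort`: list with `subjects` (per-subject
#'   list of `params`, `mesh`, `record`), `table` (the cohort data frame:
#'   `subject_id`, `true_group`, `drop_rest_mmHg`, `drop_stress_mmHg`,
#'   `genotype`, `group`) and `spec`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "lv_population_spec"))
  set.seed(spec$seed)
  sdlog <- sqrt(log(1 + spec$velocity_noise_cv^2))
  subjects <- vector("list", 2L * spec$n_per_group)
  rows <- vector("list", length(subjects))
  idx <- 0L
  for (g in 1:2) {
    mu <- spec$group_param_means[[g]]
    for (s in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      mesh <- NULL
      for (try in 1:20) {
        p <- mu
        for (f in .scalar_fields) {
          sd_f <- if (f %in% names(spec$group_param_sds)) spec$group_param_sds[[f]] else 0
          p[[f]] <- rtrunc3(mu[[f]], sd_f)
        }
        p$apical_dilation <- max(p$apical_dilation, 0)
        p$lvot_inward_mm <- max(p$lvot_inward_mm, 0)
        mesh <- tryCatch(generate_lv_surface(p, spec$n_circ, spec$n_long),
                         error = function(e) NULL)
        if (!is.null(mesh)) break
      }
      if (is.null(mesh)) stop("generation error: could not draw a valid geometry")

      a_sector <- lvot_sector_area(mesh)
      p_ref <- p; p_ref$lvot_inward_mm <- 0
      a_ref <- lvot_sector_area(generate_lv_surface(p_ref, spec$n_circ, spec$n_long))
      noise <- if (sdlog > 0) exp(stats::rnorm(1, 0, sdlog)) else 1
      v <- spec$velocity_ref_m_s * (a_ref / a_sector) * noise
      drop_rest <- bernoulli_pressure_drop(v)
      kappa <- 1 + abs(stats::rnorm(1, 0.4, 0.2))
      has_stress <- stats::runif(1) < spec$stress_test_fraction
      drop_stress <- if (has_stress) bernoulli_pressure_drop(kappa * v) else NA_real_
      genotype <- if (stats::runif(1) < spec$genotype_positive_fraction[g]) "G+" else "G-"

      record <- list(subject_id = sprintf("S%03d", idx),
                     true_group = c("A", "B")[g],
                     drop_rest_mmHg = drop_rest,
                     drop_stress_mmHg = drop_stress,
                     genotype = genotype)
      subjects[[idx]] <- list(params = p, mesh = mesh, record = record)
      rows[[idx]] <- as.data.frame(record, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$group <- assign_groups(tab)$table$group
  for (i in seq_along(subjects)) subjects[[i]]$record$group <- tab$group[i]
  structure(list(subjects = subjects, table = tab, spec = spec),
            class = "lv_cohort")
}

#' @export
print.lv_cohort <- function(x, ...) {
  cat(sprintf("Synthetic LV cohort: %d subjects (%d per group), seed %d\n",
              nrow(x$table), x$spec$n_per_group, x$spec$seed))
  print(table(x$table$group))
  invisible(x)
}

#' Extract the list of cohort meshes
#' @param cohort an `lv_cohort`.
#' @return list of `lv_mesh` objects in cohort order.
#' @export
cohort_meshes <- function(cohort) lapply(cohort$subjects, `[[`, "mesh")

#' Write / read the cohort table as CSV
#'
#' Columns: `subject_id`, `drop_rest_mmHg`, `drop_stress_mmHg` (empty =
#' missing), `genotype`, `group`.
#'
#' @param cohort an `lv_cohort` or a cohort data frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  tab <- if (inherits(cohort, "lv_cohort")) cohort$table else cohort
  utils::write.csv(tab[, c("subject_id", "drop_rest_mmHg", "drop_stress_mmHg",
                           "genotype", "group")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character"))
}
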