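# Study orchestration: group assignment, per-mode screening, the three
# discriminant axes with robustness variants, and report generation.

#' Study configuration
#'
#' @param rest_threshold_mmHg obstruction threshold on the rest pressure
#'   drop (default 30; comparisons are inclusive, >=).
#' @param robustness_threshold_mmHg alternative severe-obstruction threshold
#'   for the rest-axis robustness refit (default 50).
#' @param variance_threshold cumulative explained-variance fraction for mode
#'   inclusion (default 0.90).
#' @param axes subset of `c("rest", "dstress", "gen")` to run.
#' @param paired_only also refit the rest axis on the paired subset
#'   (subjects with both rest and stress measurements).
#' @param k_sd extreme-shape magnitude in Z units.
#' @param alpha significance level for per-mode t-tests.
#' @param correction multiplicity correction for per-mode tests: "none"
#'   (default, mirrors the study design) or "bonferroni".
#' @param shrinkage LDA shrinkage setting (see [fit_lda()]).
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return an object of class `lv_study_config`.
#' @export
study_config <- function(rest_threshold_mmHg = 30,
                         robustness_threshold_mmHg = 50,
                         variance_threshold = 0.90,
                         axes = c("rest", "dstress", "gen"),
                         paired_only = TRUE,
                         k_sd = 3,
                         alpha = 0.05,
                         correction = c("none", "bonferroni"),
                         shrinkage = "auto",
                         seed = 1L) {
  stopifnot(rest_threshold_mmHg > 0, robustness_threshold_mmHg > 0,
            variance_threshold > 0, variance_threshold <= 1)
  axes <- match.arg(axes, several.ok = TRUE)
  structure(list(rest_threshold_mmHg = rest_threshold_mmHg,
                 robustness_threshold_mmHg = robustness_threshold_mmHg,
                 variance_threshold = variance_threshold,
                 axes = axes, paired_only = paired_only, k_sd = k_sd,
                 alpha = alpha, correction = match.arg(correction),
                 shrinkage = shrinkage, seed = as.integer(seed)),
            class = "lv_study_config")
}

#' Assign obstruction groups from pressure drops
#'
#' `R+` if the rest drop is >= the threshold (inclusive), else `R-`; among
#' subjects non-obstructive at rest with a stress measurement, `R-S+` if the
#' stress drop reaches the threshold, else `R-S-`.  Subjects obstructive at
#' rest are excluded from the stress comparison; missing stress values give
#' rest groups only (never imputed).
#'
#' @param records data frame with `drop_rest_mmHg`, `drop_stress_mmHg`
#'   (NA = missing) and optionally `genotype`.
#' @param rest_threshold_mmHg threshold in mmHg (default 30).
#' @param stress_threshold_mmHg threshold for the stress drop (defaults to
#'   the rest threshold).
#' @return list with `table` (records plus `rest_group`, `stress_group` and
#'   a combined single `group` label) and `counts`.
#' @export
assign_groups <- function(records, rest_threshold_mmHg = 30,
                          stress_threshold_mmHg = rest_threshold_mmHg) {
  rest <- records$drop_rest_mmHg
  strs <- records$drop_stress_mmHg
  if (any(rest < 0, na.rm = TRUE) || any(strs < 0, na.rm = TRUE))
    stop("validation error: negative pressure drop")
  if (any(is.na(rest))) stop("drop_rest_mmHg required for every record")

  rest_group <- ifelse(rest >= rest_threshold_mmHg, "R+", "R-")
  stress_group <- rep(NA_character_, length(rest))
  elig <- rest < rest_threshold_mmHg & !is.na(strs)
  stress_group[elig] <- ifelse(strs[elig] >= stress_threshold_mmHg, "R-S+", "R-S-")
  group <- ifelse(rest_group == "R+", "R+",
                  ifelse(is.na(stress_group), "R-", stress_group))
  tab <- records
  tab$rest_group <- rest_group
  tab$stress_group <- stress_group
  tab$group <- group
  counts <- c("R-" = sum(rest_group == "R-"), "R+" = sum(rest_group == "R+"),
              "R-S-" = sum(stress_group == "R-S-", na.rm = TRUE),
              "R-S+" = sum(stress_group == "R-S+", na.rm = TRUE))
  list(table = tab, counts = counts)
}

#' Per-mode two-sample comparison of shape coefficients
#'
#' Two-tailed Student's t-test (pooled variance) per mode; no multiplicity
#' correction by default, mirroring per-mode screening as reported, with a
#' Bonferroni option.
#'
#' @param coeffs_A,coeffs_B coefficient matrices (subjects x modes).
#' @param alpha significance level.
#' @param correction "none" or "bonferroni".
#' @return data frame with per-mode means, t, df, p and significance flag.
#' @export
compare_modes <- function(coeffs_A, coeffs_B, alpha = 0.05,
                          correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  A <- as.matrix(coeffs_A); B <- as.matrix(coeffs_B)
  if (ncol(A) != ncol(B)) stop("mode-count mismatch")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 subjects")
  mA <- colMeans(A); mB <- colMeans(B)
  vA <- apply(A, 2, stats::var); vB <- apply(B, 2, stats::var)
  sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  df <- nA + nB - 2
  tstat <- numeric(ncol(A)); p <- numeric(ncol(A))
  zero <- sp2 < 1e-300
  if (any(zero)) warning("zero pooled variance in ", sum(zero), " mode(s); p set to 1")
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tstat[!zero] <- (mA[!zero] - mB[!zero]) / se[!zero]
  tstat[zero] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[zero] <- 1
  thr <- if (correction == "bonferroni") alpha / ncol(A) else alpha
  data.frame(mode = seq_len(ncol(A)), mean_A = mA, mean_B = mB,
             t = tstat, df = df, p = p, significant = p < thr)
}

angle_between <- function(a, b) {
  cs <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

#' Run the full statistical shape analysis study
#'
#' Aligns the cohort meshes, fits the PCA shape model, selects modes to the
#' cumulative-variance threshold, assigns obstruction groups, then for each
#' requested axis screens modes with t-tests, fits the Fisher discriminant,
#' validates it (resubstitution and leave-one-out AUC), Z-scores every
#' subject and synthesizes the +-k SD extreme shapes with their AHA
#' bull's-eye maps and LVOT sector areas.  The rest axis additionally gets
#' the severe-threshold (50 mmHg) robustness refit and the paired-subset
#' variant, each summarized by its angle to the main rest axis.  The whole
#' analysis is deterministic.
#'
#' @param cohort an `lv_cohort` (or a list with `table` and meshes passed
#'   via `meshes`).
#' @param config an [study_config()].
#' @param meshes optional list of `lv_mesh` overriding the cohort meshes
#'   (e.g. meshes personalized from masks with [fit_template()]).
#' @param out_dir optional output directory; if given, tables, models,
#'   reports, extreme meshes and a manifest with file hashes are written.
#' @return an object of class `lv_study`.
#' @export
run_study <- function(cohort, config = study_config(), meshes = NULL,
                      out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("study stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  tab <- cohort$table
  if (is.null(meshes)) meshes <- cohort_meshes(cohort)
  stopifnot(length(meshes) == nrow(tab))

  vectors <- stage("align", align_meshes(meshes))
  ssm <- stage("ssm", fit_pca(vectors, config$variance_threshold))
  K <- ssm$n_modes_selected
  coeffs <- coef(ssm)[, seq_len(K), drop = FALSE]

  ga <- stage("groups", assign_groups(tab, config$rest_threshold_mmHg))
  tab <- ga$table

  axis_def <- list(
    rest = list(mask = !is.na(tab$drop_rest_mmHg),
                y = tab$rest_group == "R+", labels = c("R-", "R+")),
    dstress = list(mask = !is.na(tab$stress_group),
                   y = tab$stress_group == "R-S+", labels = c("R-S-", "R-S+")),
    gen = list(mask = !is.na(tab$genotype) & tab$genotype %in% c("G-", "G+"),
               y = tab$genotype == "G+", labels = c("G-", "G+")))

  axes <- list()
  for (ax in config$axes) {
    d <- axis_def[[ax]]
    axes[[ax]] <- stage(paste0("axis_", ax),
                        run_axis(coeffs, d$mask, d$y, d$labels, ssm, config))
  }

  robustness <- NULL
  if ("rest" %in% names(axes) && !is.null(axes$rest)) {
    robustness <- stage("robustness", {
      out <- list()
      y50 <- tab$drop_rest_mmHg >= config$robustness_threshold_mmHg
      f50 <- fit_axis_only(coeffs, !is.na(tab$drop_rest_mmHg), y50,
                           c("R-", "R+"), config)
      if (!is.null(f50))
        out$threshold_50 <- list(
          lda = f50, angle_to_rest_deg = angle_between(f50$weights,
                                                       axes$rest$lda$weights))
      if (config$paired_only) {
        paired <- !is.na(tab$drop_stress_mmHg)
        fp <- fit_axis_only(coeffs, paired, tab$rest_group == "R+",
                            c("R-", "R+"), config)
        if (!is.null(fp))
          out$rest_paired <- list(
            lda = fp, angle_to_rest_deg = angle_between(fp$weights,
                                                        axes$rest$lda$weights),
            n_paired = sum(paired))
      }
      out
    })
  }

  ztab <- data.frame(subject_id = tab$subject_id, group = tab$group,
                     genotype = if (!is.null(tab$genotype)) tab$genotype else NA,
                     stringsAsFactors = FALSE)
  for (ax in names(axes))
    if (!is.null(axes[[ax]]))
      ztab[[paste0("z_", ax)]] <- zscore(axes[[ax]]$lda, coeffs)

  # genotype projection on the obstruction axes (G+ vs G- mean Z)
  genotype_projection <- NULL
  if (!is.null(tab$genotype) && any(tab$genotype %in% c("G-", "G+"))) {
    gp <- list()
    for (ax in intersect(c("rest", "dstress"), names(axes))) {
      if (is.null(axes[[ax]])) next
      z <- ztab[[paste0("z_", ax)]]
      gpos <- tab$genotype == "G+"; gneg <- tab$genotype == "G-"
      if (sum(gpos) >= 2 && sum(gneg) >= 2) {
        tt <- stats::t.test(z[gneg], z[gpos], var.equal = TRUE)
        gp[[ax]] <- list(mean_z_Gneg = mean(z[gneg]), mean_z_Gpos = mean(z[gpos]),
                         p = tt$p.value)
      }
    }
    genotype_projection <- gp
  }

  manifest <- list(package = "lvshape",
                   version = as.character(utils::packageVersion("lvshape")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = unclass(config),
                   n_subjects = nrow(tab),
                   n_modes_selected = K,
                   group_counts = as.list(ga$counts))

  report <- structure(list(config = config, ssm = ssm, coeffs = coeffs,
                           groups = ga, table = tab, axes = axes,
                           robustness = robustness, zscores = ztab,
                           genotype_projection = genotype_projection,
                           manifest = manifest),
                      class = "lv_study")
  if (!is.null(out_dir)) write_study_outputs(report, out_dir)
  report
}

# fit one axis end to end: screening, LDA, validation, extremes
run_axis <- function(coeffs, mask, y, labels, ssm, config) {
  y <- y[mask]
  C <- coeffs[mask, , drop = FALSE]
  if (sum(y) < 3 || sum(!y) < 3) {
    warning("axis ", labels[2], " skipped: fewer than 3 subjects in a group")
    return(NULL)
  }
  A <- C[!y, , drop = FALSE]; B <- C[y, , drop = FALSE]
  modes_tab <- compare_modes(A, B, alpha = config$alpha,
                             correction = config$correction)
  lda <- fit_lda(A, B, labels = labels, positive = 2,
                 shrinkage = config$shrinkage)
  validation <- loo_cv_auc(C, y, shrinkage = config$shrinkage)
  validation$threshold_mmHg <- config$rest_threshold_mmHg
  extremes <- axis_extreme_shapes(lda, ssm, k_sd = config$k_sd)
  summarize <- function(mesh) {
    th <- wall_thickness(mesh)
    list(mesh = mesh, aha17 = aha17_map(mesh, th),
         lvot_sector_area_mm2 = lvot_sector_area(mesh),
         mean_thickness_mm = mean(th, na.rm = TRUE))
  }
  list(labels = labels, n_per_group = c(sum(!y), sum(y)),
       modes = modes_tab, lda = lda, validation = validation,
       extremes = list(minus = summarize(extremes$minus),
                       plus = summarize(extremes$plus)))
}

fit_axis_only <- function(coeffs, mask, y, labels, config) {
  y <- y[mask]
  C <- coeffs[mask, , drop = FALSE]
  if (sum(y) < 3 || sum(!y) < 3) return(NULL)
  fit_lda(C[!y, , drop = FALSE], C[y, , drop = FALSE], labels = labels,
          positive = 2, shrinkage = config$shrinkage)
}

#' @export
print.lv_study <- function(x, ...) {
  cat("LV statistical shape analysis study\n")
  cat(sprintf("  %d subjects, %d PCA modes at %.0f%% variance\n",
              nrow(x$table), x$ssm$n_modes_selected,
              100 * x$config$variance_threshold))
  for (ax in names(x$axes)) {
    a <- x$axes[[ax]]
    if (is.null(a)) { cat(sprintf("  axis %s: skipped\n", ax)); next }
    cat(sprintf("  axis %-8s %s vs %s (n = %d/%d): AUC %.3f resub, %.3f LOO\n",
                ax, a$labels[1], a$labels[2], a$n_per_group[1], a$n_per_group[2],
                a$validation$auc_resubstitution, a$validation$auc_loo))
  }
  invisible(x)
}

#' Project an external cohort through a frozen model and axis
#'
#' External meshes are rigidly aligned to the shape-model mean, projected
#' through the frozen PCA (no refitting), restricted to the axis's modes and
#' Z-scored with the trained normalization; discrimination is summarized by
#' the external AUC.
#'
#' @param ssm an `lv_ssm`.
#' @param axis an `lv_lda` trained on the leading modes of `ssm`.
#' @param external_meshes list of `lv_mesh` with the training topology.
#' @param external_labels binary labels (positive = obstructive-like).
#' @return list with `auc`, `z` and `n_per_group`.
#' @export
project_external <- function(ssm, axis, external_meshes, external_labels) {
  stopifnot(inherits(ssm, "lv_ssm"), inherits(axis, "lv_lda"))
  coeffs <- predict(ssm, external_meshes, n_modes = axis$n_modes)
  z <- zscore(axis, coeffs)
  y <- as_binary(external_labels)
  list(auc = auc(z, y), z = z,
       n_per_group = c(neg = sum(!y), pos = sum(y)))
}
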