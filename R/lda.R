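# Fisher linear discriminant remodelling axes and their validation.
#
# The discriminant lives in standardized PCA-coefficient space restricted to
# the modes reaching the cumulative-variance rule.  Only the axis direction
# and the continuous, normalized Z-score are used; no classification
# threshold is ever applied (equal class priors are implicit).

#' Fit a Fisher discriminant axis between two shape-coefficient groups
#'
#' Weights are proportional to `Sw^-1 (mu_B - mu_A)` with `Sw` the pooled
#' within-class covariance, optionally shrunk toward a scaled identity with
#' a Ledoit-Wolf-style data-driven intensity (the default; many modes vs
#' possibly small groups make the plain pooled estimate ill-conditioned).
#' Scores are normalized to Z-scores using the pooled training mean and SD,
#' and the axis is oriented so that the designated positive group (the
#' obstructive-like or genotype-positive one) has the larger mean Z.
#'
#' @param coeffs_A,coeffs_B coefficient matrices (subjects x modes), both
#'   groups restricted to the same included modes.
#' @param labels character length 2: names of groups A and B.
#' @param positive which group gets positive Z orientation (1 or 2, or a
#'   group name; default group B).
#' @param shrinkage `"auto"` (default: plain pooled solve while the pooled
#'   covariance is sample-adequate and numerically invertible, Ledoit-Wolf
#'   shrinkage engaged otherwise), `"lw"` (always use the Ledoit-Wolf
#'   estimate), a number in \[0, 1\], or `0`/`"none"` for the plain solve.
#' @return an object of class `lv_lda`: `weights`, `score_mean`,
#'   `score_sd`, `labels`, `positive`, `z_train`, `y_train`,
#'   `shrinkage_gamma`, `n_modes`.
#' @export
fit_lda <- function(coeffs_A, coeffs_B, labels = c("A", "B"), positive = 2,
                    shrinkage = "auto") {
  A <- as.matrix(coeffs_A); B <- as.matrix(coeffs_B)
  if (ncol(A) != ncol(B)) stop("mode-count mismatch between groups")
  nA <- nrow(A); nB <- nrow(B)
  if (nA < 2 || nB < 2) stop("each group needs at least 2 subjects")
  if (is.character(positive)) positive <- match(positive, labels)
  stopifnot(positive %in% 1:2)

  muA <- colMeans(A); muB <- colMeans(B)
  delta <- muB - muA
  if (sqrt(sum(delta^2)) < 1e-12)
    stop("degenerate-separation error: identical group means")

  W <- rbind(sweep(A, 2, muA), sweep(B, 2, muB))
  n <- nrow(W); p <- ncol(W)
  S <- crossprod(W) / n

  gamma <- 0
  if (identical(shrinkage, "auto")) {
    # shrinkage exists to guard against sample starvation (many modes vs
    # small groups) and singular pooled covariances; when neither applies
    # the plain solve is the Fisher optimum and must not be biased
    starved <- n <= p + 2
    near_singular <- !starved && rcond_psd(S) < 1e-10
    if (starved || near_singular) {
      gamma <- max(lw_gamma(W, S), 1e-3)
      if (near_singular)
        warning("singular within-class covariance: shrinkage regularization applied")
    }
  } else if (identical(shrinkage, "lw")) {
    gamma <- lw_gamma(W, S)
  } else if (is.numeric(shrinkage)) {
    stopifnot(shrinkage >= 0, shrinkage <= 1)
    gamma <- shrinkage
  } else if (!identical(shrinkage, "none")) {
    stop("shrinkage must be 'auto', 'lw', 'none' or a number in [0, 1]")
  }
  m <- mean(diag(S))
  Sstar <- (1 - gamma) * S + gamma * m * diag(p)
  w <- tryCatch(solve(Sstar, delta), error = function(e) {
    warning("singular within-class covariance: ridge regularization applied")
    solve(Sstar + 1e-8 * max(m, 1e-12) * diag(p), delta)
  })

  scores <- rbind(A, B) %*% w
  score_mean <- mean(scores)
  score_sd <- stats::sd(scores)
  if (score_sd < 1e-300) stop("degenerate scores: zero variance along the axis")
  y <- c(rep(labels[1], nA), rep(labels[2], nB))
  z <- (scores - score_mean) / score_sd
  flipped <- FALSE
  if (mean(z[y == labels[positive]]) < mean(z[y != labels[positive]])) {
    w <- -w
    score_mean <- -score_mean
    z <- -z
    flipped <- TRUE
  }
  structure(list(weights = as.numeric(w), score_mean = score_mean,
                 score_sd = score_sd, labels = labels,
                 positive = labels[positive], orientation_flipped = flipped,
                 z_train = as.numeric(z), y_train = y,
                 shrinkage_gamma = gamma, n_modes = p),
            class = "lv_lda")
}

# reciprocal condition number of a symmetric PSD matrix
rcond_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

# Ledoit-Wolf shrinkage intensity toward mean(diag(S)) * I, computed on the
# within-group-centred rows W (S = crossprod(W)/n)
lw_gamma <- function(W, S) {
  n <- nrow(W); p <- ncol(W)
  m <- mean(diag(S))
  d2 <- sum((S - m * diag(p))^2) / p
  if (d2 < 1e-300) return(0)
  b2bar <- (sum(rowSums(W^2)^2) / n^2 - sum(S^2) / n) / p
  b2 <- min(b2bar, d2)
  max(0, min(1, b2 / d2))
}

#' Z-scores of subjects along a discriminant axis
#'
#' Applies the trained normalization and orientation; valid for subjects
#' outside the training set (external projection).
#'
#' @param model an `lv_lda`.
#' @param coeffs coefficient matrix or vector over the model's modes.
#' @return numeric vector of Z-scores.
#' @export
zscore <- function(model, coeffs) {
  stopifnot(inherits(model, "lv_lda"))
  C <- if (is.null(dim(coeffs))) matrix(coeffs, nrow = 1) else as.matrix(coeffs)
  if (ncol(C) != model$n_modes) stop("mode-count mismatch with trained axis")
  as.numeric((C %*% model$weights - model$score_mean) / model$score_sd)
}

#' @export
print.lv_lda <- function(x, ...) {
  cat(sprintf("Fisher LDA axis: %s vs %s (positive Z = %s), %d modes\n",
              x$labels[1], x$labels[2], x$positive, x$n_modes))
  cat(sprintf("  shrinkage gamma = %.4f; training Z by group: %s = %.2f, %s = %.2f\n",
              x$shrinkage_gamma,
              x$labels[1], mean(x$z_train[x$y_train == x$labels[1]]),
              x$labels[2], mean(x$z_train[x$y_train == x$labels[2]])))
  invisible(x)
}

#' @export
predict.lv_lda <- function(object, newdata, ...) zscore(object, newdata)

#' Z-score distributions by group
#' @param x an `lv_lda`.
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.lv_lda <- function(x, ...) {
  graphics::boxplot(split(x$z_train, x$y_train), ylab = "Z-score", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Fraction of (positive, negative) pairs with the positive score higher;
#' ties count one half.
#'
#' @param scores numeric scores.
#' @param labels binary labels (logical, 0/1, or two-level factor/character;
#'   the higher/TRUE/second level is positive).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (length(u) > 2) stop("labels must be binary")
    return(labels == max(u))
  }
  f <- factor(labels)
  if (nlevels(f) > 2) stop("labels must be binary")
  f == levels(f)[nlevels(f)]
}

#' Resubstitution and leave-one-out AUC of a discriminant axis
#'
#' For each subject the axis (weights and Z normalization) is refit on the
#' remaining n - 1 and the held-out subject is scored; the LOO AUC is
#' computed over held-out Z-scores.  The PCA model is held fixed (not refit
#' per fold).  Folds that would lose one class entirely are skipped with a
#' warning.
#'
#' @param coeffs coefficient matrix (subjects x modes).
#' @param labels two-group labels (see [auc()]; positive = second level).
#' @param shrinkage passed to [fit_lda()].
#' @return a `ValidationReport` list: `auc_resubstitution`, `auc_loo`,
#'   `z_loo`, `n_per_group`, `n_folds_skipped`.
#' @export
loo_cv_auc <- function(coeffs, labels, shrinkage = "auto") {
  C <- as.matrix(coeffs)
  y <- as_binary(labels)
  n <- nrow(C)
  if (n < 4 || sum(y) < 2 || sum(!y) < 2)
    stop("need n >= 4 with at least 2 subjects per class")

  full <- fit_lda(C[!y, , drop = FALSE], C[y, , drop = FALSE],
                  labels = c("neg", "pos"), positive = 2, shrinkage = shrinkage)
  auc_res <- auc(zscore(full, C), y)

  z_loo <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (sum(yi) < 2 || sum(!yi) < 2) { skipped <- skipped + 1L; next }
    m <- fit_lda(C[-i, , drop = FALSE][!yi, , drop = FALSE],
                 C[-i, , drop = FALSE][yi, , drop = FALSE],
                 labels = c("neg", "pos"), positive = 2, shrinkage = shrinkage)
    z_loo[i] <- zscore(m, C[i, ])
  }
  if (skipped > 0L) warning(skipped, " LOO folds skipped (class lost)")
  keep <- !is.na(z_loo)
  structure(list(auc_resubstitution = auc_res,
                 auc_loo = auc(z_loo[keep], y[keep]),
                 z_loo = z_loo,
                 n_per_group = c(neg = sum(!y), pos = sum(y)),
                 n_folds_skipped = skipped),
            class = "lv_validation")
}

#' @export
print.lv_validation <- function(x, ...) {
  cat(sprintf("AUC: %.3f resubstitution, %.3f leave-one-out (n = %d + %d)\n",
              x$auc_resubstitution, x$auc_loo, x$n_per_group[1], x$n_per_group[2]))
  invisible(x)
}

#' Extreme shapes along a discriminant axis
#'
#' Returns the pair of shapes whose re-projected Z-scores are exactly
#' `-k_sd` and `+k_sd`: coefficients move along the unit axis direction in
#' standardized space, scaled so one step changes Z by one.
#'
#' @param model an `lv_lda` trained on the leading `model$n_modes`
#'   standardized coefficients of `pca`.
#' @param pca the `lv_ssm` the coefficients came from.
#' @param k_sd extreme magnitude in Z units (default 3).
#' @return list with meshes `minus` and `plus`.
#' @export
axis_extreme_shapes <- function(model, pca, k_sd = 3) {
  stopifnot(inherits(model, "lv_lda"), inherits(pca, "lv_ssm"), k_sd > 0)
  w <- model$weights
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("zero weights")
  dir <- w / nw
  beta <- function(zt) (model$score_mean + zt * model$score_sd) / nw
  pad <- function(cc) c(cc, rep(0, length(pca$variances) - length(cc)))
  list(minus = reconstruct(pca, pad(beta(-k_sd) * dir), standardized = TRUE,
                           as_mesh = TRUE),
       plus = reconstruct(pca, pad(beta(k_sd) * dir), standardized = TRUE,
                          as_mesh = TRUE))
}
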