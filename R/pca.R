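# PCA statistical shape model (point-distribution model).

#' Fit a PCA statistical shape model
#'
#' Principal component analysis of aligned shape vectors via singular value
#' decomposition of the centred data matrix (equivalent to an
#' eigendecomposition of the sample covariance with divisor n - 1, but
#' numerically safer when the shape dimension far exceeds the cohort size).
#' All `min(3M, n - 1)` modes are retained; `select_modes()` applies the
#' cumulative explained-variance rule.  Mode signs are fixed
#' deterministically: the coordinate of largest absolute loading is made
#' positive.  Eigenvalue ties keep the SVD ordering.
#'
#' @param vectors list of shape vectors (from [align_meshes()]) or a numeric
#'   matrix with one shape per row.
#' @param variance_threshold cumulative explained-variance fraction used to
#'   preselect `n_modes_selected` (default 0.90).
#' @return an object of class `lv_ssm` with elements `mean_shape`, `modes`
#'   (3M x K orthonormal), `variances` (mm^2, non-increasing),
#'   `explained_ratio`, `scores` (training raw scores, n x K),
#'   `n_subjects`, `n_modes_selected`, `topology`.
#' @seealso [project()], [reconstruct()], [select_modes()],
#'   [synthesize_extreme()]
#' @export
fit_pca <- function(vectors, variance_threshold = 0.90) {
  topology <- NULL
  if (is.list(vectors)) {
    topology <- attr(vectors[[1]], "topology")
    X <- do.call(rbind, lapply(vectors, as.numeric))
  } else {
    topology <- attr(vectors, "topology")
    X <- as.matrix(vectors)
  }
  n <- nrow(X)
  if (n < 3) stop("at least 3 subjects are required to fit a shape model")
  if (any(!is.finite(X))) stop("shape vectors must be finite")

  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  K <- min(ncol(X), n - 1L)
  sv <- svd(Xc, nu = K, nv = K)
  variances <- sv$d[seq_len(K)]^2 / (n - 1)
  modes <- sv$v

  # deterministic sign convention
  for (k in seq_len(K)) {
    j <- which.max(abs(modes[, k]))
    if (modes[j, k] < 0) modes[, k] <- -modes[, k]
  }
  scores <- Xc %*% modes

  total_var <- sum(variances)
  model <- structure(list(mean_shape = structure(mean_shape, topology = topology),
                          modes = modes,
                          variances = variances,
                          explained_ratio = variances / total_var,
                          scores = scores,
                          n_subjects = n,
                          topology = topology,
                          variance_threshold = variance_threshold),
                     class = "lv_ssm")
  model$n_modes_selected <- select_modes(model, variance_threshold)
  model
}

#' Number of modes reaching a cumulative variance threshold
#'
#' Smallest K' whose cumulative explained-variance ratio reaches the
#' threshold; the boundary is inclusive ("a minimum of 90%" counts a
#' cumulative ratio of exactly 0.90).
#'
#' @param model an `lv_ssm`.
#' @param threshold fraction in (0, 1\].
#' @return integer number of modes.
#' @export
select_modes <- function(model, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  cum <- cumsum(model$explained_ratio)
  k <- which(cum >= threshold - 1e-9)
  if (length(k) == 0L) stop("threshold not reachable by available modes")
  k[1]
}

#' Project aligned shapes onto a shape model
#'
#' @param model an `lv_ssm`.
#' @param x a shape vector, a matrix of shape vectors (rows), or a list of
#'   shape vectors, already aligned to the model frame (use
#'   [align_to_reference()] or `predict()` for raw meshes).
#' @param standardized return per-mode SD units (raw score / sqrt(variance),
#'   default) rather than raw scores (mm).
#' @param n_modes number of leading modes to return (default: all).
#' @return numeric matrix of coefficients (subjects x modes).
#' @export
project <- function(model, x, standardized = TRUE,
                    n_modes = length(model$variances)) {
  stopifnot(inherits(model, "lv_ssm"))
  X <- shapes_as_matrix(x)
  if (ncol(X) != length(model$mean_shape))
    stop("dimension mismatch between shapes and model")
  raw <- sweep(X, 2, model$mean_shape) %*% model$modes[, seq_len(n_modes), drop = FALSE]
  if (standardized)
    raw <- sweep(raw, 2, sqrt(model$variances[seq_len(n_modes)]), "/")
  raw
}

shapes_as_matrix <- function(x) {
  if (is.list(x) && !is.null(x$endo)) stop("align meshes before projecting (see predict.lv_ssm)")
  if (is.list(x)) return(do.call(rbind, lapply(x, as.numeric)))
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1) else as.matrix(x)
}

#' Reconstruct shapes from model coefficients
#'
#' @param model an `lv_ssm`.
#' @param coefficients numeric vector (one shape) or matrix (subjects x
#'   modes); may use fewer modes than the model holds.
#' @param standardized whether `coefficients` are in per-mode SD units.
#' @param as_mesh refold the (single) reconstructed vector into an
#'   `lv_mesh` using the model topology.
#' @return a shape vector, matrix of shape vectors, or `lv_mesh`.
#' @export
reconstruct <- function(model, coefficients, standardized = TRUE,
                        as_mesh = FALSE) {
  stopifnot(inherits(model, "lv_ssm"))
  C <- if (is.null(dim(coefficients))) matrix(coefficients, nrow = 1)
       else as.matrix(coefficients)
  k <- ncol(C)
  if (k > length(model$variances)) stop("more coefficients than model modes")
  raw <- if (standardized) sweep(C, 2, sqrt(model$variances[seq_len(k)]), "*") else C
  X <- sweep(raw %*% t(model$modes[, seq_len(k), drop = FALSE]), 2,
             model$mean_shape, "+")
  if (as_mesh) {
    if (nrow(X) != 1L) stop("as_mesh requires a single coefficient vector")
    return(mesh_from_vector(X[1, ], model$topology))
  }
  if (nrow(X) == 1L) structure(X[1, ], topology = model$topology) else X
}

#' Synthesize an extreme shape along a direction in coefficient space
#'
#' Reconstructs the shape `k_sd` standardized units from the mean along a
#' unit direction in standardized-coefficient space; used for +-3 SD
#' extremes of PCA modes and discriminant axes.
#'
#' @param model an `lv_ssm`.
#' @param direction unit vector in standardized-coefficient space.
#' @param k_sd number of SD to travel (may be negative).
#' @return an `lv_mesh`.
#' @export
synthesize_extreme <- function(model, direction, k_sd) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must be non-zero")
  reconstruct(model, k_sd * direction / nrm, standardized = TRUE, as_mesh = TRUE)
}

#' @export
print.lv_ssm <- function(x, ...) {
  cat(sprintf("PCA statistical shape model: %d subjects, %d modes (%d selected at %.0f%% variance)\n",
              x$n_subjects, length(x$variances), x$n_modes_selected,
              100 * x$variance_threshold))
  invisible(x)
}

#' @export
summary.lv_ssm <- function(object, n = 10, ...) {
  k <- min(n, length(object$variances))
  tab <- data.frame(mode = seq_len(k),
                    variance_mm2 = object$variances[seq_len(k)],
                    explained = object$explained_ratio[seq_len(k)],
                    cumulative = cumsum(object$explained_ratio)[seq_len(k)])
  print(x = tab, row.names = FALSE, digits = 4)
  cat(sprintf("%d of %d modes reach %.0f%% cumulative variance\n",
              object$n_modes_selected, length(object$variances),
              100 * object$variance_threshold))
  invisible(tab)
}

#' Training shape coefficients
#' @param object an `lv_ssm`.
#' @param standardized per-mode SD units (default) or raw mm scores.
#' @param ... unused.
#' @return matrix subjects x modes.
#' @export
coef.lv_ssm <- function(object, standardized = TRUE, ...) {
  if (standardized) sweep(object$scores, 2, sqrt(object$variances), "/")
  else object$scores
}

#' Project new shapes through a fitted shape model
#'
#' @param object an `lv_ssm`.
#' @param newdata an `lv_mesh`, list of meshes, or matrix/list of aligned
#'   shape vectors.  Meshes are rigidly aligned to the model mean first.
#' @param standardized per-mode SD units (default).
#' @param n_modes number of leading modes (default: all).
#' @param ... unused.
#' @return coefficient matrix (subjects x modes).
#' @export
predict.lv_ssm <- function(object, newdata, standardized = TRUE,
                           n_modes = length(object$variances), ...) {
  if (inherits(newdata, "lv_mesh")) newdata <- list(newdata)
  if (is.list(newdata) && length(newdata) && inherits(newdata[[1]], "lv_mesh")) {
    newdata <- do.call(rbind, lapply(newdata, function(m)
      as.numeric(align_to_reference(m, object$mean_shape))))
  }
  project(object, newdata, standardized = standardized, n_modes = n_modes)
}

#' Scree plot of a shape model
#' @param x an `lv_ssm`.
#' @param n number of modes to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.lv_ssm <- function(x, n = min(20, length(x$variances)), ...) {
  graphics::barplot(100 * x$explained_ratio[seq_len(n)],
                    names.arg = seq_len(n),
                    xlab = "PCA mode", ylab = "explained variance (%)", ...)
  invisible(x)
}

#' Sample new shapes from the model's Gaussian distribution
#' @param object an `lv_ssm`.
#' @param nsim number of shapes.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return matrix of shape vectors (nsim x 3M).
#' @export
simulate.lv_ssm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(object$variances)
  C <- matrix(stats::rnorm(nsim * K), nsim, K)
  reconstruct(object, C, standardized = TRUE)
}
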