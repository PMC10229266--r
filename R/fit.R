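# Template-mesh personalization to a binary short-axis segmentation.
#
# The reference high-order mesh-personalization frameworks use cubic-Hermite
# meshes; this package substitutes a linear surface-grid template fitted by
# iterated normal projection with Laplacian regularization, which preserves
# the only property the statistical pipeline needs: node correspondence.

#' Fit the shared template mesh to a binary myocardial mask
#'
#' Endocardial and epicardial boundary points are extracted per slice from
#' the mask (marching squares; the inner loop is the endocardium).  After an
#' optional rigid + isotropic-scale initialization (long-axis alignment from
#' principal axes, in-plane rotation and axis sign chosen by a coarse
#' nearest-boundary cost search), each node is projected along its surface
#' normal toward its nearest corresponding boundary point, with the
#' projection displacement field relaxed by grid Laplacian smoothing before
#' it is applied, until the mean nodal displacement falls below `tol` or
#' `max_iter` is reached.
#'
#' @param mask an `lv_mask` (from [voxelize()] or equivalent).
#' @param template an `lv_mesh` used as deformable template.
#' @param lambda Laplacian smoothing weight in \[0, 1) (default 0.3).
#' @param tol convergence threshold on mean nodal displacement (mm).
#' @param max_iter maximum number of projection/smoothing iterations.
#' @param init `"auto"` (pose search) or `"none"` (template already posed).
#' @return list with `mesh` (fitted `lv_mesh`, template topology) and
#'   `report` (a `FitReport`: mean/sd/max surface-to-contour error in mm,
#'   `n_iterations`, `converged`).
#' @export
fit_template <- function(mask, template, lambda = 0.3, tol = 0.05,
                         max_iter = 100, init = c("auto", "none")) {
  stopifnot(inherits(template, "lv_mesh"))
  init <- match.arg(init)
  if (!any(mask > 0)) stop("segmentation-topology error: empty mask")
  contours <- mask_contours(mask)
  b_endo <- contour_points(contours, "endo")
  b_epi <- contour_points(contours, "epi")
  if (is.null(b_epi) || nrow(b_epi) < 24L)
    stop("segmentation-topology error: no epicardial boundary recovered")
  if (is.null(b_endo) || nrow(b_endo) < 24L)
    stop("segmentation-topology error: mask has no cavity (hollow-less)")

  mesh <- template
  if (init == "auto") mesh <- init_pose(mesh, rbind(b_endo, b_epi))

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    n_endo <- grid_normals(mesh, "endo")
    n_epi <- grid_normals(mesh, "epi")
    # normal-projection displacement field, Laplacian-smoothed over the grid
    # (smoothing the update rather than the positions: no tangential drift
    # or shrinkage, so the iteration is a contraction toward the boundary)
    d_endo <- laplacian_smooth(project_step(mesh$endo, n_endo, b_endo) -
                               mesh$endo, mesh, lambda)
    d_epi <- laplacian_smooth(project_step(mesh$epi, n_epi, b_epi) -
                              mesh$epi, mesh, lambda)
    mesh$endo <- mesh$endo + d_endo
    mesh$epi <- mesh$epi + d_epi
    disp <- mean(sqrt(rowSums(d_endo^2)) + sqrt(rowSums(d_epi^2))) / 2
    if (disp < tol) { converged <- TRUE; break }
  }
  report <- fitting_error(mesh, contours)
  report$n_iterations <- it
  report$converged <- converged
  if (!converged) warning("fit_template did not converge in ", max_iter, " iterations")
  list(mesh = mesh, report = report)
}

# move each node along its unit normal by the normal component of the offset
# to its nearest boundary point
project_step <- function(pts, normals, boundary) {
  nn <- max.col(-pdist2(pts, boundary), ties.method = "first")
  off <- boundary[nn, , drop = FALSE] - pts
  d <- rowSums(off * normals)
  pts + d * normals
}

laplacian_smooth <- function(pts, mesh, lambda) {
  if (lambda <= 0) return(pts)
  nc <- mesh$n_circ; nl <- mesh$n_long
  arr <- array(pts, dim = c(nc, nl, 3))
  jp <- c(2:nc, 1); jm <- c(nc, 1:(nc - 1))
  ip <- pmin(seq_len(nl) + 1L, nl); im <- pmax(seq_len(nl) - 1L, 1L)
  avg <- (arr[jp, , , drop = FALSE] + arr[jm, , , drop = FALSE] +
          arr[, ip, , drop = FALSE] + arr[, im, , drop = FALSE]) / 4
  out <- (1 - lambda) * arr + lambda * avg
  matrix(out, ncol = 3)
}

# rigid + isotropic scale initialization: align centroid, long axis and RMS
# size, then pick the long-axis sign and in-plane rotation minimizing the
# mean nearest-boundary distance of a subsampled node cloud
init_pose <- function(mesh, boundary) {
  tpl <- rbind(mesh$endo, mesh$epi)
  cb <- colMeans(boundary); ct <- colMeans(tpl)
  B0 <- sweep(boundary, 2, cb)
  T0 <- sweep(tpl, 2, ct)
  ax_b <- principal_axis(B0)
  ax_t <- principal_axis(T0)
  scale <- sqrt(mean(rowSums(B0^2)) / mean(rowSums(T0^2)))

  sub_t <- T0[seq(1, nrow(T0), length.out = min(300, nrow(T0))), , drop = FALSE]
  sub_b <- B0[seq(1, nrow(B0), length.out = min(600, nrow(B0))), , drop = FALSE]
  best <- NULL; best_cost <- Inf
  for (sgn in c(1, -1)) {
    R0 <- rotation_between(ax_t, sgn * ax_b)
    for (phi in 2 * pi * (0:15) / 16) {
      R <- axis_rotation(sgn * ax_b, phi) %*% R0
      cand <- scale * sub_t %*% t(R)
      cost <- mean(sqrt(do.call(pmin, as.data.frame(pdist2(cand, sub_b)))))
      if (cost < best_cost) { best_cost <- cost; best <- R }
    }
  }
  transform <- function(p) sweep(scale * sweep(p, 2, ct) %*% t(best), 2, cb, "+")
  mesh$endo <- transform(mesh$endo)
  mesh$epi <- transform(mesh$epi)
  mesh
}

principal_axis <- function(x) {
  v <- eigen(crossprod(x) / nrow(x), symmetric = TRUE)$vectors[, 1]
  v / sqrt(sum(v^2))
}

# rotation taking unit vector a onto unit vector b (Rodrigues)
rotation_between <- function(a, b) {
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  cth <- sum(a * b)
  if (cth < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- perp - sum(perp * a) * a
    return(axis_rotation(v / sqrt(sum(v^2)), pi))
  }
  vx <- skew(v)
  diag(3) + vx + vx %*% vx / (1 + cth)
}

axis_rotation <- function(axis, phi) {
  axis <- axis / sqrt(sum(axis^2))
  vx <- skew(axis)
  diag(3) + sin(phi) * vx + (1 - cos(phi)) * vx %*% vx
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Surface-to-contour fitting accuracy
#'
#' Distance from every contour point to the matching triangulated mesh
#' surface (endocardial contours against the endocardial surface, epicardial
#' against epicardial).
#'
#' @param mesh an `lv_mesh`.
#' @param contours an `lv_contour_stack`.
#' @return a `FitReport` list: `mean_error_mm`, `sd_error_mm`,
#'   `max_error_mm`, `n_points`.
#' @export
fitting_error <- function(mesh, contours) {
  stopifnot(inherits(mesh, "lv_mesh"))
  b_endo <- contour_points(contours, "endo")
  b_epi <- contour_points(contours, "epi")
  if (is.null(b_endo) && is.null(b_epi)) stop("empty contour stack")
  tris <- mesh_triangles(mesh)
  d <- c(if (!is.null(b_endo)) point_surface_distance(b_endo, mesh$endo, tris),
         if (!is.null(b_epi)) point_surface_distance(b_epi, mesh$epi, tris))
  list(mean_error_mm = mean(d), sd_error_mm = stats::sd(d),
       max_error_mm = max(d), n_points = length(d))
}
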