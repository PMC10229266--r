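# Pose normalization of corresponded meshes.
#
# Generalized Procrustes with translation and rotation only: size is left in
# the data deliberately, because the leading anatomical mode is expected to
# capture LV size and length.

# optimal rotation R minimizing ||X R - Y||_F (Kabsch)
kabsch_rotation <- function(X, Y) {
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

mesh_points <- function(mesh) rbind(mesh$endo, mesh$epi)

points_to_vector <- function(pts, topology) {
  m <- nrow(pts) / 2
  v <- c(as.vector(t(pts[seq_len(m), , drop = FALSE])),
         as.vector(t(pts[m + seq_len(m), , drop = FALSE])))
  attr(v, "topology") <- topology
  v
}

vector_to_points <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Generalized Procrustes alignment of corresponded meshes
#'
#' Iterates rigid (translation + rotation, no scaling) alignment of every
#' mesh onto the current consensus and consensus re-estimation until the
#' consensus changes by less than `tol` (mean nodal displacement, mm).
#'
#' @param meshes list of `lv_mesh` objects sharing one `topology_id`.
#' @param tol convergence tolerance on the consensus (mm).
#' @param max_iter maximum Procrustes iterations.
#' @return list of shape vectors (see [as_shape_vector()]), with the
#'   consensus shape attached as attribute `consensus`.
#' @export
align_meshes <- function(meshes, tol = 1e-6, max_iter = 100) {
  stopifnot(length(meshes) >= 1)
  ids <- vapply(meshes, `[[`, "", "topology_id")
  if (length(unique(ids)) != 1L)
    stop("topology mismatch: all meshes must share one topology_id")
  topology <- mesh_topology(meshes[[1]])

  pts <- lapply(meshes, function(m) {
    p <- mesh_points(m)
    sweep(p, 2, colMeans(p))
  })
  consensus <- pts[[1]]
  for (it in seq_len(max_iter)) {
    pts <- lapply(pts, function(p) p %*% kabsch_rotation(p, consensus))
    new_consensus <- Reduce(`+`, pts) / length(pts)
    delta <- mean(sqrt(rowSums((new_consensus - consensus)^2)))
    consensus <- new_consensus
    if (delta < tol) break
  }
  out <- lapply(pts, points_to_vector, topology = topology)
  attr(out, "consensus") <- points_to_vector(consensus, topology)
  out
}

#' Rigidly align one mesh onto a reference shape vector
#'
#' Used to bring external or held-out meshes into the frame of a trained
#' shape model before projection (translation + rotation, no scaling).
#'
#' @param mesh an `lv_mesh` with the reference's topology.
#' @param reference a shape vector (e.g. a model's mean shape).
#' @return an aligned shape vector.
#' @export
align_to_reference <- function(mesh, reference) {
  topology <- attr(reference, "topology")
  if (!is.null(topology) && !identical(topology$topology_id, mesh$topology_id))
    stop("topology mismatch between mesh and reference")
  ref <- vector_to_points(reference)
  ref <- sweep(ref, 2, colMeans(ref))
  p <- mesh_points(mesh)
  p <- sweep(p, 2, colMeans(p))
  p <- p %*% kabsch_rotation(p, ref)
  # restore the reference centroid so vectors live in the model frame
  p <- sweep(p, 2, colMeans(vector_to_points(reference)), "+")
  points_to_vector(p, if (is.null(topology)) mesh_topology(mesh) else topology)
}
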