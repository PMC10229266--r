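# Small numerical helpers shared across modules.

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @keywords internal
wrap_angle <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w <= -pi] <- pi
  w
}

#' Pairwise squared Euclidean distances
#'
#' @param a,b numeric matrices with points in rows (same number of columns).
#' @return `nrow(a)` x `nrow(b)` matrix of squared distances.
#' @keywords internal
pdist2 <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Distance from points to a triangulated surface
#'
#' Exact point-to-triangle distances: each query point is tested against the
#' triangles incident to its nearest surface vertices (a safe candidate set:
#' any triangle that could be closer has a vertex within the nearest-vertex
#' distance plus one triangle diameter).
#'
#' @param pts n x 3 matrix of query points.
#' @param verts m x 3 matrix of surface vertices.
#' @param tris t x 3 integer matrix of vertex indices (degenerate triangles
#'   are ignored).
#' @return numeric vector of n distances.
#' @keywords internal
point_surface_distance <- function(pts, verts, tris) {
  stopifnot(ncol(pts) == 3, ncol(verts) == 3, ncol(tris) == 3)
  # drop degenerate triangles (zero area), e.g. at the apex pole
  p1 <- verts[tris[, 1], , drop = FALSE]
  p2 <- verts[tris[, 2], , drop = FALSE]
  p3 <- verts[tris[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- rowSums(cr^2)
  keep <- area2 > 1e-20
  tris <- tris[keep, , drop = FALSE]
  if (nrow(tris) == 0L) stop("surface has no non-degenerate triangles")

  # triangles incident to each vertex
  tri_of_vert <- split(rep(seq_len(nrow(tris)), 3L), as.vector(tris))
  max_edge <- sqrt(max(rowSums((verts[tris[, 1], ] - verts[tris[, 2], ])^2),
                       rowSums((verts[tris[, 2], ] - verts[tris[, 3], ])^2),
                       rowSums((verts[tris[, 3], ] - verts[tris[, 1], ])^2)))

  dv2 <- pdist2(pts, verts)
  out <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    di <- sqrt(dv2[i, ])
    dmin <- min(di)
    cand_v <- which(di <= dmin + max_edge + 1e-12)
    cand_t <- unique(unlist(tri_of_vert[as.character(cand_v)], use.names = FALSE))
    out[i] <- min(point_triangle_dist(pts[i, ], verts, tris[cand_t, , drop = FALSE]))
  }
  out
}

# distance from one point to a set of triangles (vectorized over triangles):
# closest point is either the projection onto the plane (if its barycentric
# coordinates are all non-negative) or lies on one of the three edges.
point_triangle_dist <- function(p, verts, tris) {
  a <- verts[tris[, 1], , drop = FALSE]
  b <- verts[tris[, 2], , drop = FALSE]
  c <- verts[tris[, 3], , drop = FALSE]
  pm <- matrix(p, nrow(a), 3, byrow = TRUE)

  d_edge <- pmin(point_segment_dist(pm, a, b),
                 point_segment_dist(pm, b, c),
                 point_segment_dist(pm, c, a))

  ab <- b - a; ac <- c - a; ap <- pm - a
  d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
  d20 <- rowSums(ap * ab); d21 <- rowSums(ap * ac)
  den <- d00 * d11 - d01 * d01
  inside <- den > 1e-20
  v <- ifelse(inside, (d11 * d20 - d01 * d21) / den, -1)
  w <- ifelse(inside, (d00 * d21 - d01 * d20) / den, -1)
  interior <- inside & v >= 0 & w >= 0 & (v + w) <= 1
  cl <- a + ab * v + ac * w
  d_int <- sqrt(rowSums((pm - cl)^2))
  ifelse(interior, pmin(d_int, d_edge), d_edge)
}

# rowwise distance from points pm to segments [a, b]
point_segment_dist <- function(pm, a, b) {
  ab <- b - a
  t <- rowSums((pm - a) * ab) / pmax(rowSums(ab * ab), 1e-20)
  t <- pmin(pmax(t, 0), 1)
  cl <- a + ab * t
  sqrt(rowSums((pm - cl)^2))
}

#' Cast rays against a triangle soup (Moller-Trumbore)
#'
#' @param orig 3-vector ray origin.
#' @param dir 3-vector ray direction (need not be unit length).
#' @param verts,tris surface as in [point_surface_distance()].
#' @return smallest positive ray parameter t (distance if `dir` is unit),
#'   or `NA_real_` if the ray misses.
#' @keywords internal
ray_surface_hit <- function(orig, dir, verts, tris) {
  v0 <- verts[tris[, 1], , drop = FALSE]
  e1 <- verts[tris[, 2], , drop = FALSE] - v0
  e2 <- verts[tris[, 3], , drop = FALSE] - v0
  d <- matrix(dir, nrow(v0), 3, byrow = TRUE)
  pvec <- cbind(d[, 2] * e2[, 3] - d[, 3] * e2[, 2],
                d[, 3] * e2[, 1] - d[, 1] * e2[, 3],
                d[, 1] * e2[, 2] - d[, 2] * e2[, 1])
  det <- rowSums(e1 * pvec)
  ok <- abs(det) > 1e-12
  tvec <- matrix(orig, nrow(v0), 3, byrow = TRUE) - v0
  u <- rowSums(tvec * pvec) / det
  qvec <- cbind(tvec[, 2] * e1[, 3] - tvec[, 3] * e1[, 2],
                tvec[, 3] * e1[, 1] - tvec[, 1] * e1[, 3],
                tvec[, 1] * e1[, 2] - tvec[, 2] * e1[, 1])
  v <- rowSums(d * qvec) / det
  tt <- rowSums(e2 * qvec) / det
  eps <- 1e-9
  hit <- ok & u >= -eps & v >= -eps & (u + v) <= 1 + eps & tt > 1e-9
  if (!any(hit)) return(NA_real_)
  min(tt[hit])
}
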