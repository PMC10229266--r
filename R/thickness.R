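# Nodal wall thickness and AHA 17-segment aggregation.

# per-node outward normals of one surface grid, oriented from endo toward epi
grid_normals <- function(mesh, surface = c("endo", "epi")) {
  surface <- match.arg(surface)
  pts <- mesh[[surface]]
  nc <- mesh$n_circ; nl <- mesh$n_long
  arr <- array(pts, dim = c(nc, nl, 3))
  jp <- c(2:nc, 1); jm <- c(nc, 1:(nc - 1))
  t_th <- arr[jp, , , drop = FALSE] - arr[jm, , , drop = FALSE]
  ip <- pmin(seq_len(nl) + 1L, nl); im <- pmax(seq_len(nl) - 1L, 1L)
  t_u <- arr[, ip, , drop = FALSE] - arr[, im, , drop = FALSE]
  n1 <- t_th[, , 2] * t_u[, , 3] - t_th[, , 3] * t_u[, , 2]
  n2 <- t_th[, , 3] * t_u[, , 1] - t_th[, , 1] * t_u[, , 3]
  n3 <- t_th[, , 1] * t_u[, , 2] - t_th[, , 2] * t_u[, , 1]
  nrm <- cbind(as.vector(n1), as.vector(n2), as.vector(n3))
  len <- sqrt(rowSums(nrm^2))
  ref <- mesh$epi - mesh$endo
  reflen <- sqrt(rowSums(ref^2))
  bad <- len < 1e-9 * max(len)
  # degenerate rows (apex pole): fall back to the transmural direction
  nrm[bad, ] <- ref[bad, ] / pmax(reflen[bad], 1e-12)
  len[bad] <- 1
  nrm <- nrm / len
  flip <- rowSums(nrm * ref) < 0
  nrm[flip, ] <- -nrm[flip, ]
  nrm
}

#' Nodal wall thickness by normal ray casting
#'
#' Thickness at each grid node is the distance from the endocardial node to
#' the intersection of its outward normal ray with the epicardial surface;
#' the symmetric epi-to-endo measurement is averaged in when it is defined.
#' Rays are first tested against triangles near the node's grid location
#' (correspondence makes the intersection local), then against the full
#' surface before declaring a miss.
#'
#' @param mesh an `lv_mesh`.
#' @return numeric vector of per-node thickness (mm); `NA` where both rays
#'   miss, with the number of misses reported via attribute `n_missing`.
#' @export
wall_thickness <- function(mesh) {
  stopifnot(inherits(mesh, "lv_mesh"))
  tris <- mesh_triangles(mesh)
  n_endo <- grid_normals(mesh, "endo")
  n_epi <- grid_normals(mesh, "epi")
  m <- nrow(mesh$endo)
  t1 <- cast_all(mesh$endo, n_endo, mesh$epi, tris, mesh, +1)
  t2 <- cast_all(mesh$epi, -n_epi, mesh$endo, tris, mesh, -1)
  th <- ifelse(is.na(t1), t2, ifelse(is.na(t2), t1, (t1 + t2) / 2))
  structure(th, n_missing = sum(is.na(th)))
}

# cast one ray per node against a target surface, using a window of grid
# quads around the node first and the whole surface as fallback
cast_all <- function(orig, dirs, target, tris, mesh, sign_unused, window = 4L) {
  nc <- mesh$n_circ; nl <- mesh$n_long
  nq <- (nl - 1L) * nc
  out <- rep(NA_real_, nrow(orig))
  for (k in seq_len(nrow(orig))) {
    i <- (k - 1L) %/% nc + 1L
    j <- (k - 1L) %% nc + 1L
    ii <- max(1L, i - window):min(nl - 1L, i + window)
    jj <- ((j - 1L + (-window:window)) %% nc) + 1L
    q <- as.vector(outer(jj, (ii - 1L) * nc, "+"))
    cand <- tris[c(q, q + nq), , drop = FALSE]
    hit <- ray_surface_hit(orig[k, ], dirs[k, ], target, cand)
    if (is.na(hit))
      hit <- ray_surface_hit(orig[k, ], dirs[k, ], target, tris)
    out[k] <- hit
  }
  out
}

#' AHA 17-segment aggregation of nodal thickness
#'
#' Longitudinal thirds of u (base/mid/apical) are split into the standard
#' sectors: 6 x 60 degrees for basal (segments 1-6) and mid (7-12) levels,
#' 4 x 90 degrees for the apical level (13-16), with the apex-pole grid row
#' as segment 17.  The anteroseptal sector (segment 2) is centred on
#' theta = 0, matching the LVOT convention; the bull's eye is viewed from
#' the apex.  Segment values are means of the non-missing nodal thickness.
#'
#' @param mesh an `lv_mesh`.
#' @param thickness per-node thickness from [wall_thickness()] (computed if
#'   missing).
#' @return named numeric vector of 17 segment thicknesses (mm), class
#'   `aha17`.
#' @export
aha17_map <- function(mesh, thickness = NULL) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (is.null(thickness)) thickness <- wall_thickness(mesh)
  m <- nrow(mesh$endo)
  stopifnot(length(thickness) == m)
  if (mean(is.na(thickness)) > 0.10)
    stop("coverage error: thickness missing for more than 10% of nodes")

  nc <- mesh$n_circ; nl <- mesh$n_long
  U <- rep(mesh$u, each = nc)
  TH <- rep(mesh$theta, times = nl)
  apex_row <- rep(seq_len(nl), each = nc) == nl

  seg <- integer(m)
  deg <- TH * 180 / pi
  sector6 <- function(d) {
    # anteroseptal [-30,30) -> 2, anterior [30,90) -> 1, anterolateral -> 6,
    # inferolateral -> 5, inferior -> 4, inferoseptal [-90,-30) -> 3
    s <- integer(length(d))
    s[d >= -30 & d < 30] <- 2L
    s[d >= 30 & d < 90] <- 1L
    s[d >= 90 & d < 150] <- 6L
    s[d >= 150 | d < -150] <- 5L
    s[d >= -150 & d < -90] <- 4L
    s[d >= -90 & d < -30] <- 3L
    s
  }
  sector4 <- function(d) {
    # septal [-45,45) -> 14, anterior [45,135) -> 13, lateral -> 16,
    # inferior [-135,-45) -> 15
    s <- integer(length(d))
    s[d >= -45 & d < 45] <- 14L
    s[d >= 45 & d < 135] <- 13L
    s[d >= 135 | d < -135] <- 16L
    s[d >= -45 - 90 & d < -45] <- 15L
    s
  }
  basal <- !apex_row & U < 1 / 3
  mid <- !apex_row & U >= 1 / 3 & U < 2 / 3
  apical <- !apex_row & U >= 2 / 3
  seg[basal] <- sector6(deg[basal])
  seg[mid] <- sector6(deg[mid]) + 6L
  seg[apical] <- sector4(deg[apical])
  seg[apex_row] <- 17L

  vals <- vapply(1:17, function(s) {
    v <- thickness[seg == s]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  names(vals) <- c("basal_anterior", "basal_anteroseptal", "basal_inferoseptal",
                   "basal_inferior", "basal_inferolateral", "basal_anterolateral",
                   "mid_anterior", "mid_anteroseptal", "mid_inferoseptal",
                   "mid_inferior", "mid_inferolateral", "mid_anterolateral",
                   "apical_anterior", "apical_septal", "apical_inferior",
                   "apical_lateral", "apex")
  structure(vals, class = "aha17")
}

#' @export
print.aha17 <- function(x, ...) {
  cat("AHA 17-segment wall thickness (mm):\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' Effective LVOT sector area
#'
#' Mean endocardial cross-sectional sector area of the basal anteroseptal
#' outflow sector (u < 1/3, theta in \[-30, +30\] degrees), the testable
#' surrogate for outflow-tract calibre: inward remodelling of the basal
#' anteroseptal wall shrinks it.
#'
#' @param mesh an `lv_mesh`.
#' @return sector area in mm^2.
#' @export
lvot_sector_area <- function(mesh) {
  stopifnot(inherits(mesh, "lv_mesh"))
  nc <- mesh$n_circ
  rows <- which(mesh$u < 1 / 3)
  cols <- which(abs(wrap_angle(mesh$theta)) <= pi / 6 + 1e-12)
  dth <- 2 * pi / nc
  area_row <- vapply(rows, function(i) {
    idx <- (i - 1L) * nc + cols
    r2 <- mesh$endo[idx, 1]^2 + mesh$endo[idx, 2]^2
    sum(0.5 * r2 * dth)
  }, numeric(1))
  mean(area_row)
}
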