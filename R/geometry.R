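# Parametric left-ventricular geometry.
#
# Anatomical frame (shared by every module): the LV long axis is z, the base
# plane is z = 0 and the apex points toward negative z; u in [0, 1] is the
# longitudinal fraction from base to apex; theta is the circumferential angle,
# counter-clockwise when viewed from the apex, with theta = 0 at the centre of
# the anteroseptal outflow-tract (LVOT) sector.  The septum occupies a fixed
# 120 degree sector around theta = 0.

#' Generative parameters of a synthetic left ventricle
#'
#' Encodes the remodelling features relevant to outflow-tract obstruction in
#' hypertrophic cardiomyopathy: basal septal hypertrophy (a Gaussian thickness
#' bump, optionally spiralling with depth), apical dilatation, LV lengthening
#' and inward remodelling of the basal anteroseptal LVOT sector.
#'
#' @param length_mm base-to-apex cavity length L (mm).
#' @param endo_base_radius_mm endocardial radius at the base (mm).
#' @param base_thickness_mm baseline wall thickness t0 (mm).
#' @param septal_bump_amp_mm peak added septal thickness (mm); the maximal
#'   nodal wall thickness is `base_thickness_mm + septal_bump_amp_mm`.
#' @param septal_bump_center numeric length 2: circumferential centre
#'   theta_s (radians) and longitudinal centre u_s (fraction in \[0, 1\]).
#' @param septal_bump_width numeric length 2: Gaussian widths (sigma_theta in
#'   radians, sigma_u as a fraction); also used for the LVOT inward bump.
#' @param spiral_drift_rad circumferential drift of the bump centre per unit
#'   u (radians); 0 means no spiral pattern.
#' @param apical_dilation fractional endocardial radius increase at the apex
#'   (>= 0).
#' @param lvot_inward_mm peak inward radial displacement of both surfaces in
#'   the basal anteroseptal sector (mm, >= 0).
#' @param sphericity_exp exponent shaping the long-axis radius profile
#'   (2 = semi-ellipsoid).
#' @return an object of class `lv_geometry_params`.
#' @export
#' @examples
#' p <- lv_geometry_params(septal_bump_amp_mm = 9)
#' mesh <- generate_lv_surface(p, n_circ = 32, n_long = 16)
lv_geometry_params <- function(length_mm = 80,
                               endo_base_radius_mm = 25,
                               base_thickness_mm = 8,
                               septal_bump_amp_mm = 4,
                               septal_bump_center = c(0, 0.18),
                               septal_bump_width = c(0.7, 0.18),
                               spiral_drift_rad = 0,
                               apical_dilation = 0.05,
                               lvot_inward_mm = 1,
                               sphericity_exp = 2) {
  p <- list(length_mm = length_mm,
            endo_base_radius_mm = endo_base_radius_mm,
            base_thickness_mm = base_thickness_mm,
            septal_bump_amp_mm = septal_bump_amp_mm,
            septal_bump_center = as.numeric(septal_bump_center),
            septal_bump_width = as.numeric(septal_bump_width),
            spiral_drift_rad = spiral_drift_rad,
            apical_dilation = apical_dilation,
            lvot_inward_mm = lvot_inward_mm,
            sphericity_exp = sphericity_exp)
  validate_lv_geometry_params(p)
  structure(p, class = "lv_geometry_params")
}

validate_lv_geometry_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(p$length_mm) || p$length_mm <= 0) stop("length_mm must be > 0")
  if (!num1(p$endo_base_radius_mm) || p$endo_base_radius_mm <= 0)
    stop("endo_base_radius_mm must be > 0")
  if (!num1(p$base_thickness_mm) || p$base_thickness_mm <= 0)
    stop("base_thickness_mm must be > 0")
  if (length(p$septal_bump_center) != 2L || length(p$septal_bump_width) != 2L)
    stop("septal_bump_center and septal_bump_width must have length 2")
  if (any(p$septal_bump_width <= 0)) stop("bump widths must be > 0")
  if (!num1(p$apical_dilation) || p$apical_dilation < 0)
    stop("apical_dilation must be >= 0")
  if (!num1(p$lvot_inward_mm) || p$lvot_inward_mm < 0)
    stop("lvot_inward_mm must be >= 0")
  if (!num1(p$sphericity_exp) || p$sphericity_exp <= 0)
    stop("sphericity_exp must be > 0")
  invisible(p)
}

#' Generate a corresponded endo/epi LV surface mesh
#'
#' Builds the endocardium as a surface of revolution
#' `r(u) = Re * (1 - u^s)^(1/2) * (1 + d_ap * u^2)` with `z = -u * L`, offsets
#' the epicardium outward along the meridian normal by the thickness field
#' `t(theta, u) = t0 + A_sept * exp(-dtheta^2 / (2 sigma_theta^2)
#'  - (u - u_s)^2 / (2 sigma_u^2))` (bump centre drifting by
#' `spiral_drift_rad * u`), then displaces both surfaces radially inward by
#' an LVOT remodelling bump centred on the anteroseptal sector (theta = 0,
#' u = 0).  The (theta, u) node grid is identical for every parameter value,
#' so meshes are corresponded by construction.
#'
#' @param params an [lv_geometry_params()] object.
#' @param n_circ number of circumferential nodes (>= 16).
#' @param n_long number of longitudinal rows (>= 8), base row first, apex
#'   row last (the apex row is a degenerate ring at the apex point).
#' @return an object of class `lv_mesh`: matrices `endo` and `epi`
#'   (`n_circ * n_long` rows x 3, ordered row-of-constant-u-major), `theta`,
#'   `u`, `n_circ`, `n_long` and a `topology_id` string.
#' @export
generate_lv_surface <- function(params, n_circ = 64, n_long = 32) {
  stopifnot(inherits(params, "lv_geometry_params") || is.list(params))
  validate_lv_geometry_params(params)
  if (n_circ < 16) stop("n_circ must be >= 16")
  if (n_long < 8) stop("n_long must be >= 8")

  p <- params
  u <- seq(0, 1, length.out = n_long)
  theta <- wrap_angle(2 * pi * (seq_len(n_circ) - 1L) / n_circ)

  s <- p$sphericity_exp
  r_u <- p$endo_base_radius_mm * sqrt(pmax(1 - u^s, 0)) * (1 + p$apical_dilation * u^2)
  z_u <- -u * p$length_mm

  # outward meridian normal from central differences of (r(u), z(u))
  dr <- numeric(n_long); dz <- numeric(n_long)
  dr[1] <- r_u[2] - r_u[1];          dz[1] <- z_u[2] - z_u[1]
  n <- n_long
  dr[n] <- r_u[n] - r_u[n - 1];      dz[n] <- z_u[n] - z_u[n - 1]
  dr[2:(n - 1)] <- r_u[3:n] - r_u[1:(n - 2)]
  dz[2:(n - 1)] <- z_u[3:n] - z_u[1:(n - 2)]
  nr <- -dz; nz <- dr
  nlen <- sqrt(nr^2 + nz^2)
  nr <- nr / nlen; nz <- nz / nlen
  # apex pole: the outward direction is purely axial
  nr[n] <- 0; nz[n] <- -1

  # full grids (u-row major: index k = (i_u - 1) * n_circ + j_theta)
  U <- rep(u, each = n_circ)
  TH <- rep(theta, times = n_long)
  R <- rep(r_u, each = n_circ)
  Z <- rep(z_u, each = n_circ)
  NR <- rep(nr, each = n_circ)
  NZ <- rep(nz, each = n_circ)

  sig_t <- p$septal_bump_width[1]
  sig_u <- p$septal_bump_width[2]
  dth_sept <- wrap_angle(TH - (p$septal_bump_center[1] + p$spiral_drift_rad * U))
  thick <- p$base_thickness_mm + p$septal_bump_amp_mm *
    exp(-dth_sept^2 / (2 * sig_t^2) - (U - p$septal_bump_center[2])^2 / (2 * sig_u^2))
  if (any(thick <= 0))
    stop("invalid geometry: non-positive wall thickness (septal bump amplitude < -t0)")

  endo <- cbind(R * cos(TH), R * sin(TH), Z)
  epi <- endo + thick * cbind(NR * cos(TH), NR * sin(TH), NZ)

  # inward LVOT remodelling of both surfaces (radial displacement)
  w <- p$lvot_inward_mm *
    exp(-wrap_angle(TH)^2 / (2 * sig_t^2) - U^2 / (2 * sig_u^2))
  endo <- radial_inward(endo, w)
  epi <- radial_inward(epi, w)

  mesh <- structure(list(endo = endo, epi = epi, theta = theta, u = u,
                         n_circ = as.integer(n_circ), n_long = as.integer(n_long),
                         topology_id = sprintf("lvgrid-%dx%d-v1", n_circ, n_long)),
                    class = "lv_mesh")
  th_chk <- sqrt(rowSums((mesh$epi - mesh$endo)^2))
  if (any(th_chk <= 0) || any(endo_radius(mesh) < 0))
    stop("invalid geometry: epicardium does not lie strictly outside endocardium")
  mesh
}

radial_inward <- function(pts, w) {
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  scl <- ifelse(r > 1e-9, pmax(r - w, 0) / r, 1)
  cbind(pts[, 1] * scl, pts[, 2] * scl, pts[, 3])
}

endo_radius <- function(mesh) sqrt(mesh$endo[, 1]^2 + mesh$endo[, 2]^2)

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV surface mesh (%s): %d x %d nodes per surface\n",
              x$topology_id, x$n_circ, x$n_long))
  cat(sprintf("  z extent: [%.1f, %.1f] mm; base radius %.1f mm\n",
              min(x$endo[, 3], x$epi[, 3]), max(x$endo[, 3], x$epi[, 3]),
              max(endo_radius(x))))
  invisible(x)
}

#' Nodal construction thickness (distance between paired endo/epi nodes)
#' @param mesh an `lv_mesh`.
#' @return numeric vector, one value per grid node.
#' @keywords internal
nodal_offset <- function(mesh) sqrt(rowSums((mesh$epi - mesh$endo)^2))

#' Flatten a mesh to a shape vector
#'
#' Coordinates are concatenated as (x, y, z) per node, endocardium first,
#' in the fixed grid ordering shared by all meshes of one topology.
#'
#' @param mesh an `lv_mesh`.
#' @return numeric vector of length `3 * 2 * n_circ * n_long` with
#'   attribute `topology` carrying grid metadata.
#' @export
as_shape_vector <- function(mesh) {
  v <- c(as.vector(t(mesh$endo)), as.vector(t(mesh$epi)))
  attr(v, "topology") <- mesh_topology(mesh)
  v
}

mesh_topology <- function(mesh) {
  list(topology_id = mesh$topology_id, theta = mesh$theta, u = mesh$u,
       n_circ = mesh$n_circ, n_long = mesh$n_long)
}

#' Rebuild an `lv_mesh` from a shape vector
#' @param v numeric shape vector (see [as_shape_vector()]).
#' @param topology topology metadata (from `attr(v, "topology")` or another
#'   mesh's topology); used to restore the grid.
#' @return an `lv_mesh`.
#' @export
mesh_from_vector <- function(v, topology = attr(v, "topology")) {
  if (is.null(topology)) stop("topology metadata required to refold a mesh")
  m <- topology$n_circ * topology$n_long
  if (length(v) != 6L * m) stop("shape vector length does not match topology")
  endo <- matrix(v[seq_len(3L * m)], ncol = 3, byrow = TRUE)
  epi <- matrix(v[3L * m + seq_len(3L * m)], ncol = 3, byrow = TRUE)
  structure(list(endo = endo, epi = epi, theta = topology$theta,
                 u = topology$u, n_circ = topology$n_circ,
                 n_long = topology$n_long, topology_id = topology$topology_id),
            class = "lv_mesh")
}

#' Grid triangulation of one surface
#' @param mesh an `lv_mesh`.
#' @return integer matrix (t x 3) of node indices into the per-surface grid.
#' @keywords internal
mesh_triangles <- function(mesh) {
  nc <- mesh$n_circ; nl <- mesh$n_long
  i <- rep(seq_len(nl - 1L), each = nc)       # u row
  j <- rep(seq_len(nc), times = nl - 1L)      # theta column
  jn <- ifelse(j == nc, 1L, j + 1L)
  a <- (i - 1L) * nc + j
  b <- (i - 1L) * nc + jn
  cc <- i * nc + j
  d <- i * nc + jn
  rbind(cbind(a, b, cc), cbind(b, d, cc))
}

# signed volume of a closed surface = grid surface + base-ring cap fan
closed_surface_volume <- function(pts, mesh) {
  tris <- mesh_triangles(mesh)
  nc <- mesh$n_circ
  ring <- pts[seq_len(nc), , drop = FALSE]
  centroid <- colMeans(ring)
  m <- nrow(pts)
  pts2 <- rbind(pts, centroid)
  j <- seq_len(nc); jn <- ifelse(j == nc, 1L, j + 1L)
  cap <- cbind(rep(m + 1L, nc), jn, j)
  tris <- rbind(tris, cap)
  p1 <- pts2[tris[, 1], ]; p2 <- pts2[tris[, 2], ]; p3 <- pts2[tris[, 3], ]
  v6 <- sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
            p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
            p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1]))
  abs(v6) / 6
}

#' Enclosed volumes of an LV mesh
#'
#' Cavity volume (endocardial surface closed with a planar base cap),
#' epicardial volume, and their difference, the myocardial shell volume.
#' Computed by the divergence theorem on the grid triangulation.
#'
#' @param mesh an `lv_mesh`.
#' @return list with `cavity_ml`, `epi_ml`, `shell_ml` (millilitres).
#' @export
mesh_volumes <- function(mesh) {
  v_endo <- closed_surface_volume(mesh$endo, mesh)
  v_epi <- closed_surface_volume(mesh$epi, mesh)
  list(cavity_ml = v_endo / 1000,
       epi_ml = v_epi / 1000,
       shell_ml = (v_epi - v_endo) / 1000)
}
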