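# Short-axis voxelization of an LV mesh and contour extraction.
#
# The slice stack mimics short-axis cine CMR: ~8 mm thick slices at 2-2.5 mm
# in-plane resolution, ordered base -> apex.  The binary mask marks voxels
# whose centres lie between the endocardial and epicardial surfaces; contours
# are then recovered from the mask boundaries (marching squares), which is the
# delineation workflow run in reverse to fabricate segmentation inputs.

#' Voxelize an LV mesh into a short-axis binary mask and contour stack
#'
#' @param mesh an `lv_mesh`.
#' @param in_plane_mm in-plane voxel size (0 < x <= 5); default 2 mm.
#' @param slice_mm slice thickness (0 < x <= 12); default 8 mm.
#' @return list with `mask` (an `lv_mask`: 3D 0/1 array, slices in the third
#'   dimension ordered base->apex, with `spacing`, `origin` and `z_centers`
#'   attributes) and `contours` (an `lv_contour_stack`, see
#'   [mask_contours()]).  The slab spans the full myocardial z-extent, so the
#'   number of slices is `ceiling(extent / slice_mm)`.
#' @export
voxelize <- function(mesh, in_plane_mm = 2, slice_mm = 8) {
  stopifnot(inherits(mesh, "lv_mesh"))
  if (!(in_plane_mm > 0 && in_plane_mm <= 5)) stop("in_plane_mm must be in (0, 5]")
  if (!(slice_mm > 0 && slice_mm <= 12)) stop("slice_mm must be in (0, 12]")

  allz <- c(mesh$endo[, 3], mesh$epi[, 3])
  zmax <- max(allz); zmin <- min(allz)
  n_slices <- as.integer(ceiling((zmax - zmin) / slice_mm - 1e-9))
  z_centers <- zmax - (seq_len(n_slices) - 0.5) * slice_mm

  allx <- c(mesh$endo[, 1], mesh$epi[, 1])
  ally <- c(mesh$endo[, 2], mesh$epi[, 2])
  x0 <- min(allx) - 1.5 * in_plane_mm
  y0 <- min(ally) - 1.5 * in_plane_mm
  nx <- as.integer(ceiling((max(allx) - x0) / in_plane_mm)) + 2L
  ny <- as.integer(ceiling((max(ally) - y0) / in_plane_mm)) + 2L
  xc <- x0 + (seq_len(nx) - 0.5) * in_plane_mm
  yc <- y0 + (seq_len(ny) - 0.5) * in_plane_mm
  grid <- cbind(rep(xc, times = ny), rep(yc, each = nx))

  mask <- array(0L, dim = c(nx, ny, n_slices))
  for (k in seq_len(n_slices)) {
    epi_poly <- slice_polygon(mesh, "epi", z_centers[k])
    if (is.null(epi_poly)) next
    inside <- in_polygon(epi_poly, grid)
    endo_poly <- slice_polygon(mesh, "endo", z_centers[k])
    if (!is.null(endo_poly)) inside <- inside & !in_polygon(endo_poly, grid)
    mask[, , k] <- matrix(as.integer(inside), nx, ny)
  }

  mask <- structure(mask, spacing = c(in_plane_mm, in_plane_mm, slice_mm),
                    origin = c(x0, y0), z_centers = z_centers,
                    class = "lv_mask")
  list(mask = mask, contours = mask_contours(mask))
}

# closed polygon of one surface cut by the plane z = z0 (NULL when the plane
# misses the surface); columns of the (theta, u) grid are interpolated in u.
slice_polygon <- function(mesh, surface = c("endo", "epi"), z0) {
  surface <- match.arg(surface)
  pts <- mesh[[surface]]
  nc <- mesh$n_circ; nl <- mesh$n_long
  X <- matrix(pts[, 1], nrow = nc)  # nc x nl, column = u row
  Y <- matrix(pts[, 2], nrow = nc)
  Z <- matrix(pts[, 3], nrow = nc)
  # per theta column, number of u-levels above the plane (z decreasing)
  i_above <- rowSums(Z > z0)
  if (any(i_above == 0L) || any(i_above == nl)) return(NULL)
  idx <- cbind(seq_len(nc), i_above)
  idx2 <- cbind(seq_len(nc), i_above + 1L)
  za <- Z[idx]; zb <- Z[idx2]
  f <- (za - z0) / pmax(za - zb, 1e-12)
  cbind(X[idx] + f * (X[idx2] - X[idx]),
        Y[idx] + f * (Y[idx2] - Y[idx]))
}

in_polygon <- function(poly, pts) {
  bnd <- rbind(poly, poly[1, ])
  mgcv::in.out(bnd, pts)
}

#' Extract per-slice endo/epi contours from a binary mask
#'
#' Marching-squares contours at level 0.5 on each slice; when a slice holds
#' two nested loops the outer one is the epicardium and the inner the
#' endocardium, a single loop (solid apical sections) is epicardium only.
#'
#' @param mask an `lv_mask` (0/1 array with `spacing`/`origin`/`z_centers`
#'   attributes).
#' @return an `lv_contour_stack`: a list with one element per slice, each a
#'   list with `z` (slice centre, mm), `endo` and `epi` (closed polylines as
#'   n x 2 matrices in mm, or NULL).  Empty slices keep NULL contours.
#' @export
mask_contours <- function(mask) {
  sp <- attr(mask, "spacing"); or <- attr(mask, "origin")
  zc <- attr(mask, "z_centers")
  nx <- dim(mask)[1]; ny <- dim(mask)[2]
  xc <- or[1] + (seq_len(nx) - 0.5) * sp[1]
  yc <- or[2] + (seq_len(ny) - 0.5) * sp[2]
  out <- vector("list", dim(mask)[3])
  nonempty <- which(apply(mask > 0, 3, any))
  for (k in seq_along(out)) {
    sl <- mask[, , k]
    if (!any(sl > 0)) {
      out[[k]] <- list(z = zc[k], endo = NULL, epi = NULL)
      next
    }
    cl <- grDevices::contourLines(xc, yc, sl, levels = 0.5)
    loops <- lapply(cl, function(l) cbind(l$x, l$y))
    # degenerate loops (<8 points) are only legitimate at the apex cap
    loops <- loops[vapply(loops, nrow, 0L) >= 8L]
    if (length(loops) == 0L) {
      if (k != max(nonempty))
        stop("resolution error: degenerate contour (<8 points) in slice ", k,
             "; voxel spacing too coarse for this ventricle")
      out[[k]] <- list(z = zc[k], endo = NULL, epi = NULL)
      next
    }
    areas <- vapply(loops, polygon_area, numeric(1))
    ord <- order(areas, decreasing = TRUE)
    epi <- loops[[ord[1]]]
    endo <- if (length(loops) >= 2L) loops[[ord[2]]] else NULL
    if (k == min(nonempty) && is.null(endo))
      stop("resolution error: basal cavity contour degenerate or missing; ",
           "voxel spacing too coarse for this ventricle")
    out[[k]] <- list(z = zc[k], endo = endo, epi = epi)
  }
  structure(out, spacing = sp, class = "lv_contour_stack")
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Myocardial volume implied by a binary mask
#' @param mask an `lv_mask`.
#' @return volume in ml (voxel count x voxel volume).
#' @export
mask_volume <- function(mask) {
  sp <- attr(mask, "spacing")
  sum(mask) * prod(sp) / 1000
}

# contour stack points pooled as 3D coordinates, per surface
contour_points <- function(contours, surface = c("endo", "epi")) {
  surface <- match.arg(surface)
  do.call(rbind, lapply(contours, function(sl) {
    p <- sl[[surface]]
    if (is.null(p)) NULL else cbind(p, sl$z)
  }))
}

#' Write a contour stack to the documented JSON schema
#'
#' One object per slice: `{"z": <mm>, "endo": [[x,y],...] | null,
#' "epi": [[x,y],...] | null}`, plus top-level voxel spacing.
#'
#' @param contours an `lv_contour_stack`.
#' @param path output file.
#' @export
write_contours_json <- function(contours, path) {
  slices <- lapply(contours, function(sl)
    list(z = sl$z,
         endo = if (is.null(sl$endo)) NULL else unname(sl$endo),
         epi = if (is.null(sl$epi)) NULL else unname(sl$epi)))
  jsonlite::write_json(list(spacing_mm = attr(contours, "spacing"),
                            slices = slices),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
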