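# Plain-text persistence: ASCII VTK meshes, JSON models, CSV tables.

#' Write an LV mesh as legacy ASCII VTK PolyData
#'
#' Both surfaces go into one file (endocardial points first), triangulated
#' with the grid topology; optional per-node scalars (e.g. wall thickness)
#' are written as POINT_DATA.
#'
#' @param mesh an `lv_mesh`.
#' @param path output file (conventionally `.vtk`).
#' @param point_data optional named list of per-node numeric vectors, each
#'   of length `n_circ * n_long` (replicated onto both surfaces) or twice
#'   that.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = NULL) {
  stopifnot(inherits(mesh, "lv_mesh"))
  pts <- rbind(mesh$endo, mesh$epi)
  m <- nrow(mesh$endo)
  tris <- rbind(mesh_triangles(mesh), mesh_triangles(mesh) + m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("LV surface mesh %s", mesh$topology_id),
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(pts))), con)
  utils::write.table(format(pts, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tris), 4L * nrow(tris)), con)
  utils::write.table(cbind(3L, tris - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (length(v) == m) v <- c(v, v)
      stopifnot(length(v) == nrow(pts))
      v[!is.finite(v)] <- -1
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(format(v, scientific = FALSE), con)
    }
  }
  invisible(path)
}

#' Persist / restore a shape model as JSON
#'
#' Mean shape, modes, variances and metadata (topology, subject count) are
#' written at full precision.
#'
#' @param model an `lv_ssm`.
#' @param path JSON file path.
#' @export
write_ssm_json <- function(model, path) {
  stopifnot(inherits(model, "lv_ssm"))
  obj <- list(mean_shape = as.numeric(model$mean_shape),
              modes = model$modes,
              variances = model$variances,
              explained_ratio = model$explained_ratio,
              n_subjects = model$n_subjects,
              n_modes_selected = model$n_modes_selected,
              variance_threshold = model$variance_threshold,
              topology = model$topology)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ssm_json
#' @export
read_ssm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- obj$topology
  topo$n_circ <- as.integer(topo$n_circ); topo$n_long <- as.integer(topo$n_long)
  model <- list(mean_shape = structure(obj$mean_shape, topology = topo),
                modes = as.matrix(obj$modes),
                variances = obj$variances,
                explained_ratio = obj$explained_ratio,
                scores = NULL,
                n_subjects = obj$n_subjects,
                topology = topo,
                variance_threshold = obj$variance_threshold,
                n_modes_selected = obj$n_modes_selected)
  structure(model, class = "lv_ssm")
}

#' Persist / restore a discriminant axis as JSON
#' @param model an `lv_lda`.
#' @param path JSON file path.
#' @export
write_lda_json <- function(model, path) {
  stopifnot(inherits(model, "lv_lda"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "lv_lda")
}

#' Write all study outputs to a directory
#'
#' Cohort and Z-score tables as CSV, per-axis validation and the study
#' manifest (with MD5 hashes of every written file) as JSON, shape model
#' and axes as JSON, extreme meshes as VTK with thickness point data, and
#' AHA bull's-eye tables as CSV.
#'
#' @param report an `lv_study` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(f) { written <<- c(written, f); f }

  write_cohort_csv(report$table, put(file.path(out_dir, "cohort.csv")))
  utils::write.csv(report$zscores, put(file.path(out_dir, "zscores.csv")),
                   row.names = FALSE, na = "")
  write_ssm_json(report$ssm, put(file.path(out_dir, "shape_model.json")))

  aha_rows <- list()
  for (ax in names(report$axes)) {
    a <- report$axes[[ax]]
    if (is.null(a)) next
    write_lda_json(a$lda, put(file.path(out_dir, sprintf("lda_%s.json", ax))))
    jsonlite::write_json(
      list(auc_resubstitution = a$validation$auc_resubstitution,
           auc_loo = a$validation$auc_loo,
           n_per_group = as.list(stats::setNames(as.numeric(a$n_per_group),
                                                 a$labels)),
           threshold_mmHg = a$validation$threshold_mmHg),
      put(file.path(out_dir, sprintf("validation_%s.json", ax))),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(a$modes, put(file.path(out_dir, sprintf("modes_%s.csv", ax))),
                     row.names = FALSE)
    for (side in c("minus", "plus")) {
      ex <- a$extremes[[side]]
      write_mesh_vtk(ex$mesh,
                     put(file.path(out_dir, sprintf("extreme_%s_%s.vtk", ax, side))))
      aha_rows[[paste(ax, side)]] <-
        data.frame(axis = ax, side = side, segment = seq_len(17),
                   name = names(ex$aha17), thickness_mm = as.numeric(ex$aha17))
    }
  }
  if (length(aha_rows))
    utils::write.csv(do.call(rbind, aha_rows),
                     put(file.path(out_dir, "aha17_extremes.csv")),
                     row.names = FALSE)

  manifest <- report$manifest
  manifest$files <- lapply(stats::setNames(written, basename(written)),
                           function(f) unname(tools::md5sum(f)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest_path)
}
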