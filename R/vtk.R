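# Legacy ASCII VTK unstructured-grid export (quad cells, cell data).

vtk_header <- function(con, mesh, title) {
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  n <- nrow(mesh$nodes)
  writeLines(sprintf("POINTS %d double", n), con)
  writeLines(sprintf("%.12g %.12g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  m <- nrow(mesh$cells)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  writeLines(sprintf("4 %d %d %d %d",
                     mesh$cells[, 1] - 1L, mesh$cells[, 2] - 1L,
                     mesh$cells[, 3] - 1L, mesh$cells[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("9", m), con)   # VTK_QUAD
}

vtk_cell_scalar <- function(con, name, vals) {
  writeLines(c(sprintf("SCALARS %s double 1", name), "LOOKUP_TABLE default"),
             con)
  writeLines(sprintf("%.12g", vals), con)
}

#' Write a quad mesh to legacy VTK
#'
#' Cell data `station` (sweep station index) and `area` are attached.
#'
#' @param mesh a `quad_mesh`.
#' @param path output `.vtk` file.
#' @export
write_vtk_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "quad_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mesh, "tortuflow mesh")
  m <- nrow(mesh$cells)
  writeLines(sprintf("CELL_DATA %d", m), con)
  vtk_cell_scalar(con, "station", rep(seq_len(mesh$n_along),
                                      each = mesh$n_across))
  vtk_cell_scalar(con, "area", mesh$cell_area)
  invisible(path)
}

#' Write solved flow fields to legacy VTK
#'
#' Cell data `u`, `v`, `p` and derived `speed`.
#'
#' @param mesh a `quad_mesh`.
#' @param fields a `flow_fields` solved on `mesh`.
#' @param path output `.vtk` file.
#' @export
write_vtk_fields <- function(mesh, fields, path) {
  stopifnot(inherits(mesh, "quad_mesh"), inherits(fields, "flow_fields"))
  con <- file(path, "w")
  on.exit(close(con))
  vtk_header(con, mesh, "tortuflow fields")
  writeLines(sprintf("CELL_DATA %d", nrow(mesh$cells)), con)
  vtk_cell_scalar(con, "u", fields$u)
  vtk_cell_scalar(con, "v", fields$v)
  vtk_cell_scalar(con, "p", fields$p)
  vtk_cell_scalar(con, "speed", sqrt(fields$u^2 + fields$v^2))
  invisible(path)
}

#' Write a residual history to CSV
#'
#' @param run a `flow_fields` or `flow_series`.
#' @param path output file.
#' @export
write_residuals_csv <- function(run, path) {
  write_numeric_csv(residual_history(run), path)
}
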