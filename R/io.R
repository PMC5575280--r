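#' Export a mesh (and optional results) to legacy VTK
#'
#' Writes an ASCII legacy VTK unstructured grid for visual inspection in
#' ParaView or similar: hexahedra (cell type 12) or triangles (type 5), with
#' optional nodal displacement vectors and per-cell von Mises stress.
#'
#' @param mesh a [fem_mesh()].
#' @param path output file path (conventionally `.vtk`).
#' @param result optional `fem_result` whose displacements/stresses are
#'   attached as point/cell data.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, result = NULL) {
  stopifnot(inherits(mesh, "fem_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  nn <- n_nodes(mesh); ne <- n_elements(mesh)
  npe <- ncol(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "daphniarmor mesh export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(format(mesh$nodes, digits = 12, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("CELLS %d %d", ne, ne * (npe + 1L)), con)
  utils::write.table(cbind(npe, mesh$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(if (npe == 8L) 12L else 5L, ne)), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS material int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(mesh$material_id))), con)
  if (!is.null(result)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(result$element_stress, digits = 9), con)
    writeLines(sprintf("POINT_DATA %d", nn), con)
    writeLines("VECTORS displacement double", con)
    utils::write.table(format(result$displacements, digits = 9,
                              scientific = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read / write a model (mesh, materials, load case) as JSON
#'
#' Documented interchange schema: object with `nodes` (n x 3 array, metres),
#' `elements` (1-based connectivity), `element_kind`, `material_id`,
#' `materials` (records of `id`, `young_modulus`, `poisson_ratio`,
#' `thickness`), and optionally `fixed_dofs` / `point_loads` arrays.
#'
#' @param path JSON file path.
#' @param mesh,materials,load model parts (writer only; `materials`/`load`
#'   optional).
#' @return reader: list with `mesh`, `materials`, `load` (the latter two may
#'   be `NULL`); writer: `path` invisibly.
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mesh <- fem_mesh(matrix(unlist(j$nodes), ncol = 3, byrow = FALSE),
                   matrix(as.integer(unlist(j$elements)),
                          ncol = if (j$element_kind == "hex8") 8L else 3L,
                          byrow = FALSE),
                   element_kind = j$element_kind,
                   material_id = j$material_id)
  materials <- NULL
  if (!is.null(j$materials)) {
    materials <- material_table(j$materials$id, j$materials$young_modulus,
                                j$materials$poisson_ratio,
                                j$materials$thickness %||% NA_real_)
  }
  load <- NULL
  if (!is.null(j$fixed_dofs)) {
    load <- load_case(j$fixed_dofs, j$point_loads)
  }
  list(mesh = mesh, materials = materials, load = load)
}

#' @rdname read_model_json
#' @export
write_model_json <- function(mesh, path, materials = NULL, load = NULL) {
  stopifnot(inherits(mesh, "fem_mesh"))
  j <- list(nodes = mesh$nodes, elements = mesh$elements,
            element_kind = mesh$element_kind,
            material_id = mesh$material_id)
  if (!is.null(materials)) j$materials <- as.data.frame(materials)
  if (!is.null(load)) {
    j$fixed_dofs <- as.data.frame(load$fixed_dofs)
    j$point_loads <- as.data.frame(load$point_loads)
  }
  jsonlite::write_json(j, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
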