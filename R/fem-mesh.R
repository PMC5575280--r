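#' Finite-element mesh
#'
#' Container for the small structural models used throughout the package:
#' 8-node hexahedral solids (`"hex8"`) for the laminate cylinder stacks and
#' 3-node flat facet shells (`"shell3"`) for the carapace surface models.
#' Coordinates are stored in SI metres; unit conversions happen only at I/O
#' boundaries.
#'
#' @param nodes numeric matrix, one row per node, three columns (x, y, z) in
#'   metres.
#' @param elements integer matrix of connectivity, one row per element; 8
#'   columns for `"hex8"`, 3 for `"shell3"`. Indices are 1-based.
#' @param element_kind `"hex8"` or `"shell3"`.
#' @param material_id integer or character vector, one material label per
#'   element, resolvable in the material table passed to the solver.
#' @return an object of class `fem_mesh`.
#' @seealso [material_table()], [assemble_and_solve()], [shell_solve()]
#' @export
fem_mesh <- function(nodes, elements, element_kind = c("hex8", "shell3"),
                     material_id) {
  element_kind <- match.arg(element_kind)
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3L) stop("nodes must have three coordinate columns")
  elements <- as.matrix(elements)
  storage.mode(elements) <- "integer"
  npe <- c(hex8 = 8L, shell3 = 3L)[[element_kind]]
  if (ncol(elements) != npe) {
    stop(sprintf("%s elements need %d nodes, got %d columns",
                 element_kind, npe, ncol(elements)))
  }
  if (length(material_id) == 1L) material_id <- rep(material_id, nrow(elements))
  if (length(material_id) != nrow(elements)) {
    stop("material_id must have one entry per element")
  }
  if (any(elements < 1L) || any(elements > nrow(nodes))) {
    stop("element connectivity references non-existent nodes")
  }
  structure(
    list(nodes = nodes, elements = elements, element_kind = element_kind,
         material_id = as.character(material_id)),
    class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("<fem_mesh> %s: %d nodes, %d elements, %d material label(s)\n",
              x$element_kind, nrow(x$nodes), nrow(x$elements),
              length(unique(x$material_id))))
  invisible(x)
}

#' Number of nodes / elements in a mesh
#' @param mesh a [fem_mesh()].
#' @return integer count.
#' @export
n_nodes <- function(mesh) nrow(mesh$nodes)

#' @rdname n_nodes
#' @export
n_elements <- function(mesh) nrow(mesh$elements)

#' Material table
#'
#' Linear-elastic isotropic material definitions keyed by label. Shell
#' elements additionally carry a wall thickness.
#'
#' @param id character vector of material labels.
#' @param young_modulus Young's modulus in Pa (> 0).
#' @param poisson_ratio Poisson's ratio, in `[0, 0.5)`.
#' @param thickness shell wall thickness in metres (`NA` for solid materials).
#' @return a `data.frame` of class `material_table`.
#' @export
material_table <- function(id, young_modulus, poisson_ratio, thickness = NA_real_) {
  stopifnot(length(id) == length(young_modulus),
            length(poisson_ratio) %in% c(1L, length(id)))
  if (any(young_modulus <= 0)) stop("young_modulus must be > 0")
  if (any(poisson_ratio < 0 | poisson_ratio >= 0.5)) {
    stop("poisson_ratio must lie in [0, 0.5)")
  }
  out <- data.frame(id = as.character(id),
                    young_modulus = as.numeric(young_modulus),
                    poisson_ratio = as.numeric(poisson_ratio),
                    thickness = as.numeric(thickness),
                    stringsAsFactors = FALSE)
  class(out) <- c("material_table", "data.frame")
  out
}

resolve_materials <- function(mesh, materials) {
  idx <- match(mesh$material_id, materials$id)
  if (anyNA(idx)) {
    missing <- unique(mesh$material_id[is.na(idx)])
    stop("material label(s) not in material table: ",
         paste(missing, collapse = ", "))
  }
  idx
}

#' Load case: supports and point loads
#'
#' @param fixed_dofs two-column matrix or data.frame `(node, axis)` of
#'   constrained degrees of freedom; axis is 1 (x), 2 (y) or 3 (z). For shell
#'   models axes 4-6 are the rotations.
#' @param point_loads three-column matrix or data.frame `(node, axis, newtons)`.
#' @return an object of class `load_case`.
#' @export
load_case <- function(fixed_dofs, point_loads = NULL) {
  fixed_dofs <- as.matrix(as.data.frame(fixed_dofs))[, 1:2, drop = FALSE]
  colnames(fixed_dofs) <- c("node", "axis")
  if (is.null(point_loads)) {
    point_loads <- matrix(numeric(0), ncol = 3)
  } else {
    point_loads <- as.matrix(as.data.frame(point_loads))[, 1:3, drop = FALSE]
  }
  colnames(point_loads) <- c("node", "axis", "newtons")
  fk <- paste(fixed_dofs[, 1], fixed_dofs[, 2])
  lk <- paste(point_loads[, 1], point_loads[, 2])
  if (length(intersect(fk, lk)) > 0L) {
    stop("constrained degrees of freedom overlap with loaded ones")
  }
  structure(list(fixed_dofs = fixed_dofs, point_loads = point_loads),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("<load_case> %d constrained dof(s), %d point load(s), total |F| = %g N\n",
              nrow(x$fixed_dofs), nrow(x$point_loads),
              sum(abs(x$point_loads[, 3]))))
  invisible(x)
}

#' Validate a mesh against its invariants
#'
#' Checks connectivity bounds, resolvability of all material labels and, for
#' hexahedral meshes, positivity of the Jacobian determinant at all 2x2x2
#' quadrature points of every element.
#'
#' @param mesh a [fem_mesh()].
#' @param materials a [material_table()] (optional; material resolution is
#'   skipped when absent).
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_mesh <- function(mesh, materials = NULL) {
  stopifnot(inherits(mesh, "fem_mesh"))
  if (!is.null(materials)) resolve_materials(mesh, materials)
  if (mesh$element_kind == "hex8") {
    gp <- as.matrix(expand.grid(x = c(-gauss2, gauss2),
                                y = c(-gauss2, gauss2),
                                z = c(-gauss2, gauss2)))
    dN <- lapply(seq_len(nrow(gp)),
                 function(i) hex8_dshape(gp[i, 1], gp[i, 2], gp[i, 3]))
    for (e in seq_len(n_elements(mesh))) {
      xe <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
      for (d in dN) {
        J <- crossprod(d, xe)
        if (det(J) <= 0) {
          stop(sprintf("element %d has non-positive Jacobian determinant", e))
        }
      }
    }
  } else {
    for (e in seq_len(n_elements(mesh))) {
      xe <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
      a2 <- crossprod_vec3(xe[2, ] - xe[1, ], xe[3, ] - xe[1, ])
      if (sqrt(sum(a2^2)) / 2 <= 0) {
        stop(sprintf("element %d is a degenerate (zero-area) facet", e))
      }
    }
  }
  invisible(TRUE)
}

# per-element volumes of a hex8 mesh (2x2x2 Gauss integration of det J)
hex_volumes <- function(mesh) {
  stopifnot(mesh$element_kind == "hex8")
  gp <- as.matrix(expand.grid(c(-gauss2, gauss2), c(-gauss2, gauss2),
                              c(-gauss2, gauss2)))
  dN <- lapply(seq_len(8), function(i) hex8_dshape(gp[i, 1], gp[i, 2], gp[i, 3]))
  vapply(seq_len(n_elements(mesh)), function(e) {
    xe <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    sum(vapply(dN, function(d) det(crossprod(d, xe)), numeric(1)))
  }, numeric(1))
}
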