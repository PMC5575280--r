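# Solid hexahedral displacement FEM.
#
# Element: 8-node trilinear hexahedron, 2x2x2 Gauss quadrature, optionally
# augmented with Wilson-Taylor incompatible bending modes (nine internal
# degrees of freedom, statically condensed at element level, incompatible-mode
# strains evaluated with the centroid Jacobian so that the constant-strain
# patch test is passed exactly on distorted meshes).

elastic_D3 <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# strain-displacement rows for a set of nodal derivative triples (n x 3)
strain_B <- function(dNdx) {
  n <- nrow(dNdx)
  B <- matrix(0, 6, 3 * n)
  ix <- 3 * seq_len(n) - 2
  B[1, ix] <- dNdx[, 1]
  B[2, ix + 1] <- dNdx[, 2]
  B[3, ix + 2] <- dNdx[, 3]
  B[4, ix] <- dNdx[, 2]; B[4, ix + 1] <- dNdx[, 1]
  B[5, ix + 1] <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 2]
  B[6, ix] <- dNdx[, 3]; B[6, ix + 2] <- dNdx[, 1]
  B
}

# derivatives of the three incompatible bubble modes (1-xi^2, 1-eta^2, 1-zeta^2)
bubble_dshape <- function(xi, eta, zeta) {
  matrix(c(-2 * xi, 0, 0,
           0, -2 * eta, 0,
           0, 0, -2 * zeta), ncol = 3, byrow = TRUE)
}

hex8_gauss_points <- local({
  g <- as.matrix(expand.grid(xi = c(-gauss2, gauss2),
                             eta = c(-gauss2, gauss2),
                             zeta = c(-gauss2, gauss2)))
  lapply(seq_len(8), function(i) g[i, ])
})

# 24x24 (condensed) stiffness of one hexahedron
hex8_stiffness <- function(xe, D, incompatible_modes = TRUE) {
  Kcc <- matrix(0, 24, 24)
  Kci <- matrix(0, 24, 9)
  Kii <- matrix(0, 9, 9)
  J0 <- crossprod(hex8_dshape(0, 0, 0), xe)
  detJ0 <- det(J0)
  J0inv <- solve(J0)
  for (gp in hex8_gauss_points) {
    dN <- hex8_dshape(gp[1], gp[2], gp[3])
    J <- crossprod(dN, xe)
    detJ <- det(J)
    if (detJ <= 0) stop("non-positive Jacobian in hexahedron")
    dNdx <- dN %*% t(solve(J))
    B <- strain_B(dNdx)
    Kcc <- Kcc + crossprod(B, D %*% B) * detJ
    if (incompatible_modes) {
      # Taylor correction: map bubble derivatives with the centroid Jacobian
      dMdx <- bubble_dshape(gp[1], gp[2], gp[3]) %*% t(J0inv) * (detJ0 / detJ)
      Bi <- strain_B(dMdx)
      Kci <- Kci + crossprod(B, D %*% Bi) * detJ
      Kii <- Kii + crossprod(Bi, D %*% Bi) * detJ
    }
  }
  if (incompatible_modes) {
    Kcc <- Kcc - Kci %*% solve(Kii, t(Kci))
  }
  Kcc
}

solve_result <- function(displacements, element_stress, reactions = NULL,
                         strain_energy = NA_real_, external_work = NA_real_) {
  structure(
    list(displacements = displacements,
         element_stress = element_stress,
         max_deformation = max(sqrt(rowSums(displacements^2))),
         max_stress = if (length(element_stress)) max(element_stress) else 0,
         reactions = reactions,
         strain_energy = strain_energy,
         external_work = external_work),
    class = "fem_result")
}

#' @export
print.fem_result <- function(x, ...) {
  cat(sprintf("<fem_result> %d nodes | max deformation %.4g m | max von Mises stress %.4g Pa\n",
              nrow(x$displacements), x$max_deformation, x$max_stress))
  invisible(x)
}

dof_index <- function(node, axis, ndof_per_node) {
  (node - 1L) * ndof_per_node + axis
}

build_load_vector <- function(load, n_node, ndof_per_node) {
  f <- numeric(n_node * ndof_per_node)
  pl <- load$point_loads
  if (nrow(pl)) {
    idx <- dof_index(pl[, 1], pl[, 2], ndof_per_node)
    for (i in seq_along(idx)) f[idx[i]] <- f[idx[i]] + pl[i, 3]
  }
  f
}

# shared reduced solve: returns full displacement vector + reactions
constrained_solve <- function(K, f, fixed_idx) {
  n <- length(f)
  free <- setdiff(seq_len(n), fixed_idx)
  if (length(free) == 0L) return(list(u = numeric(n), reactions = -f))
  Kff <- K[free, free, drop = FALSE]
  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, f[free])),
    error = function(e) {
      stop("under-constrained: stiffness system is singular; ",
           "constraints do not remove all rigid-body modes (",
           conditionMessage(e), ")", call. = FALSE)
    })
  # guard against a factorization that silently "succeeded" on a singular system
  if (any(!is.finite(uf))) {
    stop("under-constrained: stiffness system is singular", call. = FALSE)
  }
  u <- numeric(n)
  u[free] <- uf
  r <- as.numeric(K %*% u) - f
  # residual at free dofs must vanish: equilibrium check
  res <- max(abs(r[free]))
  fscale <- max(abs(f))
  if (fscale > 0 && res > 1e-6 * fscale) {
    stop(sprintf("under-constrained or ill-conditioned: equilibrium residual %.3g exceeds tolerance",
                 res / fscale), call. = FALSE)
  }
  list(u = u, reactions = r)
}

#' Assemble and solve a linear elastic solid model
#'
#' Static displacement finite-element solution for an 8-node hexahedral mesh:
#' assembles the global sparse stiffness matrix, applies the supports and
#' point loads of the load case, solves for nodal displacements, and
#' post-processes von Mises equivalent stress at element centroids.
#'
#' @param mesh a `hex8` [fem_mesh()].
#' @param materials a [material_table()] resolving every `material_id`.
#' @param load a [load_case()].
#' @param incompatible_modes logical; augment each hexahedron with
#'   Wilson-Taylor incompatible bending modes (default `TRUE`). The plain
#'   trilinear element is retained under `FALSE` but is markedly too stiff in
#'   bending-dominated problems on coarse meshes.
#' @return a `fem_result` with per-node `displacements` (metres), per-element
#'   von Mises `element_stress` (Pa), their maxima, reaction forces and the
#'   strain-energy / external-work pair (which agree for a converged solve).
#' @export
assemble_and_solve <- function(mesh, materials, load, incompatible_modes = TRUE) {
  stopifnot(inherits(mesh, "fem_mesh"), mesh$element_kind == "hex8",
            inherits(load, "load_case"))
  midx <- resolve_materials(mesh, materials)
  nn <- n_nodes(mesh)
  ne <- n_elements(mesh)

  # one D and one stiffness per distinct material (meshes reuse geometry a lot,
  # but element geometry varies; cache D only)
  Dcache <- lapply(seq_len(nrow(materials)), function(i)
    elastic_D3(materials$young_modulus[i], materials$poisson_ratio[i]))

  nk <- 24L * 24L
  ii <- integer(ne * nk); jj <- integer(ne * nk); vv <- numeric(ne * nk)
  pos <- 0L
  for (e in seq_len(ne)) {
    conn <- mesh$elements[e, ]
    xe <- mesh$nodes[conn, , drop = FALSE]
    ke <- tryCatch(
      hex8_stiffness(xe, Dcache[[midx[e]]], incompatible_modes),
      error = function(err) stop(sprintf("element %d: %s", e,
                                         conditionMessage(err)), call. = FALSE))
    edof <- as.vector(t(cbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn)))
    ii[pos + seq_len(nk)] <- rep(edof, times = 24L)
    jj[pos + seq_len(nk)] <- rep(edof, each = 24L)
    vv[pos + seq_len(nk)] <- as.vector(ke)
    pos <- pos + nk
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(3L * nn, 3L * nn),
                            symmetric = FALSE)
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  f <- build_load_vector(load, nn, 3L)
  fixed_idx <- dof_index(load$fixed_dofs[, 1], load$fixed_dofs[, 2], 3L)
  sol <- constrained_solve(K, f, fixed_idx)
  u <- matrix(sol$u, ncol = 3, byrow = TRUE)

  # centroid von Mises stress per element (compatible part of the strain field)
  stress <- numeric(ne)
  dN0 <- hex8_dshape(0, 0, 0)
  for (e in seq_len(ne)) {
    conn <- mesh$elements[e, ]
    xe <- mesh$nodes[conn, , drop = FALSE]
    J <- crossprod(dN0, xe)
    dNdx <- dN0 %*% t(solve(J))
    B <- strain_B(dNdx)
    ue <- as.vector(t(u[conn, , drop = FALSE]))
    sig <- Dcache[[midx[e]]] %*% (B %*% ue)
    stress[e] <- von_mises(sig)
  }

  se <- 0.5 * sum(sol$u * as.numeric(K %*% sol$u))
  ew <- 0.5 * sum(f * sol$u)
  solve_result(u, stress, reactions = sol$reactions,
               strain_energy = se, external_work = ew)
}

von_mises <- function(sig) {
  # sig: (xx, yy, zz, xy, yz, zx)
  sqrt(0.5 * ((sig[1] - sig[2])^2 + (sig[2] - sig[3])^2 + (sig[3] - sig[1])^2) +
         3 * (sig[4]^2 + sig[5]^2 + sig[6]^2))
}

#' Maximum displacement magnitude over a node subset
#'
#' Used to extract the reported "maximum deformation" of a model region, e.g.
#' the bottom face of a laminate cylinder stack.
#'
#' @param result a `fem_result`.
#' @param node_subset integer vector of node indices (non-empty).
#' @param component `"magnitude"` (default) or one of `"x"`, `"y"`, `"z"` for a
#'   single signed-axis absolute displacement.
#' @return maximum deformation in metres.
#' @export
max_deformation_in_region <- function(result, node_subset,
                                      component = c("magnitude", "x", "y", "z")) {
  component <- match.arg(component)
  node_subset <- as.integer(node_subset)
  if (length(node_subset) == 0L) stop("node_subset must be non-empty")
  U <- result$displacements[node_subset, , drop = FALSE]
  if (component == "magnitude") max(sqrt(rowSums(U^2)))
  else max(abs(U[, match(component, c("x", "y", "z"))]))
}
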