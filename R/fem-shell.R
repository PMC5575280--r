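# Flat facet shell: constant-strain membrane triangle superposed with the
# discrete-Kirchhoff plate-bending triangle (DKT, Batoz formulation). Each
# node carries six degrees of freedom (three translations, three rotations);
# the in-plane ("drilling") rotation receives a small artificial stiffness so
# that assemblies of coplanar facets remain non-singular.

# DKT strain-displacement matrix (3 x 9) at area coordinates (xi, eta) for a
# triangle with local in-plane coordinates (x1,y1),(x2,y2),(x3,y3).
# Nodal dof order (w, thx, thy) with thx = dw/dy, thy = -dw/dx.
dkt_B <- function(xy, xi, eta) {
  x23 <- xy[2, 1] - xy[3, 1]; y23 <- xy[2, 2] - xy[3, 2]
  x31 <- xy[3, 1] - xy[1, 1]; y31 <- xy[3, 2] - xy[1, 2]
  x12 <- xy[1, 1] - xy[2, 1]; y12 <- xy[1, 2] - xy[2, 2]
  L23 <- x23^2 + y23^2; L31 <- x31^2 + y31^2; L12 <- x12^2 + y12^2
  P4 <- -6 * x23 / L23; P5 <- -6 * x31 / L31; P6 <- -6 * x12 / L12
  t4 <- -6 * y23 / L23; t5 <- -6 * y31 / L31; t6 <- -6 * y12 / L12
  q4 <- 3 * x23 * y23 / L23; q5 <- 3 * x31 * y31 / L31; q6 <- 3 * x12 * y12 / L12
  r4 <- 3 * y23^2 / L23; r5 <- 3 * y31^2 / L31; r6 <- 3 * y12^2 / L12
  A2 <- x31 * y12 - x12 * y31          # 2 * area

  Hx_xi <- c(P6 * (1 - 2 * xi) + (P5 - P6) * eta,
             q6 * (1 - 2 * xi) - (q5 + q6) * eta,
             -4 + 6 * (xi + eta) + r6 * (1 - 2 * xi) - eta * (r5 + r6),
             -P6 * (1 - 2 * xi) + eta * (P4 + P6),
             q6 * (1 - 2 * xi) - eta * (q6 - q4),
             -2 + 6 * xi + r6 * (1 - 2 * xi) + eta * (r4 - r6),
             -eta * (P5 + P4),
             eta * (q4 - q5),
             -eta * (r5 - r4))
  Hy_xi <- c(t6 * (1 - 2 * xi) + eta * (t5 - t6),
             1 + r6 * (1 - 2 * xi) - eta * (r5 + r6),
             -q6 * (1 - 2 * xi) + eta * (q5 + q6),
             -t6 * (1 - 2 * xi) + eta * (t4 + t6),
             -1 + r6 * (1 - 2 * xi) + eta * (r4 - r6),
             -q6 * (1 - 2 * xi) - eta * (q4 - q6),
             -eta * (t4 + t5),
             eta * (r4 - r5),
             -eta * (q4 - q5))
  Hx_eta <- c(-P5 * (1 - 2 * eta) - xi * (P6 - P5),
              q5 * (1 - 2 * eta) - xi * (q5 + q6),
              -4 + 6 * (xi + eta) + r5 * (1 - 2 * eta) - xi * (r5 + r6),
              xi * (P4 + P6),
              xi * (q4 - q6),
              -xi * (r6 - r4),
              P5 * (1 - 2 * eta) - xi * (P4 + P5),
              q5 * (1 - 2 * eta) + xi * (q4 - q5),
              -2 + 6 * eta + r5 * (1 - 2 * eta) + xi * (r4 - r5))
  Hy_eta <- c(-t5 * (1 - 2 * eta) - xi * (t6 - t5),
              1 + r5 * (1 - 2 * eta) - xi * (r5 + r6),
              -q5 * (1 - 2 * eta) + xi * (q5 + q6),
              xi * (t4 + t6),
              xi * (r4 - r6),
              -xi * (q4 - q6),
              t5 * (1 - 2 * eta) - xi * (t4 + t5),
              -1 + r5 * (1 - 2 * eta) + xi * (r4 - r5),
              -q5 * (1 - 2 * eta) - xi * (q4 - q5))

  rbind(y31 * Hx_xi + y12 * Hx_eta,
        -x31 * Hy_xi - x12 * Hy_eta,
        -x31 * Hx_xi - x12 * Hx_eta + y31 * Hy_xi + y12 * Hy_eta) / A2
}

# 9x9 DKT bending stiffness in local coordinates
dkt_stiffness <- function(xy, E, nu, t) {
  Db <- E * t^3 / (12 * (1 - nu^2)) *
    matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  A2 <- (xy[3, 1] - xy[1, 1]) * (xy[1, 2] - xy[2, 2]) -
        (xy[1, 1] - xy[2, 1]) * (xy[3, 2] - xy[1, 2])
  gp <- list(c(0.5, 0), c(0, 0.5), c(0.5, 0.5))
  K <- matrix(0, 9, 9)
  for (p in gp) {
    B <- dkt_B(xy, p[1], p[2])
    K <- K + crossprod(B, Db %*% B) * (A2 / 6)
  }
  K
}

# 6x6 constant-strain membrane stiffness in local coordinates, dof (u1,v1,...)
cst_stiffness <- function(xy, E, nu, t) {
  b <- c(xy[2, 2] - xy[3, 2], xy[3, 2] - xy[1, 2], xy[1, 2] - xy[2, 2])
  cc <- c(xy[3, 1] - xy[2, 1], xy[1, 1] - xy[3, 1], xy[2, 1] - xy[1, 1])
  A <- 0.5 * ((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
              (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2]))
  Bm <- matrix(0, 3, 6)
  Bm[1, c(1, 3, 5)] <- b
  Bm[2, c(2, 4, 6)] <- cc
  Bm[3, c(1, 3, 5)] <- cc
  Bm[3, c(2, 4, 6)] <- b
  Bm <- Bm / (2 * A)
  Dm <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  list(K = t * A * crossprod(Bm, Dm %*% Bm), B = Bm, D = Dm, area = A)
}

# local orthonormal frame of a facet; rows e1, e2, e3
facet_frame <- function(xe) {
  e1 <- xe[2, ] - xe[1, ]
  n <- crossprod_vec3(e1, xe[3, ] - xe[1, ])
  nn <- sqrt(sum(n^2))
  if (nn <= .Machine$double.eps * max(abs(xe)) ^ 2) {
    stop("degenerate (zero-area) facet")
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e3 <- n / nn
  e2 <- crossprod_vec3(e3, e1)
  rbind(e1, e2, e3)
}

# 18x18 facet shell stiffness in global coordinates + local stress operators
shell3_stiffness <- function(xe, E, nu, t, drill_factor = 1e-6) {
  R <- facet_frame(xe)
  xy_local <- t(R %*% t(sweep(xe, 2, xe[1, ])))[, 1:2, drop = FALSE]
  mem <- cst_stiffness(xy_local, E, nu, t)
  if (mem$area <= 0) stop("degenerate (zero-area) facet")
  Kb <- dkt_stiffness(xy_local, E, nu, t)
  Klocal <- matrix(0, 18, 18)
  mi <- c(1, 2, 7, 8, 13, 14)            # u, v per node
  bi <- c(3, 4, 5, 9, 10, 11, 15, 16, 17) # w, thx, thy per node
  di <- c(6, 12, 18)                     # drilling rotation
  Klocal[mi, mi] <- mem$K
  Klocal[bi, bi] <- Kb
  kd <- drill_factor * max(diag(Klocal))
  Klocal[cbind(di, di)] <- kd
  Tm <- matrix(0, 18, 18)
  for (k in 0:5) Tm[3 * k + 1:3, 3 * k + 1:3] <- R
  list(K = crossprod(Tm, Klocal %*% Tm), R = R, xy = xy_local,
       Tm = Tm, mem = mem)
}

#' Solve a thin-shell carapace model
#'
#' Flat-facet shell solution for a `shell3` mesh: each triangular facet
#' carries a constant-strain membrane field superposed with discrete-Kirchhoff
#' plate bending, with six degrees of freedom per node. Supports and loads
#' follow the same [load_case()] contract as [assemble_and_solve()] (axes 4-6
#' address the nodal rotations).
#'
#' @inheritParams assemble_and_solve
#' @param shell_mesh a `shell3` [fem_mesh()]; every material referenced must
#'   have a positive `thickness`.
#' @return a `fem_result`; `element_stress` is the larger of the top/bottom
#'   surface von Mises stresses (membrane + bending) per facet.
#' @export
shell_solve <- function(shell_mesh, materials, load) {
  stopifnot(inherits(shell_mesh, "fem_mesh"),
            shell_mesh$element_kind == "shell3",
            inherits(load, "load_case"))
  midx <- resolve_materials(shell_mesh, materials)
  if (any(!is.finite(materials$thickness[midx]) | materials$thickness[midx] <= 0)) {
    stop("shell elements require a positive material thickness")
  }
  nn <- n_nodes(shell_mesh)
  ne <- n_elements(shell_mesh)
  nk <- 18L * 18L
  ii <- integer(ne * nk); jj <- integer(ne * nk); vv <- numeric(ne * nk)
  ops <- vector("list", ne)
  pos <- 0L
  for (e in seq_len(ne)) {
    conn <- shell_mesh$elements[e, ]
    xe <- shell_mesh$nodes[conn, , drop = FALSE]
    m <- midx[e]
    se <- tryCatch(
      shell3_stiffness(xe, materials$young_modulus[m],
                       materials$poisson_ratio[m], materials$thickness[m]),
      error = function(err) stop(sprintf("element %d: %s", e,
                                         conditionMessage(err)), call. = FALSE))
    ops[[e]] <- se
    edof <- as.vector(vapply(conn, function(nd) 6L * (nd - 1L) + 1:6,
                             integer(6)))
    ii[pos + seq_len(nk)] <- rep(edof, times = 18L)
    jj[pos + seq_len(nk)] <- rep(edof, each = 18L)
    vv[pos + seq_len(nk)] <- as.vector(se$K)
    pos <- pos + nk
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(6L * nn, 6L * nn))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)

  f <- build_load_vector(load, nn, 6L)
  fixed_idx <- dof_index(load$fixed_dofs[, 1], load$fixed_dofs[, 2], 6L)
  sol <- constrained_solve(K, f, fixed_idx)
  U6 <- matrix(sol$u, ncol = 6, byrow = TRUE)
  u <- U6[, 1:3, drop = FALSE]

  stress <- numeric(ne)
  for (e in seq_len(ne)) {
    conn <- shell_mesh$elements[e, ]
    se <- ops[[e]]
    m <- midx[e]
    t_sh <- materials$thickness[m]
    ulocal <- as.numeric(se$Tm %*% as.vector(t(U6[conn, , drop = FALSE])))
    mi <- c(1, 2, 7, 8, 13, 14)
    bi <- c(3, 4, 5, 9, 10, 11, 15, 16, 17)
    sig_m <- se$mem$D %*% (se$mem$B %*% ulocal[mi])
    Db <- materials$young_modulus[m] * t_sh^3 /
      (12 * (1 - materials$poisson_ratio[m]^2)) *
      matrix(c(1, materials$poisson_ratio[m], 0,
               materials$poisson_ratio[m], 1, 0,
               0, 0, (1 - materials$poisson_ratio[m]) / 2), 3, 3)
    Bb <- dkt_B(se$xy, 1 / 3, 1 / 3)
    Mvec <- Db %*% (Bb %*% ulocal[bi])
    sb <- 6 * Mvec / t_sh^2
    vm <- function(s) sqrt(s[1]^2 - s[1] * s[2] + s[2]^2 + 3 * s[3]^2)
    stress[e] <- max(vm(sig_m + sb), vm(sig_m - sb))
  }
  se_energy <- 0.5 * sum(sol$u * as.numeric(K %*% sol$u))
  ew <- 0.5 * sum(f * sol$u)
  solve_result(u, stress, reactions = sol$reactions,
               strain_energy = se_energy, external_work = ew)
}
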