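test_that("uniaxial patch test: nu = 0 cube under uniform top load", {
  mesh <- block_mesh(1, 1, 1)
  g <- mesh$nodes
  bottom <- which(g[, 3] == 0)
  top <- which(g[, 3] == 1)
  fix <- rbind(cbind(bottom, 3), cbind(1, 1), cbind(1, 2), cbind(2, 2))
  ld <- load_case(fix, cbind(top, 3, 0.25))    # total 1 N on unit area, E = 1
  res <- assemble_and_solve(mesh, material_table("m", 1, 0), ld)
  expect_equal(unname(res$displacements[top, 3]), rep(1, 4), tolerance = 1e-10)
  expect_lt(max(abs(res$displacements[, 1:2])), 1e-12)
  expect_equal(res$max_stress, 1, tolerance = 1e-10)
})

test_that("constant-strain field is reproduced exactly on a distorted mesh", {
  mesh <- block_mesh(2, 2, 2)
  g <- mesh$nodes
  interior <- which(apply(g, 1, function(p) all(p > 0 & p < 1)))
  g[interior, ] <- c(0.42, 0.55, 0.61)    # single interior node, distorted
  mesh <- fem_mesh(g, mesh$elements, "hex8", "m")
  validate_mesh(mesh)
  ufield <- function(x) cbind(0.10 * x[, 1] + 0.02 * x[, 2] + 0.03 * x[, 3],
                              0.05 * x[, 2] + 0.01 * x[, 3],
                              0.02 * x[, 1] + 0.04 * x[, 3])
  # prescribe the linear field on all boundary nodes via stiff springs is
  # avoided: solve the reduced system directly against the exact solution
  boundary <- setdiff(seq_len(nrow(g)), interior)
  u_exact <- ufield(g)
  # equilibrium: with all boundary dofs fixed at the exact linear field, the
  # interior solution must reproduce the field to machine precision
  fix <- cbind(rep(boundary, each = 3), rep(1:3, length(boundary)))
  ld <- load_case(fix, cbind(interior, 3, 0))
  # impose non-homogeneous values by superposition: K u = 0 with u_b given
  # translates to f_free = -K_fb u_b; emulate via direct assembly check
  mats <- material_table("m", 7, 0.3)
  res0 <- assemble_and_solve(mesh, mats, ld)    # sanity: solvable system
  expect_true(all(is.finite(res0$displacements)))
  # direct check through the element stiffness: residual of the exact field
  # at the interior node must vanish (constant-strain completeness)
  Dm <- daphniarmor:::elastic_D3(7, 0.3)
  r <- numeric(3)
  for (e in seq_len(n_elements(mesh))) {
    conn <- mesh$elements[e, ]
    if (!(interior %in% conn)) next
    ke <- daphniarmor:::hex8_stiffness(mesh$nodes[conn, ], Dm, TRUE)
    fe <- ke %*% as.vector(t(u_exact[conn, ]))
    pos <- which(conn == interior)
    r <- r + fe[3 * (pos - 1) + 1:3]
  }
  expect_lt(max(abs(r)), 1e-10 * max(abs(u_exact)) * 7)
})

test_that("single unconstrained hexahedron has exactly 6 rigid-body modes", {
  for (incomp in c(TRUE, FALSE)) {
    ke <- daphniarmor:::hex8_stiffness(daphniarmor:::hex8_local / 2 + 0.5,
                                       daphniarmor:::elastic_D3(1, 0.3),
                                       incomp)
    expect_equal(ke, t(ke), tolerance = 1e-12)   # symmetry
    ev <- eigen(ke, symmetric = TRUE, only.values = TRUE)$values
    expect_identical(sum(abs(ev) < 1e-9 * max(ev)), 6L)
  }
})

test_that("zero load gives zero displacements and zero stress", {
  mesh <- block_mesh(2, 2, 2)
  g <- mesh$nodes
  fixed <- which(g[, 1] == 0)
  ld <- load_case(cbind(rep(fixed, each = 3), rep(1:3, length(fixed))),
                  cbind(which(g[, 1] == 1)[1], 3, 0))
  res <- assemble_and_solve(mesh, material_table("m", 5, 0.25), ld)
  expect_equal(res$max_deformation, 0)
  expect_equal(res$max_stress, 0)
})

test_that("cantilever tip deflection matches Euler-Bernoulli and converges", {
  expect_lt(abs(cantilever_rel_error(16, 2, 2)), 0.05)
  # plain trilinear elements converge monotonically from below under uniform
  # refinement (the enhanced element is already within a shear-deflection
  # correction of the Euler-Bernoulli value at the coarse mesh)
  errs <- abs(c(cantilever_rel_error(8, 1, 1, incompatible_modes = FALSE),
                cantilever_rel_error(16, 2, 2, incompatible_modes = FALSE),
                cantilever_rel_error(24, 2, 4, incompatible_modes = FALSE)))
  expect_true(all(diff(errs) < 0))
})

test_that("external work matches strain energy", {
  mesh <- block_mesh(3, 2, 2)
  g <- mesh$nodes
  fixed <- which(g[, 1] == 0)
  tip <- which(g[, 1] == 1)
  ld <- load_case(cbind(rep(fixed, each = 3), rep(1:3, length(fixed))),
                  cbind(tip, 2, 0.01))
  res <- assemble_and_solve(mesh, material_table("m", 100, 0.3), ld)
  expect_equal(res$strain_energy, res$external_work, tolerance = 1e-8)
})

test_that("under-constrained systems raise an explicit error", {
  mesh <- block_mesh(1, 1, 1)
  ld <- load_case(cbind(1, 3), cbind(7, 3, 1))   # one dof fixed: rigid modes remain
  expect_error(assemble_and_solve(mesh, material_table("m", 1, 0.3), ld),
               "under-constrained")
})

test_that("mesh invariants are enforced", {
  expect_error(fem_mesh(matrix(0, 4, 3), matrix(c(1, 2, 9), 1), "shell3", "m"),
               "non-existent")
  # inverted element: negative Jacobian detected
  g <- daphniarmor:::hex8_local / 2 + 0.5
  g_bad <- g[c(5:8, 1:4), ]
  mesh <- fem_mesh(g_bad, matrix(1:8, 1), "hex8", "m")
  expect_error(validate_mesh(mesh), "Jacobian")
  # unresolvable material label
  mesh2 <- fem_mesh(g, matrix(1:8, 1), "hex8", "unknown")
  expect_error(validate_mesh(mesh2, material_table("m", 1, 0.3)),
               "material")
})

test_that("max_deformation_in_region matches a brute-force oracle", {
  res <- structure(list(displacements = matrix(c(3e-9, 4e-9, 0), 1)),
                   class = "fem_result")
  expect_equal(max_deformation_in_region(res, 1), 5e-9)
  expect_error(max_deformation_in_region(res, integer(0)), "non-empty")

  set.seed(42)
  for (rep in 1:10) {
    U <- matrix(rnorm(30), 10, 3)
    res <- structure(list(displacements = U), class = "fem_result")
    sub <- sample(10, 4)
    oracle <- max(vapply(sub, function(i) sqrt(sum(U[i, ]^2)), numeric(1)))
    expect_equal(max_deformation_in_region(res, sub), oracle)
    expect_equal(max_deformation_in_region(res, sub, component = "z"),
                 max(abs(U[sub, 3])))
  }
})
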