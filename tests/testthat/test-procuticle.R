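test_that("T360 and T120 follow the lamination arithmetic", {
  # published medians: thickness / layers * 2, then / 3
  expect_equal(t360_from_observation(pulex_uninduced_obs()), 0.843 / 9 * 2,
               tolerance = 1e-12)
  expect_equal(round(t360_from_observation(pulex_uninduced_obs()), 5), 0.18733)
  expect_equal(round(t360_from_observation(longi_uninduced_obs()), 5), 0.30633)
  expect_equal(t360_from_observation(procuticle_observation(1, 2)), 1)
  expect_equal(t120_from_t360(3), 1)
  expect_equal(round(t120_from_t360(0.18733), 5), 0.06244)
  expect_equal(round(t120_from_t360(0.30633), 5), 0.10211)
  expect_error(procuticle_observation(1, 0), "layer_count")
  expect_error(t120_from_t360(0), "t360")
})

test_that("cylinder counts reproduce the published 13 / 16 / 9", {
  expect_identical(cylinders_for_thickness(pulex_uninduced_obs()), 13L)
  expect_identical(cylinders_for_thickness(pulex_induced_obs()), 16L)
  expect_identical(cylinders_for_thickness(longi_uninduced_obs()), 9L)
})

test_that("stack mesh partitions materials into alternating strips", {
  # n = 1, strip_count = 2: two material regions of equal volume
  spec <- cylinder_stack_spec(1, 0.1, strip_count = 2L, n_across = 8L,
                              n_z_per_cylinder = 1L)
  mesh <- build_stack_mesh(spec)
  validate_mesh(mesh, rbind(spec$fibre, spec$matrix))
  vol_by <- tapply(daphniarmor:::hex_volumes(mesh), mesh$material_id, sum)
  expect_equal(length(vol_by), 2L)
  expect_equal(unname(vol_by["fibre"] / sum(vol_by)), 0.5, tolerance = 1e-6)

  # strip orientations cycle with period 3 at 120 degrees
  spec4 <- cylinder_stack_spec(4, 0.1, n_across = 8L, n_z_per_cylinder = 1L)
  mesh4 <- build_stack_mesh(spec4)
  cyl <- attr(mesh4, "cylinder")
  lab1 <- mesh4$material_id[cyl == 1]
  lab4 <- mesh4$material_id[cyl == 4]
  expect_identical(lab1, lab4)                    # 360 deg == 0 deg
  expect_false(identical(lab1, mesh4$material_id[cyl == 2]))

  # fibre volume fraction ~ 0.5 for any even strip count
  for (sc in c(4L, 6L, 8L)) {
    sp <- cylinder_stack_spec(1, 0.1, strip_count = sc, n_across = 12L,
                              n_z_per_cylinder = 1L)
    m <- build_stack_mesh(sp)
    v <- tapply(daphniarmor:::hex_volumes(m), m$material_id, sum)
    expect_equal(unname(v["fibre"] / sum(v)), 0.5, tolerance = 0.02)
  }

  expect_error(build_stack_mesh(
    cylinder_stack_spec(1, 0.1, strip_count = 16L, n_across = 8L)),
    "finer mesh")
  expect_error(cylinder_stack_spec(1, 0.1, strip_count = 3L), "even")
})

test_that("stack load case applies the documented supports and 3 mN total", {
  spec <- cylinder_stack_spec(1, 0.1, n_across = 8L, n_z_per_cylinder = 1L)
  mesh <- build_stack_mesh(spec)
  ld <- stack_load_case(mesh)
  expect_equal(sum(ld$point_loads[, 3]), -3e-3)
  expect_equal(nrow(ld$point_loads), 5L)
  # exactly one fully fixed node (all three axes)
  per_node <- table(ld$fixed_dofs[, 1])
  expect_identical(sum(per_node == 3L), 1L)
  # solvable: no rigid-body modes left
  res <- assemble_and_solve(mesh, rbind(spec$fibre, spec$matrix), ld)
  expect_true(all(is.finite(res$displacements)))
  expect_gt(res$max_deformation, 0)
})

test_that("lamination series decreases strictly and follows a power law", {
  ser <- coarse_series(pulex_uninduced_obs())
  expect_true(all(diff(ser$bottom_max_deformation_nm) < 0))
  fit <- fit_power_law(ser)
  expect_gt(fit$b, -3.3)
  expect_lt(fit$b, -2.3)
  expect_gt(fit$r_squared, 0.98)
})

test_that("thicker T120 gives smaller deformation at n = 1", {
  d1 <- function(obs) coarse_series(obs, max_cylinders = 1)$bottom_max_deformation_nm
  # T120 ordering: uninduced pulex (thin) > induced pulex > uninduced longicephala
  v <- c(i = d1(pulex_uninduced_obs()), ii = d1(pulex_induced_obs()),
         iii = d1(longi_uninduced_obs()))
  expect_true(v["i"] > v["ii"] && v["ii"] > v["iii"])
})

test_that("equal fibre and matrix moduli make the stack rotation-invariant", {
  obs <- longi_uninduced_obs()
  t120 <- t120_from_t360(t360_from_observation(obs))
  homo <- function(rot) {
    spec <- cylinder_stack_spec(2, t120, rotation_step_deg = rot,
                                fibre = material_table("fibre", 5e9, 0.3),
                                matrix = material_table("matrix", 5e9, 0.3),
                                n_across = 8L, n_z_per_cylinder = 1L)
    mesh <- build_stack_mesh(spec)
    res <- assemble_and_solve(mesh, rbind(spec$fibre, spec$matrix),
                              stack_load_case(mesh))
    res$max_deformation
  }
  expect_equal(homo(120), homo(90), tolerance = 1e-10)
  # and distinct moduli do depend on the laminate structure: swapping the
  # fibre / matrix assignment changes the response
  mk <- function(fe, me) {
    spec <- cylinder_stack_spec(2, t120,
                                fibre = material_table("fibre", fe, 0.3),
                                matrix = material_table("matrix", me, 0.3),
                                n_across = 8L, n_z_per_cylinder = 1L)
    mesh <- build_stack_mesh(spec)
    assemble_and_solve(mesh, rbind(spec$fibre, spec$matrix),
                       stack_load_case(mesh))$max_deformation
  }
  expect_gt(abs(mk(17e9, 0.2e9) / mk(0.2e9, 17e9) - 1), 1e-4)
})

test_that("procuticle CSV reader validates its columns", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(morphotype = "x", thickness_um = 1.2, layers = 8),
            tmp, row.names = FALSE)
  obs <- read_procuticle_csv(tmp)
  expect_length(obs, 1)
  expect_equal(obs[[1]]$thickness_um, 1.2)
  write.csv(data.frame(a = 1), tmp, row.names = FALSE)
  expect_error(read_procuticle_csv(tmp), "columns")
})
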