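template_pair <- function() {
  list(u = daphniarmor:::carapace_template("pulex", induced = FALSE),
       i = daphniarmor:::carapace_template("pulex", induced = TRUE))
}

structure_pair <- function() {
  list(u = procuticle_structure(0.843, 1.66e6),
       i = procuticle_structure(1.358, 2.93e6))
}

test_that("aligning a set with itself is the identity", {
  s <- template_pair()$u
  al <- align_landmark_sets(list(s, s))
  tr <- attr(al[[2]], "transform")
  expect_equal(tr$scale, 1, tolerance = 1e-10)
  expect_equal(tr$rotation, diag(3), tolerance = 1e-10)
  expect_equal(max(abs(tr$translation)), 0, tolerance = 1e-10)
  expect_equal(al[[2]]$surface, s$surface, tolerance = 1e-12)
})

test_that("alignment inverts an applied similarity transform", {
  s <- template_pair()$u
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  sc <- 1.8
  tv <- c(1e-4, -2e-4, 5e-5)
  s2 <- s
  for (blk in c("outline", "surface", "cleft", "reference")) {
    s2[[blk]] <- sweep(tcrossprod(s[[blk]], R) * sc, 2, tv, `+`)
  }
  al <- align_landmark_sets(list(s, s2))
  expect_equal(al[[2]]$surface, s$surface, tolerance = 1e-8)
  expect_equal(al[[2]]$outline, s$outline, tolerance = 1e-8)
})

test_that("3-point alignment residual beats random similarity transforms", {
  set.seed(3)
  s <- template_pair()$u
  s2 <- s
  for (blk in c("outline", "surface", "cleft", "reference")) {
    s2[[blk]] <- s[[blk]] * 1.2 + matrix(rnorm(length(s[[blk]]), 0, 2e-5),
                                         nrow(s[[blk]]), 3)
  }
  al <- align_landmark_sets(list(s, s2))
  resid <- sum((al[[2]]$reference - s$reference)^2)
  for (k in 1:20) {
    th <- rnorm(1, 0, 0.1); sc <- exp(rnorm(1, 0, 0.05))
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    tv <- rnorm(3, 0, 1e-5)
    cand <- sweep(tcrossprod(s2$reference, R) * sc, 2, tv, `+`)
    expect_gte(sum((cand - s$reference)^2), resid - 1e-18)
  }
})

test_that("collinear reference points are rejected", {
  s <- template_pair()$u
  s$reference <- rbind(c(0, 0, 0), c(1e-3, 0, 0), c(2e-3, 0, 0))
  expect_error(landmark_set(s$outline, s$surface, s$cleft, s$reference,
                            species = "pulex"), "non-collinear")
})

test_that("shape averaging is the pointwise mean and order-invariant", {
  set.seed(8)
  cfg <- generator_config(seed = 8)
  pop <- gen_carapace_population(cfg, "pulex", n = 4, jitter_sd = 0.02)
  al <- align_landmark_sets(pop)
  avg <- average_shapes(al)
  # brute-force per-coordinate mean
  oracle <- Reduce(`+`, lapply(al, `[[`, "surface")) / length(al)
  expect_equal(avg$surface, oracle, tolerance = 1e-12)
  avg2 <- average_shapes(rev(al))
  expect_equal(avg$surface, avg2$surface, tolerance = 1e-12)
  # averaging identical sets returns the set
  same <- average_shapes(list(pop[[1]], pop[[1]], pop[[1]]))
  expect_equal(same$outline, pop[[1]]$outline, tolerance = 1e-12)
  # mirror pair averages onto the mirror plane (z = 0 plane contains the refs)
  m <- pop[[1]]
  m$surface[, 3] <- -m$surface[, 3]
  mid <- average_shapes(list(pop[[1]], m))
  expect_equal(max(abs(mid$surface[, 3])), 0, tolerance = 1e-12)
})

test_that("shell model triangulation and node sets follow the grid rules", {
  s <- template_pair()$u
  m <- build_shell_model(s, structure_pair()$u)
  nr <- s$grid_dim[1]; nc <- s$grid_dim[2]
  expect_identical(n_elements(m$mesh),
                   as.integer(2 * (nr - 1) * (nc - 1) + 2 * (nr - 1)))
  expect_identical(n_nodes(m$mesh), as.integer(nr * nc + nr))
  # constrained nodes all on the outline rows/dorsal column, none ventral
  expect_length(intersect(m$constrained_nodes, m$ventral_nodes), 0)
  rows <- (m$constrained_nodes - 1L) %/% nc + 1L
  cols <- (m$constrained_nodes - 1L) %% nc + 1L
  expect_true(all(rows == 1L | rows == nr | cols == 1L))
  # load nodes sit in the column of maximal lateral width (exhaustive scan)
  depth_by_col <- vapply(seq_len(nc), function(c)
    max(abs(s$surface[seq(c, nr * nc, by = nc), 3])), numeric(1))
  expect_identical(m$load_column, which.max(depth_by_col))
  expect_equal(sum(abs(m$load$point_loads[, 3])), 1e-3)
})

test_that("a folded grid raises a degenerate-triangle error", {
  s <- template_pair()$u
  s$surface[2, ] <- s$surface[1, ]
  s$surface[12, ] <- s$surface[1, ]  # collapse a whole quad onto one point
  s$surface[11, ] <- s$surface[1, ]
  expect_error(build_shell_model(s, structure_pair()$u), "degenerate")
})

test_that("swap matrix reproduces the qualitative shape/structure ordering", {
  tp <- template_pair(); st <- structure_pair()
  sw <- run_swap_matrix(tp$u, tp$i, st$u, st$i)
  expect_identical(nrow(sw), 4L)
  expect_true(all(sw$max_deformation_um > 0))
  cell <- function(sh, stc) {
    sw$max_deformation_um[sw$shape == sh & sw$structure == stc]
  }
  # induced structure stiffens for either fixed shape
  expect_lt(cell("uninduced", "induced"), cell("uninduced", "uninduced"))
  expect_lt(cell("induced", "induced"), cell("induced", "uninduced"))
  # full published ordering: (u,i) < (i,i) < (u,u) < (i,u)
  expect_true(cell("uninduced", "induced") < cell("induced", "induced"))
  expect_true(cell("induced", "induced") < cell("uninduced", "uninduced"))
  expect_true(cell("uninduced", "uninduced") < cell("induced", "uninduced"))
})

test_that("shell deformation scales linearly with load and 1/E", {
  tp <- template_pair(); st <- structure_pair()
  m1 <- solve_shell_model(build_shell_model(tp$u, st$u, load_n = 1e-3))
  m2 <- solve_shell_model(build_shell_model(tp$u, st$u, load_n = 2e-3))
  expect_equal(m2$max_deformation_um / m1$max_deformation_um, 2,
               tolerance = 1e-8)
  stE <- procuticle_structure(st$u$thickness_um, 2 * st$u$young_modulus_pa)
  m3 <- solve_shell_model(build_shell_model(tp$u, stE, load_n = 1e-3))
  expect_equal(m3$max_deformation_um / m1$max_deformation_um, 0.5,
               tolerance = 1e-8)
})

test_that("maximum deformation falls on the free ventral margin", {
  tp <- template_pair()
  m <- build_shell_model(tp$u, structure_pair()$u)
  sol <- solve_shell_model(m)
  imax <- which.max(sqrt(rowSums(sol$result$displacements^2)))
  expect_true(imax %in% m$ventral_nodes)
})

test_that("landmark sets round-trip through the CSV format", {
  s <- template_pair()$u
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_landmarks_csv(s, tmp)
  back <- read_landmarks_csv(tmp, species = "pulex")
  expect_equal(back$surface, s$surface, tolerance = 1e-12)
  expect_equal(back$outline, s$outline, tolerance = 1e-12)
  expect_equal(back$reference, s$reference, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the landmark scheme tables carry the species point counts", {
  expect_identical(nrow(landmark_scheme("pulex")), 33L)
  expect_identical(nrow(landmark_scheme("longicephala")), 31L)
})
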