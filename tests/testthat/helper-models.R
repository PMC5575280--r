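# Shared fixture builders: all meshes are constructed in code at test time.

# structured hex8 block [0,L] x [0,b] x [0,h]
block_mesh <- function(nx, ny, nz, L = 1, b = 1, h = 1, material = "m") {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, b, length.out = ny + 1)
  zs <- seq(0, h, length.out = nz + 1)
  g <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  nid <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))
  conn <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in 1:nz) for (j in 1:ny) for (i in 1:nx) {
    e <- e + 1L
    conn[e, ] <- c(nid(i, j, k), nid(i + 1, j, k),
                   nid(i + 1, j + 1, k), nid(i, j + 1, k),
                   nid(i, j, k + 1), nid(i + 1, j, k + 1),
                   nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
  }
  fem_mesh(g, conn, "hex8", material)
}

# cantilever tip-deflection test: returns relative error vs FL^3 / 3EI
cantilever_rel_error <- function(nx, ny, nz, incompatible_modes = TRUE) {
  L <- 8; b <- 1; h <- 1; E <- 1000; F <- -1e-3
  mesh <- block_mesh(nx, ny, nz, L, b, h)
  g <- mesh$nodes
  fixed <- which(g[, 1] == 0)
  tip <- which(g[, 1] == L)
  ld <- load_case(cbind(rep(fixed, each = 3), rep(1:3, length(fixed))),
                  cbind(tip, 3, F / length(tip)))
  res <- assemble_and_solve(mesh, material_table("m", E, 0), ld,
                            incompatible_modes = incompatible_modes)
  I <- b * h^3 / 12
  wref <- abs(F) * L^3 / (3 * E * I)
  max(abs(res$displacements[tip, 3])) / wref - 1
}

# flat square plate shell mesh with right-angle triangulation
plate_mesh <- function(n, L = 1, material = "m") {
  xs <- seq(0, L, length.out = n + 1)
  g <- as.matrix(expand.grid(x = xs, y = xs))
  nid <- function(i, j) i + (n + 1) * (j - 1)
  conn <- matrix(0L, 2 * n * n, 3)
  e <- 0L
  for (j in 1:n) for (i in 1:n) {
    conn[e + 1L, ] <- c(nid(i, j), nid(i + 1, j), nid(i + 1, j + 1))
    conn[e + 2L, ] <- c(nid(i, j), nid(i + 1, j + 1), nid(i, j + 1))
    e <- e + 2L
  }
  fem_mesh(cbind(g, 0), conn, "shell3", material)
}

# independent Kirchhoff oracle: centre deflection of a simply supported
# square plate under a central point load (Navier double series)
kirchhoff_plate_centre_deflection <- function(P, L, E, nu, t, terms = 99) {
  D <- E * t^3 / (12 * (1 - nu^2))
  s <- 0
  for (m in seq(1, terms, 2)) for (n in seq(1, terms, 2)) {
    s <- s + sin(m * pi / 2)^2 * sin(n * pi / 2)^2 / (m^2 + n^2)^2
  }
  4 * P * L^2 / (pi^4 * D) * s
}

# simply supported plate, central point load: relative error vs the oracle
plate_rel_error <- function(n, t = 0.01) {
  L <- 1; E <- 1e6; nu <- 0.3; P <- -1
  mesh <- plate_mesh(n, L)
  g <- mesh$nodes
  edge <- which(g[, 1] %in% c(0, L) | g[, 2] %in% c(0, L))
  fix <- rbind(cbind(edge, 3),
               cbind(seq_len(nrow(g)), 1), cbind(seq_len(nrow(g)), 2))
  centre <- which(g[, 1] == L / 2 & g[, 2] == L / 2)
  ld <- load_case(fix, cbind(centre, 3, P))
  res <- shell_solve(mesh, material_table("m", E, nu, thickness = t), ld)
  wref <- kirchhoff_plate_centre_deflection(abs(P), L, E, nu, t)
  max(abs(res$displacements[, 3])) / wref - 1
}

# coarse laminate run shared by several property tests
coarse_series <- function(obs, ..., max_cylinders = 6L) {
  run_lamination_series(obs, max_cylinders = max_cylinders,
                        n_across = 8L, n_z_per_cylinder = 1L, ...)
}

pulex_uninduced_obs <- function() procuticle_observation(0.843, 9, "D. pulex uninduced")
pulex_induced_obs <- function() procuticle_observation(1.358, 11, "D. pulex induced")
longi_uninduced_obs <- function() procuticle_observation(0.919, 6, "D. longicephala uninduced")
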