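# Shared low-level numerics (loaded first by collation order).

# Gauss 2-point abscissa
gauss2 <- 1 / sqrt(3)

# local corner coordinates of the 8-node hexahedron (VTK ordering)
hex8_local <- matrix(c(-1, -1, -1,
                        1, -1, -1,
                        1,  1, -1,
                       -1,  1, -1,
                       -1, -1,  1,
                        1, -1,  1,
                        1,  1,  1,
                       -1,  1,  1), ncol = 3, byrow = TRUE)

# trilinear shape-function derivative matrix (8 x 3) at (xi, eta, zeta)
hex8_dshape <- function(xi, eta, zeta) {
  g <- hex8_local
  cbind(g[, 1] * (1 + g[, 2] * eta) * (1 + g[, 3] * zeta),
        g[, 2] * (1 + g[, 1] * xi)  * (1 + g[, 3] * zeta),
        g[, 3] * (1 + g[, 1] * xi)  * (1 + g[, 2] * eta)) / 8
}

crossprod_vec3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
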