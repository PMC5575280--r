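#' Procuticle observation
#'
#' A single STEM-derived measurement of the carapace procuticle: total
#' thickness and the number of bright-dark lamellae (each lamella spans a 180
#' degree rotation of chitin fibre orientation in the Bouligand stack).
#'
#' @param thickness_um procuticle thickness in micrometres (> 0).
#' @param layer_count integer number of lamellae (>= 1).
#' @param morphotype free-text label (species and induction state).
#' @return an object of class `procuticle_observation`.
#' @export
procuticle_observation <- function(thickness_um, layer_count, morphotype = "") {
  if (!is.finite(thickness_um) || thickness_um <= 0) {
    stop("thickness_um must be > 0")
  }
  layer_count <- as.integer(layer_count)
  if (is.na(layer_count) || layer_count < 1L) stop("layer_count must be >= 1")
  structure(list(thickness_um = thickness_um, layer_count = layer_count,
                 morphotype = as.character(morphotype)),
            class = "procuticle_observation")
}

#' @export
print.procuticle_observation <- function(x, ...) {
  cat(sprintf("<procuticle_observation> %s: %.3f um, %d layer(s); T120 = %.4f um -> %d cylinder(s)\n",
              if (nzchar(x$morphotype)) x$morphotype else "(unlabelled)",
              x$thickness_um, x$layer_count,
              t120_from_t360(t360_from_observation(x)),
              cylinders_for_thickness(x)))
  invisible(x)
}

#' Thickness of a full 360-degree fibre rotation
#'
#' One counted lamella corresponds to a 180 degree fibre rotation, so the
#' thickness spanned by a complete 360 degree rotation is
#' `thickness / layer_count * 2`.
#'
#' @param obs a [procuticle_observation()].
#' @return thickness in micrometres.
#' @export
t360_from_observation <- function(obs) {
  stopifnot(inherits(obs, "procuticle_observation"))
  obs$thickness_um / obs$layer_count * 2
}

#' Thickness of a 120-degree fibre rotation (one model cylinder)
#'
#' @param t360 thickness of a 360 degree rotation in micrometres (> 0).
#' @return `t360 / 3` in micrometres.
#' @export
t120_from_t360 <- function(t360) {
  if (!is.finite(t360) || t360 <= 0) stop("t360 must be > 0")
  t360 / 3
}

#' Cylinders needed to meet the observed procuticle thickness
#'
#' Number of whole 120-degree cylinders that fit into the observed thickness:
#' `floor(thickness / T120)`.
#'
#' @param obs a [procuticle_observation()].
#' @return integer cylinder count.
#' @export
cylinders_for_thickness <- function(obs) {
  t120 <- t120_from_t360(t360_from_observation(obs))
  as.integer(floor(obs$thickness_um / t120 + 1e-9))
}

#' Laminate cylinder-stack specification
#'
#' Geometry and materials for the stepwise laminate model of the procuticle:
#' a stack of `n_cylinders` discs, each representing a 120 degree fibre
#' rotation of thickness `t120_um`, subdivided vertically into parallel
#' strips of alternating fibre / matrix material, with the strip direction
#' rotated by `rotation_step_deg` from one cylinder to the next.
#'
#' @param n_cylinders number of stacked cylinders (>= 1; 6 spans two full
#'   fibre rotations).
#' @param t120_um thickness of one cylinder in micrometres.
#' @param diameter_um cylinder diameter in micrometres (default 1.5).
#' @param strip_count even number of alternating strips across the diameter
#'   (default 8).
#' @param rotation_step_deg fibre-direction increment between successive
#'   cylinders, in degrees, in (0, 180] (default 120).
#' @param fibre,matrix [material_table()] rows (single-row tables) for the two
#'   phases; defaults are chitin fibre E = 17 GPa and protein matrix
#'   E = 0.2 GPa, both with Poisson's ratio 0.3.
#' @param n_across number of elements across the diameter (default 12).
#' @param n_z_per_cylinder element layers through each cylinder (default 2).
#' @return an object of class `cylinder_stack_spec`.
#' @export
cylinder_stack_spec <- function(n_cylinders, t120_um, diameter_um = 1.5,
                                strip_count = 8L, rotation_step_deg = 120,
                                fibre = material_table("fibre", 17e9, 0.3),
                                matrix = material_table("matrix", 0.2e9, 0.3),
                                n_across = 12L, n_z_per_cylinder = 2L) {
  n_cylinders <- as.integer(n_cylinders)
  strip_count <- as.integer(strip_count)
  if (n_cylinders < 1L) stop("n_cylinders must be >= 1")
  if (!is.finite(t120_um) || t120_um <= 0) stop("t120_um must be > 0")
  if (strip_count < 2L || strip_count %% 2L != 0L) {
    stop("strip_count must be an even integer >= 2 (alternating fibre/matrix)")
  }
  if (rotation_step_deg <= 0 || rotation_step_deg > 180) {
    stop("rotation_step_deg must lie in (0, 180]")
  }
  structure(list(n_cylinders = n_cylinders, t120_um = t120_um,
                 diameter_um = diameter_um, strip_count = strip_count,
                 rotation_step_deg = rotation_step_deg,
                 fibre = fibre, matrix = matrix,
                 n_across = as.integer(n_across),
                 n_z_per_cylinder = as.integer(n_z_per_cylinder)),
            class = "cylinder_stack_spec")
}

#' Build the hexahedral mesh of a laminate cylinder stack
#'
#' Discretizes the stack with a structured square-to-disc mapped grid
#' (`n_across` elements across the diameter, `n_z_per_cylinder` layers per
#' cylinder). Element material labels alternate in parallel strips across the
#' diameter; the strip direction of cylinder k is rotated by
#' `(k - 1) * rotation_step_deg` about the stack axis.
#'
#' @param spec a [cylinder_stack_spec()].
#' @return a `hex8` [fem_mesh()] with material labels `"fibre"` / `"matrix"`
#'   and attributes `cylinder` (per-element cylinder index) and `spec`.
#' @export
build_stack_mesh <- function(spec) {
  stopifnot(inherits(spec, "cylinder_stack_spec"))
  R_um <- spec$diameter_um / 2
  strip_w <- spec$diameter_um / spec$strip_count
  elem_w <- spec$diameter_um / spec$n_across
  if (strip_w < elem_w - 1e-12) {
    stop("strip width (", strip_w, " um) is below the in-plane element size (",
         elem_w, " um); increase n_across for a finer mesh")
  }
  n <- spec$n_across
  um <- 1e-6

  # square [-1,1]^2 -> unit disc (elliptical mapping, boundary exact)
  s <- seq(-1, 1, length.out = n + 1)
  grid2 <- expand.grid(a = s, b = s)
  px <- grid2$a * sqrt(1 - grid2$b^2 / 2)
  py <- grid2$b * sqrt(1 - grid2$a^2 / 2)

  nz_tot <- spec$n_cylinders * spec$n_z_per_cylinder
  zs <- seq(0, spec$n_cylinders * spec$t120_um, length.out = nz_tot + 1)
  npl <- (n + 1)^2
  nodes <- do.call(rbind, lapply(zs, function(z)
    cbind(px * R_um, py * R_um, z))) * um

  nid <- function(i, j, k) i + (n + 1) * (j - 1) + npl * (k - 1)
  ne_plane <- n * n
  ne <- ne_plane * nz_tot
  conn <- matrix(0L, ne, 8)
  cyl_of <- integer(ne)
  cent <- matrix(0, ne, 2)
  e <- 0L
  for (k in seq_len(nz_tot)) {
    cyl <- (k - 1L) %/% spec$n_z_per_cylinder + 1L
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        e <- e + 1L
        conn[e, ] <- c(nid(i, j, k), nid(i + 1, j, k),
                       nid(i + 1, j + 1, k), nid(i, j + 1, k),
                       nid(i, j, k + 1), nid(i + 1, j, k + 1),
                       nid(i + 1, j + 1, k + 1), nid(i, j + 1, k + 1))
        cyl_of[e] <- cyl
        base <- conn[e, 1:4]
        cent[e, ] <- colMeans(nodes[base, 1:2, drop = FALSE]) / um
      }
    }
  }

  theta <- (cyl_of - 1L) * spec$rotation_step_deg * pi / 180
  # coordinate across the strips (perpendicular to the fibre direction)
  p <- -cent[, 1] * sin(theta) + cent[, 2] * cos(theta)
  idx <- pmin(pmax(floor((p + R_um) / strip_w), 0), spec$strip_count - 1)
  material <- ifelse(idx %% 2 == 0, "fibre", "matrix")

  mesh <- fem_mesh(nodes, conn, "hex8", material)
  attr(mesh, "cylinder") <- cyl_of
  attr(mesh, "spec") <- spec
  mesh
}

#' Support and load conditions for the cylinder-stack simulations
#'
#' All edge nodes of the bottom surface are blocked in z; the edge node on the
#' positive y-axis is additionally blocked in x, and the node on the opposite
#' side of the y-axis is blocked in all directions. A total force of
#' `total_force_n` (default 3 mN) is applied downwards, split equally over the
#' `n_load_nodes` nodes nearest the centre of the top surface.
#'
#' @param mesh a cylinder-stack mesh from [build_stack_mesh()].
#' @param total_force_n total applied force in newtons (default `3e-3`).
#' @param n_load_nodes number of loaded top-centre nodes (default 5).
#' @return a [load_case()].
#' @export
stack_load_case <- function(mesh, total_force_n = 3e-3, n_load_nodes = 5L) {
  nodes <- mesh$nodes
  zmin <- min(nodes[, 3]); zmax <- max(nodes[, 3])
  r <- sqrt(nodes[, 1]^2 + nodes[, 2]^2)
  R <- max(r)
  tol <- 1e-6 * R
  bottom_ring <- which(abs(nodes[, 3] - zmin) < tol & r > R - tol)
  if (length(bottom_ring) < 3L) stop("cannot identify the bottom edge ring")

  ring_xy <- nodes[bottom_ring, 1:2, drop = FALSE]
  on_pos_y <- bottom_ring[which.min((ring_xy[, 1])^2 + (ring_xy[, 2] - R)^2)]
  on_neg_y <- bottom_ring[which.min((ring_xy[, 1])^2 + (ring_xy[, 2] + R)^2)]

  fixed <- rbind(cbind(bottom_ring, 3L),
                 cbind(on_pos_y, 1L),
                 cbind(on_neg_y, 1L), cbind(on_neg_y, 2L))
  fixed <- unique(fixed)

  top <- which(abs(nodes[, 3] - zmax) < tol)
  if (length(top) < n_load_nodes) {
    stop("fewer than ", n_load_nodes, " nodes on the top face")
  }
  ord <- order(r[top])
  load_nodes <- top[ord[seq_len(n_load_nodes)]]
  loads <- cbind(load_nodes, 3L, -total_force_n / n_load_nodes)
  load_case(fixed, loads)
}

#' Run the lamination simulation series
#'
#' Builds laminate stack models with 1 to `max_cylinders` cylinders at the
#' T120 derived from a procuticle observation, solves each under the standard
#' load case, and records the maximum deformation on the model's bottom
#' surface.
#'
#' @param obs a [procuticle_observation()].
#' @param max_cylinders last cylinder count of the series (default 6).
#' @param ... further arguments passed to [cylinder_stack_spec()]
#'   (materials, strip count, mesh density, ...).
#' @param total_force_n total applied force in newtons (default 3 mN).
#' @return a `data.frame` of class `deformation_series` with columns
#'   `n_cylinders` and `bottom_max_deformation_nm`, plus a `morphotype`
#'   attribute.
#' @export
run_lamination_series <- function(obs, max_cylinders = 6L, ...,
                                  total_force_n = 3e-3) {
  stopifnot(inherits(obs, "procuticle_observation"))
  t120 <- t120_from_t360(t360_from_observation(obs))
  def_nm <- numeric(max_cylinders)
  for (n in seq_len(max_cylinders)) {
    spec <- cylinder_stack_spec(n_cylinders = n, t120_um = t120, ...)
    mesh <- build_stack_mesh(spec)
    materials <- rbind(spec$fibre, spec$matrix)
    ld <- stack_load_case(mesh, total_force_n = total_force_n)
    res <- tryCatch(
      assemble_and_solve(mesh, materials, ld),
      error = function(e) stop(sprintf("lamination series failed at n = %d: %s",
                                       n, conditionMessage(e)), call. = FALSE))
    bottom <- which(abs(mesh$nodes[, 3] - min(mesh$nodes[, 3])) <
                      1e-6 * max(abs(mesh$nodes)))
    def_nm[n] <- max_deformation_in_region(res, bottom) * 1e9
  }
  out <- data.frame(n_cylinders = seq_len(max_cylinders),
                    bottom_max_deformation_nm = def_nm)
  attr(out, "morphotype") <- obs$morphotype
  class(out) <- c("deformation_series", "data.frame")
  out
}

#' Read procuticle observations from CSV
#'
#' Expects columns `morphotype`, `thickness_um`, `layers`.
#'
#' @param path CSV file path.
#' @return list of [procuticle_observation()] objects.
#' @export
read_procuticle_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("morphotype", "thickness_um", "layers")
  if (!all(need %in% names(d))) {
    stop("procuticle CSV needs columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(d)), function(i)
    procuticle_observation(d$thickness_um[i], d$layers[i], d$morphotype[i]))
}

#' Reference morphotype summaries
#'
#' Published summary statistics for the four morphotypes (two species, each
#' uninduced and predator-induced): median procuticle thickness and layer
#' count, AFM procuticle Young's modulus (mean and SD), microindenter
#' structural Young's modulus, critical force, the laminate model each
#' morphotype maps onto, and the cylinder count meeting the observed
#' thickness. Shipped as plain CSV under `extdata`.
#'
#' @return a `data.frame`, one row per morphotype.
#' @export
morphotype_reference <- function() {
  utils::read.csv(system.file("extdata", "morphotype_summaries.csv",
                              package = "daphniarmor"),
                  stringsAsFactors = FALSE)
}

#' Reference laminate deformation series
#'
#' The published maximum bottom-side deformations (nm) of the three laminate
#' models (i: D. pulex uninduced / D. longicephala induced; ii: D. pulex
#' induced; iii: D. longicephala uninduced) for 1 to 6 stacked cylinders.
#' These printed values feed the power-law fit and extrapolation stage.
#'
#' @return a `data.frame` with columns `n_cylinders`, `model_i_nm`,
#'   `model_ii_nm`, `model_iii_nm`.
#' @export
laminate_deformation_reference <- function() {
  utils::read.csv(system.file("extdata", "laminate_deformation_reference.csv",
                              package = "daphniarmor"),
                  stringsAsFactors = FALSE)
}

#' Reference shape-swap simulation summaries
#'
#' Published maximum deformation (um) and maximum stress (kPa) of the shell
#' simulations crossing carapace shape (uninduced / induced) with procuticle
#' structure (uninduced / induced) for both species, at 1 mN load.
#'
#' @return a `data.frame` with columns `species`, `shape`, `structure`,
#'   `max_deformation_um`, `max_stress_kpa`.
#' @export
shape_swap_reference <- function() {
  utils::read.csv(system.file("extdata", "shape_swap_reference.csv",
                              package = "daphniarmor"),
                  stringsAsFactors = FALSE)
}
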