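#' Landmark set describing one carapace
#'
#' Combines the species outline scheme (33 ordered landmarks/semi-landmarks
#' for *D. pulex*, 31 for *D. longicephala*), the 310-point surface
#' semi-landmark grid (31 horizontal x 10 vertical lines projected onto one
#' body hemisphere), one extra cleft semi-landmark per horizontal line
#' marking the free ventral margin, and the 3 anatomical reference points
#' used for alignment (rostrum tip, carapace-spine transition, fifth dorsal
#' thorn). Coordinates are in metres, lateral view in the x-y plane
#' (x anterior-posterior, y dorsoventral) with z the lateral depth.
#'
#' @param outline numeric matrix (n x 2 or n x 3) of ordered outline points.
#' @param surface numeric matrix (310 x 3): the complete grid, row-major over
#'   31 rows (head to spine) by 10 columns (dorsal to ventral).
#' @param cleft numeric matrix (31 x 3), one point per horizontal grid line.
#' @param reference numeric matrix (3 x 3) of distinct, non-collinear
#'   alignment anchors.
#' @param species `"pulex"` or `"longicephala"`.
#' @param origin_convention `"nauplius-eye"` (pulex) or `"compound-eye"`
#'   (longicephala).
#' @param grid_dim grid size as `c(rows, cols)` (default `c(31, 10)`).
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(outline, surface, cleft, reference,
                         species = c("pulex", "longicephala"),
                         origin_convention = NULL,
                         grid_dim = c(31L, 10L)) {
  species <- match.arg(species)
  origin_convention <- origin_convention %||%
    if (species == "pulex") "nauplius-eye" else "compound-eye"
  outline <- unname(as.matrix(outline))
  if (ncol(outline) == 2L) outline <- cbind(outline, 0)
  surface <- unname(as.matrix(surface))
  cleft <- unname(as.matrix(cleft))
  reference <- unname(as.matrix(reference))
  n_expect <- c(pulex = 33L, longicephala = 31L)[[species]]
  if (nrow(outline) != n_expect) {
    stop(sprintf("%s outline scheme has %d points, got %d",
                 species, n_expect, nrow(outline)))
  }
  if (nrow(surface) != prod(grid_dim) || ncol(surface) != 3L) {
    stop(sprintf("surface grid must be complete: %d x 3 points",
                 prod(grid_dim)))
  }
  if (nrow(cleft) != grid_dim[1] || ncol(cleft) != 3L) {
    stop("need one 3-D cleft point per horizontal grid line")
  }
  if (nrow(reference) != 3L || ncol(reference) != 3L) {
    stop("need exactly 3 reference points in 3-D")
  }
  if (any(duplicated(round(reference, 15))) ||
      ref_collinear(reference)) {
    stop("reference points must be 3 distinct non-collinear points")
  }
  structure(list(outline = outline, surface = surface, cleft = cleft,
                 reference = reference, species = species,
                 origin_convention = origin_convention,
                 grid_dim = as.integer(grid_dim)),
            class = "landmark_set")
}

ref_collinear <- function(P) {
  v1 <- P[2, ] - P[1, ]; v2 <- P[3, ] - P[1, ]
  n <- crossprod_vec3(v1, v2)
  scale <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  scale == 0 || sqrt(sum(n^2)) < 1e-10 * scale
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %s (%s origin): %d outline, %d surface, %d cleft points\n",
              x$species, x$origin_convention, nrow(x$outline),
              nrow(x$surface), nrow(x$cleft)))
  invisible(x)
}

# least-squares similarity transform (Umeyama): maps rows of A onto rows of B
similarity_transform <- function(A, B) {
  muA <- colMeans(A); muB <- colMeans(B)
  A0 <- sweep(A, 2, muA); B0 <- sweep(B, 2, muB)
  S <- crossprod(A0, B0) / nrow(A)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  Dm <- diag(c(1, 1, d))
  R <- sv$v %*% Dm %*% t(sv$u)
  varA <- sum(A0^2) / nrow(A)
  scale <- sum(diag(Dm) * sv$d) / varA
  t_vec <- muB - scale * as.numeric(R %*% muA)
  list(scale = scale, rotation = R, translation = t_vec)
}

apply_similarity <- function(P, tr) {
  sweep(tcrossprod(P, tr$rotation) * tr$scale, 2, tr$translation, `+`)
}

#' Align landmark sets on their reference points
#'
#' Computes, for every set, the least-squares optimal similarity transform
#' (uniform scale + rotation + translation) mapping its 3 reference points
#' onto those of the first set, and applies it to all point blocks.
#'
#' @param sets list of at least 2 [landmark_set()] objects with the same
#'   species scheme.
#' @return list of aligned `landmark_set` objects (the first is returned
#'   unchanged); each carries the applied transform as attribute `transform`.
#' @export
align_landmark_sets <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 landmark sets to align")
  sp <- unique(vapply(sets, function(s) s$species, character(1)))
  if (length(sp) != 1L) stop("all landmark sets must share one species scheme")
  target <- sets[[1]]$reference
  lapply(sets, function(s) {
    if (ref_collinear(s$reference)) stop("collinear reference points")
    tr <- similarity_transform(s$reference, target)
    out <- s
    for (blk in c("outline", "surface", "cleft", "reference")) {
      out[[blk]] <- apply_similarity(s[[blk]], tr)
    }
    attr(out, "transform") <- tr
    out
  })
}

#' Average aligned landmark sets
#'
#' Pointwise mean configuration over sets with identical point schemas,
#' producing the representative shape used for the shell simulations.
#'
#' @param aligned list of aligned [landmark_set()] objects.
#' @return a single `landmark_set`.
#' @export
average_shapes <- function(aligned) {
  if (length(aligned) < 1L) stop("no landmark sets supplied")
  s1 <- aligned[[1]]
  for (s in aligned[-1]) {
    same <- s$species == s1$species &&
      nrow(s$outline) == nrow(s1$outline) &&
      all(s$grid_dim == s1$grid_dim)
    if (!same) stop("landmark sets have mismatching point schemas")
  }
  out <- s1
  for (blk in c("outline", "surface", "cleft", "reference")) {
    out[[blk]] <- Reduce(`+`, lapply(aligned, `[[`, blk)) / length(aligned)
  }
  out
}

#' Procuticle structure for a shell model
#'
#' Bundles the carapace wall thickness (from the STEM observation) with the
#' AFM-derived Young's modulus into the material side of a shell simulation.
#'
#' @param thickness_um carapace wall thickness in micrometres, or a
#'   [procuticle_observation()] whose thickness is used.
#' @param young_modulus_pa procuticle Young's modulus in Pa.
#' @param poisson_ratio shell Poisson's ratio (default 0.15).
#' @param label material label (default "procuticle").
#' @return an object of class `procuticle_structure`.
#' @export
procuticle_structure <- function(thickness_um, young_modulus_pa,
                                 poisson_ratio = 0.15, label = "procuticle") {
  if (inherits(thickness_um, "procuticle_observation")) {
    thickness_um <- thickness_um$thickness_um
  }
  if (thickness_um <= 0) stop("thickness_um must be > 0")
  if (young_modulus_pa <= 0) stop("young_modulus_pa must be > 0")
  structure(list(thickness_um = thickness_um,
                 young_modulus_pa = young_modulus_pa,
                 poisson_ratio = poisson_ratio, label = label),
            class = "procuticle_structure")
}

#' Build a loaded carapace shell model from a landmark set
#'
#' Triangulates the 310-point surface grid plus cleft points into `shell3`
#' facets (two per grid quad, plus the cleft fans along the ventral margin),
#' assigns the wall thickness and AFM-derived modulus, constrains every
#' body-outline node (first and last horizontal line and the dorsal-edge
#' column) in all translations while leaving the ventral margin free, and
#' distributes a total load of `load_n` over the `n_load_nodes` surface nodes
#' at the carapace's highest lateral width, directed toward the sagittal
#' plane.
#'
#' @param shape a [landmark_set()].
#' @param structure a [procuticle_structure()].
#' @param load_n total load in newtons (default 1 mN).
#' @param n_load_nodes nodes sharing the load (default 5).
#' @return an object of class `shell_model`: fields `mesh`, `materials`,
#'   `load`, `load_nodes`, `constrained_nodes`, `ventral_nodes`.
#' @export
build_shell_model <- function(shape, structure, load_n = 1e-3,
                              n_load_nodes = 5L) {
  stopifnot(inherits(shape, "landmark_set"),
            inherits(structure, "procuticle_structure"))
  nr <- shape$grid_dim[1]; nc <- shape$grid_dim[2]
  gid <- function(r, c) (r - 1L) * nc + c
  cid <- function(r) nr * nc + r
  nodes <- rbind(shape$surface, shape$cleft)

  tri <- matrix(0L, 2L * (nr - 1L) * (nc - 1L) + 2L * (nr - 1L), 3L)
  e <- 0L
  for (r in seq_len(nr - 1L)) {
    for (c in seq_len(nc - 1L)) {
      tri[e + 1L, ] <- c(gid(r, c), gid(r + 1L, c), gid(r + 1L, c + 1L))
      tri[e + 2L, ] <- c(gid(r, c), gid(r + 1L, c + 1L), gid(r, c + 1L))
      e <- e + 2L
    }
  }
  for (r in seq_len(nr - 1L)) {   # cleft fans along the ventral margin
    tri[e + 1L, ] <- c(gid(r, nc), gid(r + 1L, nc), cid(r + 1L))
    tri[e + 2L, ] <- c(gid(r, nc), cid(r + 1L), cid(r))
    e <- e + 2L
  }

  mesh <- fem_mesh(nodes, tri, "shell3", structure$label)
  # degenerate-facet check with grid indices in the message
  for (k in seq_len(nrow(tri))) {
    xe <- nodes[tri[k, ], , drop = FALSE]
    a2 <- sqrt(sum(crossprod_vec3(xe[2, ] - xe[1, ], xe[3, ] - xe[1, ])^2))
    if (a2 <= 1e-24) {
      stop(sprintf("degenerate triangle at facet %d (grid nodes %s): fold in the landmark grid",
                   k, paste(tri[k, ], collapse = ", ")))
    }
  }

  materials <- material_table(structure$label, structure$young_modulus_pa,
                              structure$poisson_ratio,
                              thickness = structure$thickness_um * 1e-6)

  # outline of the body: head line (r = 1), spine line (r = nr), dorsal edge
  # (c = 1); the ventral margin (c = nc and the cleft points) stays free
  constrained <- unique(c(gid(1L, seq_len(nc)), gid(nr, seq_len(nc)),
                          gid(seq_len(nr), 1L)))
  ventral <- c(gid(seq_len(nr), nc), cid(seq_len(nr)))
  constrained <- setdiff(constrained, ventral)

  # highest lateral width: column whose nodes reach maximal |z|
  depth <- abs(shape$surface[, 3])
  widest <- which.max(depth)
  col_of <- ((seq_len(nr * nc) - 1L) %% nc) + 1L
  load_col <- col_of[widest]
  col_nodes <- which(col_of == load_col)
  col_nodes <- setdiff(col_nodes, constrained)
  if (length(col_nodes) < n_load_nodes) {
    stop("not enough free nodes in the widest grid column to carry the load")
  }
  ord <- order(-depth[col_nodes])
  load_nodes <- col_nodes[ord[seq_len(n_load_nodes)]]
  zsign <- sign(shape$surface[widest, 3])
  if (zsign == 0) zsign <- 1
  loads <- cbind(load_nodes, 3L, -zsign * load_n / n_load_nodes)

  fixed <- cbind(rep(constrained, each = 3L), rep(1:3, length(constrained)))
  structure(list(mesh = mesh, materials = materials,
                 load = load_case(fixed, loads),
                 load_nodes = load_nodes, load_column = load_col,
                 constrained_nodes = constrained, ventral_nodes = ventral,
                 structure = structure, species = shape$species),
            class = "shell_model")
}

#' @export
print.shell_model <- function(x, ...) {
  cat(sprintf("<shell_model> %s: %d nodes, %d facets | t = %.3g um, E = %.3g Pa | %d loaded, %d constrained nodes\n",
              x$species, n_nodes(x$mesh), n_elements(x$mesh),
              x$structure$thickness_um, x$structure$young_modulus_pa,
              length(x$load_nodes), length(x$constrained_nodes)))
  invisible(x)
}

#' Solve a carapace shell model
#'
#' @param model a [shell_model()].
#' @return list with the raw `fem_result` plus `max_deformation_um` and
#'   `max_stress_kpa` on the reporting scales.
#' @export
solve_shell_model <- function(model) {
  res <- shell_solve(model$mesh, model$materials, model$load)
  list(result = res,
       max_deformation_um = res$max_deformation * 1e6,
       max_stress_kpa = res$max_stress / 1e3)
}

#' Run the 2 x 2 shape-versus-structure swap experiment
#'
#' Crosses carapace shape (uninduced / induced) with procuticle structure
#' (uninduced / induced): four shell simulations under the same total load,
#' separating the contributions of shape change and cuticle reorganization to
#' mechanical resistance.
#'
#' @param shape_uninduced,shape_induced [landmark_set()] objects.
#' @param structure_uninduced,structure_induced [procuticle_structure()]
#'   objects.
#' @param load_n total load in newtons (default 1 mN).
#' @return a `data.frame` of class `swap_result` with one row per cell:
#'   `shape`, `structure`, `max_deformation_um`, `max_stress_kpa`.
#' @export
run_swap_matrix <- function(shape_uninduced, shape_induced,
                            structure_uninduced, structure_induced,
                            load_n = 1e-3) {
  shapes <- list(uninduced = shape_uninduced, induced = shape_induced)
  structures <- list(uninduced = structure_uninduced,
                     induced = structure_induced)
  rows <- list()
  for (sh in names(shapes)) {
    for (st in names(structures)) {
      sol <- tryCatch(
        solve_shell_model(build_shell_model(shapes[[sh]], structures[[st]],
                                            load_n = load_n)),
        error = function(e) stop(sprintf("swap cell (shape %s, structure %s): %s",
                                         sh, st, conditionMessage(e)),
                                 call. = FALSE))
      rows[[length(rows) + 1L]] <-
        data.frame(shape = sh, structure = st,
                   max_deformation_um = sol$max_deformation_um,
                   max_stress_kpa = sol$max_stress_kpa,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (any(out$max_deformation_um <= 0)) {
    stop("swap cell produced non-positive deformation under nonzero load")
  }
  class(out) <- c("swap_result", "data.frame")
  out
}

#' Read / write landmark sets as CSV
#'
#' Long format with columns `point_id`, `role`
#' (`outline|surface|cleft|reference`), `x`, `y`, `z` (metres).
#'
#' @param path file path.
#' @param set a [landmark_set()] (writer only).
#' @param species,origin_convention passed to [landmark_set()] (reader only).
#' @return reader: a `landmark_set`; writer: `path` invisibly.
#' @export
read_landmarks_csv <- function(path, species = "pulex",
                               origin_convention = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  pick <- function(role) {
    b <- d[d$role == role, , drop = FALSE]
    as.matrix(b[order(b$point_id), c("x", "y", "z")])
  }
  landmark_set(pick("outline"), pick("surface"), pick("cleft"),
               pick("reference"), species = species,
               origin_convention = origin_convention)
}

#' @rdname read_landmarks_csv
#' @export
write_landmarks_csv <- function(set, path) {
  stopifnot(inherits(set, "landmark_set"))
  blk <- function(m, role) data.frame(point_id = seq_len(nrow(m)), role = role,
                                      x = m[, 1], y = m[, 2], z = m[, 3])
  d <- rbind(blk(set$outline, "outline"), blk(set$surface, "surface"),
             blk(set$cleft, "cleft"), blk(set$reference, "reference"))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Outline landmark definitions per species
#'
#' Machine-readable table of the ordered outline landmark/semi-landmark
#' definitions for both species schemes, shipped under `extdata`.
#'
#' @param species `"pulex"` or `"longicephala"`.
#' @return a `data.frame` with columns `point`, `definition`.
#' @export
landmark_scheme <- function(species = c("pulex", "longicephala")) {
  species <- match.arg(species)
  d <- utils::read.csv(system.file("extdata", "landmark_schemes.csv",
                                   package = "daphniarmor"),
                       stringsAsFactors = FALSE)
  d[d$species == species, c("point", "definition")]
}
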