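#' Flat triangulated sheet
#'
#' Square sheet in the z = 0 plane, `x, y` in `[0, side]`, triangulated on
#' a regular grid; winding gives all face normals along `+z`.
#'
#' @param side Side length in mm.
#' @param spacing Target edge length in mm.
#' @return A [surface_mesh].
#' @export
make_flat_sheet <- function(side = 10, spacing = 1) {
  stopifnot(side > 0, spacing > 0)
  n <- max(1L, round(side / spacing))
  g <- seq(0, side, length.out = n + 1L)
  grid_mesh(outer(g, rep(1, n + 1L)), outer(rep(1, n + 1L), g),
            matrix(0, n + 1L, n + 1L), name = "flat_sheet")
}

# Triangulate a structured (nu x nv) grid of 3D points given as three
# coordinate matrices. Winding: for a grid in the xy-plane with u = x,
# v = y, normals point along +z.
grid_mesh <- function(X, Y, Z, name = "grid") {
  nu <- nrow(X); nv <- ncol(X)
  vid <- matrix(seq_len(nu * nv), nu, nv)     # column-major vertex ids
  v <- cbind(as.vector(X), as.vector(Y), as.vector(Z))
  i <- rep(seq_len(nu - 1L), nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  v00 <- vid[cbind(i, j)]
  v10 <- vid[cbind(i + 1L, j)]
  v01 <- vid[cbind(i, j + 1L)]
  v11 <- vid[cbind(i + 1L, j + 1L)]
  f <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  surface_mesh(v, f, name = name)
}

#' Two parallel plates facing each other
#'
#' Idealized limit of opposing sulcal walls: two square sheets separated by
#' `separation` along z, with inward-facing winding (the lower plate's
#' normals point `+z`, the upper plate's `-z`), so facing vertices have
#' \eqn{n_x \cdot n_y = -1}.
#'
#' @param separation Plate separation in mm.
#' @param side Plate side length in mm.
#' @param spacing Target edge length in mm.
#' @return A [surface_mesh]; attribute `labels` marks `"lower"`/`"upper"`
#'   vertices.
#' @export
make_parallel_plates <- function(separation, side = 10, spacing = 1) {
  stopifnot(separation > 0, side > 0, spacing > 0)
  lower <- make_flat_sheet(side, spacing)
  upper <- lower
  upper$vertices[, 3L] <- separation
  upper$faces <- upper$faces[, c(1L, 3L, 2L)]   # flip winding: normals -z
  mesh <- merge_meshes(list(lower, upper), name = "parallel_plates")
  attr(mesh, "labels") <- rep(c("lower", "upper"),
                              each = nrow(lower$vertices))
  mesh
}

# Concatenate meshes (no vertex welding).
merge_meshes <- function(meshes, name = "merged") {
  off <- 0L
  v <- list(); f <- list()
  for (m in meshes) {
    v[[length(v) + 1L]] <- m$vertices
    f[[length(f) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  surface_mesh(do.call(rbind, v), do.call(rbind, f), name = name)
}

#' Triangulated sphere (subdivided icosahedron)
#'
#' Icosahedron refined by `subdivisions` rounds of midpoint subdivision,
#' with every vertex projected to the sphere; winding is outward.
#'
#' @param radius Radius in mm.
#' @param subdivisions Number of subdivision rounds (0 = icosahedron).
#' @param center Sphere centre in mm.
#' @return A closed [surface_mesh].
#' @export
make_sphere <- function(radius = 10, subdivisions = 3, center = c(0, 0, 0)) {
  stopifnot(radius > 0, subdivisions >= 0)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  mesh <- surface_mesh(v / sqrt(1 + phi^2), f, name = "sphere")
  for (k in seq_len(subdivisions)) {
    mesh <- subdivide_mesh(mesh)
    nrm <- sqrt(rowSums(mesh$vertices^2))
    mesh$vertices <- mesh$vertices / nrm
  }
  mesh$vertices <- sweep(mesh$vertices * radius, 2L, center, "+")
  if (signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  mesh$name <- "sphere"
  mesh
}

#' Midpoint (1-to-4) triangle subdivision
#'
#' Splits every triangle into four by edge midpoints (no smoothing or
#' reprojection); shared edge midpoints are welded.
#'
#' @param mesh A [surface_mesh].
#' @return The refined [surface_mesh].
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  ekey <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  uk <- unique(ekey)
  mid_id <- nrow(v) + match(ekey, uk)
  ue <- e[!duplicated(ekey), , drop = FALSE]
  mids <- (v[ue[, 1L], , drop = FALSE] + v[ue[, 2L], , drop = FALSE]) / 2
  nf <- nrow(f)
  m12 <- mid_id[seq_len(nf)]
  m23 <- mid_id[nf + seq_len(nf)]
  m31 <- mid_id[2L * nf + seq_len(nf)]
  newf <- rbind(cbind(f[, 1L], m12, m31),
                cbind(f[, 2L], m23, m12),
                cbind(f[, 3L], m31, m23),
                cbind(m12, m23, m31))
  surface_mesh(rbind(v, mids), newf, name = mesh$name)
}

#' Synthetic sulcus phantom
#'
#' Open surface emulating a cortical fold: two opposing planar walls
#' separated by `width` (wall-to-wall), joined below by a semicylindrical
#' fundus of radius `width/2` and, optionally, capped above by outward
#' quarter-cylinder gyral crowns. The profile lies in the x–z plane and is
#' extruded along y over `length`. Winding is chosen so normals point into
#' the sulcal gap (the CSF side): facing interior wall vertices have
#' \eqn{n_x \cdot n_y = -1}, and the minimal cross-wall vertex distance
#' equals `width` exactly (facing grid sites are aligned).
#'
#' @param width Wall-to-wall separation in mm.
#' @param depth Total sulcal depth in mm (must exceed `width`).
#' @param length Extrusion length in mm.
#' @param gyral_cap Add outward gyral crowns at the top?
#' @param spacing Target edge length in mm (must be below `width/2`).
#' @param seed Unused source of randomness slot (the phantom is
#'   deterministic); kept so specs carry a complete provenance record.
#' @param segments Optional explicit resolution
#'   `list(wall =, fundus =, cap =, axial =)` (segment counts). When given,
#'   the mesh topology is independent of `width`, which is what the
#'   synthetic cohort uses to keep vertex correspondence across subjects.
#' @return A [surface_mesh] with attribute `labels` (per-vertex:
#'   `"wall_neg"`, `"wall_pos"`, `"fundus"`, `"cap_neg"`, `"cap_pos"`).
#' @export
make_sulcus_phantom <- function(width = 2, depth = 15, length = 20,
                                gyral_cap = FALSE, spacing = 0.5,
                                seed = NULL, segments = NULL) {
  stopifnot(width > 0, depth > width, length > 0)
  if (spacing >= width / 2)
    stop("spacing must be below width/2 to resolve the sulcal gap")
  half <- width / 2
  wall_h <- depth - half          # straight wall extent
  rc <- half                      # crown radius

  if (is.null(segments)) {
    segments <- list(wall = max(2L, ceiling(wall_h / spacing)),
                     fundus = max(4L, ceiling(pi * half / spacing)),
                     cap = max(2L, ceiling(pi / 2 * rc / spacing)),
                     axial = max(2L, ceiling(length / spacing)))
  }

  # cross-section profile (x, z) traversed cap A -> wall A (down) ->
  # fundus -> wall B (up) -> cap B, with per-point labels
  prof <- list(); lab <- list()
  if (gyral_cap) {
    psi <- seq(pi / 2, pi, length.out = segments$cap + 1L)
    psi <- psi[-length(psi)]          # stop before the wall-top point
    prof[[length(prof) + 1L]] <-
      cbind(-(half + rc) - rc * cos(psi), rc * sin(psi))
    lab[[length(lab) + 1L]] <- rep("cap_neg", length(psi))
  }
  zw <- seq(0, -wall_h, length.out = segments$wall + 1L)
  prof[[length(prof) + 1L]] <- cbind(rep(-half, length(zw)), zw)
  lab[[length(lab) + 1L]] <- rep("wall_neg", length(zw))
  th <- seq(pi, 2 * pi, length.out = segments$fundus + 1L)
  th <- th[-c(1L, length(th))]       # wall bottoms already present
  prof[[length(prof) + 1L]] <- cbind(half * cos(th), -wall_h + half * sin(th))
  lab[[length(lab) + 1L]] <- rep("fundus", length(th))
  prof[[length(prof) + 1L]] <- cbind(rep(half, length(zw)), rev(zw))
  lab[[length(lab) + 1L]] <- rep("wall_pos", length(zw))
  if (gyral_cap) {
    psi <- seq(pi, pi / 2, length.out = segments$cap + 1L)
    psi <- psi[-1L]
    prof[[length(prof) + 1L]] <-
      cbind((half + rc) + rc * cos(psi), rc * sin(psi))
    lab[[length(lab) + 1L]] <- rep("cap_pos", length(psi))
  }
  prof <- do.call(rbind, prof)
  labs <- unlist(lab)

  yy <- seq(0, length, length.out = segments$axial + 1L)
  np <- nrow(prof)
  X <- matrix(prof[, 1L], np, length(yy))
  Y <- matrix(yy, np, length(yy), byrow = TRUE)
  Z <- matrix(prof[, 2L], np, length(yy))
  mesh <- grid_mesh(X, Y, Z, name = "sulcus")
  # grid_mesh winding gives face normal ~ tangent x u_v; with u along the
  # profile and v along +y this is tangent x (+y), which points into the
  # gap for the traversal order above
  attr(mesh, "labels") <- rep(labs, length(yy))
  attr(mesh, "spec") <- list(width = width, depth = depth, length = length,
                             gyral_cap = gyral_cap, spacing = spacing,
                             seed = seed, segments = segments)
  mesh
}
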