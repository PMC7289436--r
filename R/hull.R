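# Incremental 3D convex hull.
#
# Returns a surface_mesh of the hull with outward winding. For (near)
# coplanar point sets a planar fallback triangulates the 2D convex
# polygon in-plane (a degenerate 3D hull has no outward side, but the
# gyrification proxy still needs an outer surface there). Collinear or
# coincident point sets error.
convex_hull_3d <- function(points, tol = 1e-9) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 3L) stop("degenerate hull: fewer than 3 points")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  sv <- svd(x, nu = 0L)
  scale <- sv$d[1L]
  if (scale < tol) stop("degenerate hull: coincident points")
  if (sv$d[2L] / scale < 1e-7) stop("degenerate hull: collinear points")
  if (sv$d[3L] / scale < 1e-7) return(planar_hull(pts, sv$v))

  faces <- init_tetra(pts, tol * scale)
  eps <- 1e-9 * scale
  for (p in setdiff(seq_len(n), unique(as.vector(faces)))) {
    # faces visible from point p
    nrm <- face_cross(list(vertices = pts, faces = faces))
    cref <- pts[faces[, 1L], , drop = FALSE]
    side <- rowSums(nrm * (matrix(pts[p, ], nrow(faces), 3L, byrow = TRUE) -
                           cref))
    vis <- side > eps
    if (!any(vis)) next
    # horizon: boundary edges of the visible set
    fv <- faces[vis, , drop = FALSE]
    ed <- rbind(fv[, c(1L, 2L)], fv[, c(2L, 3L)], fv[, c(3L, 1L)])
    key <- paste(pmin(ed[, 1L], ed[, 2L]), pmax(ed[, 1L], ed[, 2L]))
    horizon <- ed[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    faces <- rbind(faces[!vis, , drop = FALSE],
                   cbind(horizon, p))
  }
  hull <- surface_mesh(pts, faces, name = "convex_hull")
  hull <- repair_mesh(hull)
  if (is_closed_mesh(hull) && signed_volume(hull) < 0)
    hull$faces <- hull$faces[, c(1L, 3L, 2L)]
  hull
}

# Seed tetrahedron with outward winding for the incremental hull.
init_tetra <- function(pts, tol) {
  n <- nrow(pts)
  i1 <- which.min(pts[, 1L])
  i2 <- which.max(pts[, 1L])
  if (i1 == i2) stop("degenerate hull: coincident points")
  d <- pts[i2, ] - pts[i1, ]
  # farthest from the line (i1, i2)
  rel <- sweep(pts, 2L, pts[i1, ])
  cr <- cross3(rel, matrix(d, n, 3L, byrow = TRUE))
  i3 <- which.max(rowSums(cr * cr))
  nrm <- cross3(matrix(pts[i2, ] - pts[i1, ], 1L),
                matrix(pts[i3, ] - pts[i1, ], 1L))[1L, ]
  h <- rel %*% nrm
  i4 <- which.max(abs(h))
  if (abs(h[i4]) <= tol) stop("degenerate hull: coplanar points")
  f <- rbind(c(i1, i2, i3), c(i1, i3, i4), c(i1, i4, i2), c(i2, i4, i3))
  # orient every face away from the centroid
  ctr <- colMeans(pts[c(i1, i2, i3, i4), , drop = FALSE])
  nr <- face_cross(list(vertices = pts, faces = f))
  out <- rowSums(nr * (pts[f[, 1L], , drop = FALSE] -
                       matrix(ctr, 4L, 3L, byrow = TRUE)))
  f[out < 0, ] <- f[out < 0, c(1L, 3L, 2L), drop = FALSE]
  f
}

# Planar fallback: 2D convex polygon of the projected points, fan
# triangulated in-plane.
planar_hull <- function(pts, basis) {
  uv <- sweep(pts, 2L, colMeans(pts)) %*% basis[, 1:2]
  idx <- grDevices::chull(uv[, 1L], uv[, 2L])
  if (length(idx) < 3L) stop("degenerate hull: collinear points")
  f <- cbind(idx[1L], idx[seq(2L, length(idx) - 1L)],
             idx[seq(3L, length(idx))])
  surface_mesh(pts, f, name = "convex_hull_planar")
}
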