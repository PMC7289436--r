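#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` holds the triangulated representation of a cortical (or
#' phantom) surface: an `n x 3` matrix of vertex coordinates in millimetres
#' and an `m x 3` integer matrix of 1-based vertex indices, one row per
#' triangle.
#'
#' @param vertices Numeric matrix (`n x 3`) of vertex coordinates in mm.
#' @param faces Integer matrix (`m x 3`) of 1-based vertex indices.
#' @param name Label for the mesh (used in provenance metadata).
#'
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces` and `name`.
#' @export
#' @examples
#' tet <- surface_mesh(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
#'   faces = rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
#'   name = "tetrahedron"
#' )
#' n_vertices(tet)
surface_mesh <- function(vertices, faces, name = "mesh") {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L)
    stop("`vertices` must be an n x 3 matrix of mm coordinates")
  if (!all(is.finite(vertices)))
    stop("`vertices` must be finite")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (nrow(faces) > 0L) {
    if (ncol(faces) != 3L)
      stop("`faces` must be an m x 3 matrix of vertex indices")
    if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices))
      stop("face indices must lie in 1..n_vertices")
    if (any(faces[, 1L] == faces[, 2L] | faces[, 1L] == faces[, 3L] |
            faces[, 2L] == faces[, 3L]))
      stop("faces must not repeat a vertex")
  } else {
    faces <- matrix(integer(0), 0L, 3L)
  }
  if (nrow(vertices) == 0L) stop("mesh has no vertices")
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces,
                 name = as.character(name)[1L]),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh '%s': %d vertices, %d faces>\n",
              x$name, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Number of vertices / faces of a mesh
#' @param mesh A `surface_mesh`.
#' @return Integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# Face normals (not normalized; magnitude = 2 * face area) and face areas.
face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cross3(v[f[, 2L], , drop = FALSE] - v[f[, 1L], , drop = FALSE],
         v[f[, 3L], , drop = FALSE] - v[f[, 1L], , drop = FALSE])
}

face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr * cr))
}

#' Total surface area of a mesh
#' @param mesh A `surface_mesh`.
#' @return Total area in mm^2.
#' @export
mesh_area <- function(mesh) sum(face_areas(mesh))

# Signed volume of a (closed) mesh via the divergence theorem; positive when
# face winding is globally outward.
signed_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c_ <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) -
      a[, 2L] * (b[, 1L] * c_[, 3L] - b[, 3L] * c_[, 1L]) +
      a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

# TRUE when every edge is shared by exactly two faces.
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0L) return(FALSE)
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}
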