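#' Per-vertex normals and areas
#'
#' Computes the per-vertex local frame used by the ephaptic index: the unit
#' surface normal \eqn{n} (area-weighted mean of incident face normals,
#' renormalized) and the vertex area \eqn{\delta A} (one third of the areas
#' of the incident faces). Vertices with no incident non-degenerate face
#' are flagged invalid; their normals are zero and excluded from index
#' computations.
#'
#' With `orientation = "outward"` and a closed mesh, all normals are flipped
#' when the mesh's signed volume is negative, so they point out of the
#' enclosed volume. On an open mesh this check is impossible and the
#' winding-derived orientation is kept with a warning.
#'
#' @param mesh A (repaired) [surface_mesh].
#' @param orientation `"outward"` or `"as_is"` (keep winding orientation).
#' @return An object of class `vertex_frame`: list with `normals` (`n x 3`,
#'   unit rows), `areas` (mm^2), `valid_mask` (logical).
#' @export
compute_vertex_frame <- function(mesh, orientation = c("as_is", "outward")) {
  orientation <- match.arg(orientation)
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  cr <- face_cross(mesh)                 # |cr| = 2 * face area
  fa <- 0.5 * sqrt(rowSums(cr * cr))

  normals <- matrix(0, nv, 3L)
  # accumulate with rowsum on a padded index so every vertex appears;
  # cr is already area-weighted (|cr| = 2 * area)
  pad <- seq_len(nv)
  acc_area <- rowsum(c(fa, fa, fa, numeric(nv)),
                     c(f[, 1L], f[, 2L], f[, 3L], pad))
  areas <- acc_area[, 1L] / 3
  acc_n <- rowsum(rbind(cr, cr, cr, matrix(0, nv, 3L)),
                  c(f[, 1L], f[, 2L], f[, 3L], pad))
  nrm <- sqrt(rowSums(acc_n * acc_n))
  valid <- nrm > 0 & areas > 0
  normals[valid, ] <- acc_n[valid, , drop = FALSE] / nrm[valid]

  if (orientation == "outward") {
    if (is_closed_mesh(mesh)) {
      if (signed_volume(mesh) < 0) normals <- -normals
    } else {
      warning("mesh is open: outward orientation undefined, ",
              "keeping winding-based orientation")
    }
  }
  structure(list(normals = normals, areas = unname(areas),
                 valid_mask = unname(valid)),
            class = "vertex_frame")
}

#' @export
print.vertex_frame <- function(x, ...) {
  cat(sprintf("<vertex_frame: %d vertices (%d valid), total area %.4g mm^2>\n",
              length(x$areas), sum(x$valid_mask), sum(x$areas)))
  invisible(x)
}
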